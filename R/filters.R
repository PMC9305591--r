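#' Site filter thresholds
#'
#' Bundle of the per-site quality thresholds applied before analysis:
#' maximum fraction of missing calls, minimum minor-allele frequency
#' (computed over called alleles, pooled across all samples), and minimum
#' p-value of the Hardy-Weinberg exact test (pooled).
#'
#' @param max_missing_fraction Maximum missing-call fraction per site
#'   (default 0.10, i.e. a site must be called in at least 90% of
#'   individuals).
#' @param maf_min Minimum minor-allele frequency (default 0.025).
#' @param hwe_min_p Minimum HWE exact-test p-value (default 0.001).
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(max_missing_fraction = 0.10, maf_min = 0.025,
                        hwe_min_p = 0.001) {
  stopifnot(max_missing_fraction >= 0, max_missing_fraction <= 1,
            maf_min >= 0, maf_min <= 0.5,
            hwe_min_p > 0, hwe_min_p <= 1)
  structure(list(max_missing_fraction = max_missing_fraction,
                 maf_min = maf_min, hwe_min_p = hwe_min_p),
            class = "filter_spec")
}

#' Hardy-Weinberg equilibrium exact test
#'
#' Conditional exact test of HWE genotype proportions given the observed
#' allele counts. All heterozygote counts compatible with the allele
#' counts are enumerated; each configuration (nAA, nAa, naa) is weighted
#' by the multinomial coefficient times `2^nAa`, weights are normalized
#' to probabilities, and the p-value is the sum of probabilities of
#' configurations no more probable than the observed one.
#'
#' @param n_AA,n_Aa,n_aa Non-negative genotype counts
#'   (homozygote / heterozygote / other homozygote), summing to >= 1.
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one genotype is required")
  nA <- 2L * n_AA + n_Aa
  na <- 2L * n - nA
  hets <- seq.int(nA %% 2L, min(nA, na), by = 2L)
  # log weight of configuration with h heterozygotes
  lw <- lfactorial(n) - lfactorial((nA - hets) / 2) - lfactorial(hets) -
    lfactorial((na - hets) / 2) + hets * log(2)
  prob <- exp(lw - max(lw))
  prob <- prob / sum(prob)
  p_obs <- prob[match(n_Aa, hets)]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-12)]))
}

#' Apply per-site quality filters
#'
#' Retains sites with call rate `>= 1 - max_missing_fraction`, pooled
#' minor-allele frequency `>= maf_min`, and (optionally) pooled HWE
#' exact-test p-value `>= hwe_min_p`. Per-rule removal counts are
#' reported via `message()` and attached as attribute `"filter_log"`.
#'
#' @param gm A non-empty [genotype_matrix()].
#' @param spec A [filter_spec()].
#' @param use_hwe Apply the HWE rule? The HWE filter targets highly
#'   non-neutral loci and is appropriate for population-structure
#'   analyses; selection scans typically disable it so as not to discard
#'   their own signal.
#' @return A filtered `genotype_matrix` (possibly with zero sites).
#' @export
filter_sites <- function(gm, spec, use_hwe = TRUE) {
  stopifnot(inherits(spec, "filter_spec"))
  if (n_samples(gm) == 0L) stop("genotype matrix has no samples")
  if (n_sites(gm) == 0L) return(gm)
  call_rate <- colMeans(!is.na(gm$calls))
  ok_miss <- call_rate >= 1 - spec$max_missing_fraction
  mf <- maf(gm)
  ok_maf <- !is.na(mf) & mf >= spec$maf_min
  if (use_hwe) {
    hwe_p <- vapply(seq_len(n_sites(gm)), function(j) {
      g <- gm$calls[, j]
      g <- g[!is.na(g)]
      if (!length(g)) return(1)
      hwe_exact_test(sum(g == 0L), sum(g == 1L), sum(g == 2L))
    }, numeric(1))
    ok_hwe <- hwe_p >= spec$hwe_min_p
  } else {
    ok_hwe <- rep(TRUE, n_sites(gm))
  }
  keep <- ok_miss & ok_maf & ok_hwe
  log <- c(missing = sum(!ok_miss), maf = sum(!ok_maf),
           hwe = sum(!ok_hwe), retained = sum(keep))
  message(sprintf(
    "filter_sites: %d/%d retained (removed: %d missingness, %d MAF, %d HWE)",
    log[["retained"]], n_sites(gm), log[["missing"]], log[["maf"]],
    log[["hwe"]]))
  out <- gm_subset(gm, sites = keep)
  attr(out, "filter_log") <- log
  out
}

#' Build a pairwise comparison subset
#'
#' Restricts the matrix to the individuals of two disjoint group sets and
#' retains sites with at least `min_called_a` called individuals in the
#' first pool, at least `min_called_b` in the second, and pooled
#' minor-allele frequency `>= maf_min` after the restriction. This is the
#' operation used to build the pairwise comparison files contrasting
#' historical, native, and invasive samples.
#'
#' @param gm A [genotype_matrix()].
#' @param group_a,group_b Disjoint character vectors of group labels.
#' @param min_called_a,min_called_b Minimum called individuals per pool
#'   (defaults 5, i.e. half of a ten-specimen museum series and the
#'   matching contemporary floor).
#' @param maf_min Minimum pooled MAF after restriction (default 0.025).
#' @return A `genotype_matrix` containing exactly the union of the two
#'   group's individuals.
#' @export
comparison_subset <- function(gm, group_a, group_b,
                              min_called_a = 5L, min_called_b = 5L,
                              maf_min = 0.025) {
  if (length(intersect(group_a, group_b)))
    stop("overlapping groups: ",
         paste(intersect(group_a, group_b), collapse = ", "))
  ra <- group_rows(gm, group_a)
  rb <- group_rows(gm, group_b)
  sub <- gm_subset(gm, samples = c(ra, rb))
  ra2 <- group_rows(sub, group_a)
  rb2 <- group_rows(sub, group_b)
  called_a <- colSums(!is.na(sub$calls[ra2, , drop = FALSE]))
  called_b <- colSums(!is.na(sub$calls[rb2, , drop = FALSE]))
  mf <- maf(sub)
  keep <- called_a >= min_called_a & called_b >= min_called_b &
    !is.na(mf) & mf >= maf_min
  message(sprintf("comparison_subset: %d/%d sites retained",
                  sum(keep), n_sites(sub)))
  gm_subset(sub, sites = keep)
}
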