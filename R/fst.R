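#' Per-site Weir-Cockerham F_ST between two pools
#'
#' The Weir & Cockerham (1984) moment estimator for `r = 2` populations,
#' computed from genotype counts. For each site, per-pool sample sizes
#' `n_i` (called individuals), alternate-allele frequencies `p_i`, and
#' observed heterozygote fractions `h_i` give the mean sample size
#' `n_bar`, the squared coefficient-of-variation correction `n_c`, the
#' weighted mean frequency `p_bar`, the among-population variance `s2`,
#' and the mean heterozygosity `h_bar`, from which the variance
#' components are
#' \deqn{a = (n_bar/n_c) [ s2 - (p_bar(1-p_bar) - s2/2 - h_bar/4)/(n_bar-1) ]}
#' \deqn{b = (n_bar/(n_bar-1)) [ p_bar(1-p_bar) - s2/2 - (2 n_bar - 1) h_bar / (4 n_bar) ]}
#' \deqn{c = h_bar / 2}
#' and `theta = a / (a + b + c)`. The within-individual component uses
#' observed heterozygosity, with no HWE assumption. A site is defined
#' only where both pools have at least two called individuals; sites
#' monomorphic across both pools (or with a non-positive denominator)
#' carry `theta = NA`. Negative `theta` is retained, not clamped.
#'
#' @param gm A [genotype_matrix()].
#' @param pop1,pop2 Character vectors of group labels forming the two
#'   pools.
#' @return `data.frame` with columns `snp_id`, `scaffold`, `pos`, `n1`,
#'   `n2`, `a`, `b`, `c`, `theta`; one row per site, in genome order.
#' @export
site_fst_wc <- function(gm, pop1, pop2) {
  r1 <- group_rows(gm, pop1)
  r2 <- group_rows(gm, pop2)
  if (!length(r1) || !length(r2)) stop("empty population pool")
  m1 <- gm$calls[r1, , drop = FALSE]
  m2 <- gm$calls[r2, , drop = FALSE]
  n1 <- colSums(!is.na(m1))
  n2 <- colSums(!is.na(m2))
  p1 <- ifelse(n1 > 0, colSums(m1, na.rm = TRUE) / (2 * n1), NA_real_)
  p2 <- ifelse(n2 > 0, colSums(m2, na.rm = TRUE) / (2 * n2), NA_real_)
  h1 <- ifelse(n1 > 0, colSums(m1 == 1L, na.rm = TRUE) / n1, NA_real_)
  h2 <- ifelse(n2 > 0, colSums(m2 == 1L, na.rm = TRUE) / n2, NA_real_)

  ok <- n1 >= 2L & n2 >= 2L
  nbar <- (n1 + n2) / 2
  nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
  pbar <- (n1 * p1 + n2 * p2) / (2 * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar  # (r - 1) = 1
  hbar <- (n1 * h1 + n2 * h2) / (2 * nbar)

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a[!ok] <- NA_real_
  b[!ok] <- NA_real_
  cc[!ok] <- NA_real_
  denom <- a + b + cc
  theta <- ifelse(ok & denom > 0, a / denom, NA_real_)
  data.frame(snp_id = gm$sites$snp_id, scaffold = gm$sites$scaffold,
             pos = gm$sites$pos, n1 = n1, n2 = n2,
             a = a, b = b, c = cc, theta = theta,
             stringsAsFactors = FALSE)
}

#' Sliding-window F_ST
#'
#' Aggregates per-site variance components into overlapping genomic
#' windows. Windows start at positions 1, 1+step, 1+2*step, ... on each
#' scaffold and span `window_bp` (1-based inclusive). A window is emitted
#' only if it contains at least `min_sites` sites with defined `theta`.
#' The `weighted` value is the ratio-of-sums `sum(a) / sum(a + b + c)`
#' over contained sites (the conventional weighted window F_ST), and
#' `mean` is the average of per-site ratios.
#'
#' @param fst Per-site table from [site_fst_wc()].
#' @param window_bp Window span in bp (default 900,000).
#' @param step_bp Step between window starts in bp (default 10,000).
#' @param min_sites Minimum defined sites per emitted window (default 1).
#' @return `data.frame` with columns `scaffold`, `start`, `end`,
#'   `n_sites`, `weighted`, `mean`.
#' @export
windowed_fst <- function(fst, window_bp = 900000L, step_bp = 10000L,
                         min_sites = 1L) {
  stopifnot(window_bp >= step_bp, step_bp >= 1)
  fst <- fst[!is.na(fst$theta), , drop = FALSE]
  out <- lapply(split(fst, fst$scaffold), function(d) {
    d <- d[order(d$pos), , drop = FALSE]
    if (!nrow(d)) return(NULL)
    starts <- seq.int(1L, max(d$pos), by = step_bp)
    ends <- starts + window_bp - 1L
    csA <- c(0, cumsum(d$a))
    csD <- c(0, cumsum(d$a + d$b + d$c))
    csT <- c(0, cumsum(d$theta))
    lo <- findInterval(starts - 1L, d$pos)
    hi <- findInterval(ends, d$pos)
    n <- hi - lo
    keep <- n >= min_sites
    data.frame(scaffold = d$scaffold[1L], start = starts[keep],
               end = ends[keep], n_sites = n[keep],
               weighted = (csA[hi + 1L] - csA[lo + 1L])[keep] /
                 (csD[hi + 1L] - csD[lo + 1L])[keep],
               mean = (csT[hi + 1L] - csT[lo + 1L])[keep] / n[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), n_sites = integer(0),
                      weighted = numeric(0), mean = numeric(0))
  rownames(out) <- NULL
  out
}

#' Multi-locus pairwise F_ST with bootstrap significance
#'
#' For every pair of groups, the multi-locus Weir-Cockerham estimate is
#' the ratio-of-sums `sum(a) / sum(a + b + c)` over all sites defined for
#' that pair. Significance is assessed by resampling loci with
#' replacement: `p` is the fraction of bootstrap replicates whose
#' estimate is `<= 0` (a one-sided test of differentiation exceeding
#' zero).
#'
#' @param gm A [genotype_matrix()].
#' @param groups Character vector (length >= 2) of group labels.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return A list with symmetric matrices `fst` (diagonal 0) and `p`
#'   (diagonal `NA`), dimnames `groups`.
#' @export
multilocus_fst <- function(gm, groups, n_boot = 1000L, seed = 1L) {
  stopifnot(length(groups) >= 2, n_boot >= 1)
  sz <- table(gm$samples$group)[groups]
  if (any(is.na(sz)) || any(sz < 2))
    stop("every group needs at least 2 individuals")
  k <- length(groups)
  fst <- matrix(0, k, k, dimnames = list(groups, groups))
  pmat <- matrix(NA_real_, k, k, dimnames = list(groups, groups))
  set.seed(seed)
  for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k)) {
    tab <- site_fst_wc(gm, groups[i], groups[j])
    d <- tab$a + tab$b + tab$c
    use <- !is.na(tab$theta)
    if (!any(use)) { fst[i, j] <- fst[j, i] <- NA_real_; next }
    A <- tab$a[use]; D <- d[use]
    est <- sum(A) / sum(D)
    idx <- matrix(sample.int(length(A), length(A) * n_boot, replace = TRUE),
                  ncol = n_boot)
    boots <- colSums(matrix(A[idx], ncol = n_boot)) /
      colSums(matrix(D[idx], ncol = n_boot))
    pv <- mean(boots <= 0)
    fst[i, j] <- fst[j, i] <- est
    pmat[i, j] <- pmat[j, i] <- pv
  }
  list(fst = fst, p = pmat)
}
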