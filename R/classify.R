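#' Classify pooled outlier SNPs for one invasive subpopulation
#'
#' Given the three pairwise outlier sets for one invasive subpopulation
#' — contemporary native vs. historical (`o_ukhs`), invasive vs.
#' historical (`o_auhs`), and native vs. invasive (`o_ukau`) — every SNP
#' flagged in at least one set receives exactly one category:
#'
#' * `divergent`: flagged in the native-vs-invasive set AND in either
#'   (or both) of the historical comparisons — a change in one lineage
#'   only. Membership in all three sets also satisfies this rule, so the
#'   triple pattern is classified divergent.
#' * `parallel`: flagged in both historical comparisons but NOT between
#'   the contemporary ranges — the same change on both continents.
#' * `uk_only` / `au_only` / `ukau_only`: flagged in exactly one set.
#'
#' @param o_ukhs,o_auhs,o_ukau [outlier_set()]s of the comparison triple.
#' @return Named character vector: SNP id -> category.
#' @export
classify_pairwise <- function(o_ukhs, o_auhs, o_ukau) {
  u <- union(o_ukhs$members, union(o_auhs$members, o_ukau$members))
  in1 <- u %in% o_ukhs$members
  in2 <- u %in% o_auhs$members
  in3 <- u %in% o_ukau$members
  cat_ <- ifelse((in1 | in2) & in3, "divergent",
          ifelse(in1 & in2, "parallel",
          ifelse(in1, "uk_only",
          ifelse(in2, "au_only", "ukau_only"))))
  stats::setNames(cat_, u)
}

#' Pool classifications from the two invasive subpopulations
#'
#' Per SNP, the pooled category set is the union of its categories from
#' the two per-subpopulation maps; a SNP absent from one map contributes
#' only the other's category. A SNP may therefore carry several pooled
#' categories (e.g. divergent against one subpopulation and parallel
#' against the other).
#'
#' @param east,south Named category vectors from [classify_pairwise()].
#' @return Named list: SNP id -> character vector of categories (sorted,
#'   unique).
#' @export
pool_subpops <- function(east, south) {
  ids <- union(names(east), names(south))
  out <- lapply(ids, function(id)
    sort(unique(c(if (id %in% names(east)) east[[id]],
                  if (id %in% names(south)) south[[id]]))))
  stats::setNames(out, ids)
}

#' Category counts of a pooled classification
#'
#' @param pooled Named list from [pool_subpops()].
#' @return Named integer vector of SNP counts per category (a SNP with
#'   several categories is counted in each), plus `total` distinct SNPs.
#' @export
classification_counts <- function(pooled) {
  cats <- c("divergent", "parallel", "uk_only", "au_only", "ukau_only")
  n <- vapply(cats, function(k)
    sum(vapply(pooled, function(v) k %in% v, logical(1))), integer(1))
  c(n, total = length(pooled))
}
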