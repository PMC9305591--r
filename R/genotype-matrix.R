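#' Genotype matrix container
#'
#' The central data structure of the pipeline: a matrix of diploid
#' alternate-allele counts (0, 1, 2, or `NA` for missing) with per-site and
#' per-sample metadata. Rows are individuals, columns are biallelic SNP
#' sites. Every individual belongs to exactly one group (sampling
#' location), and positions are 1-based and strictly increasing within
#' each scaffold.
#'
#' @param calls Integer matrix, individuals x sites, values in
#'   `c(0, 1, 2, NA)`.
#' @param sites `data.frame` with columns `snp_id`, `scaffold`, `pos`
#'   (1-based), `ref`, `alt`; one row per column of `calls`.
#' @param samples `data.frame` with columns `id` and `group`; one row per
#'   row of `calls`.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, sites, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  stopifnot(is.data.frame(sites), is.data.frame(samples))
  if (nrow(samples) != nrow(calls))
    stop("sample metadata rows (", nrow(samples),
         ") do not match call matrix rows (", nrow(calls), ")")
  if (nrow(sites) != ncol(calls))
    stop("site metadata rows (", nrow(sites),
         ") do not match call matrix columns (", ncol(calls), ")")
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("calls must be 0, 1, 2 or NA")
  if (anyDuplicated(samples$id))
    stop("duplicated individual ids")
  if (any(is.na(samples$group)) || any(samples$group == ""))
    stop("every individual must carry a group label")
  if (nrow(sites)) {
    req <- c("snp_id", "scaffold", "pos", "ref", "alt")
    miss <- setdiff(req, names(sites))
    if (length(miss)) stop("sites missing columns: ", paste(miss, collapse = ", "))
    ord <- order(sites$scaffold, sites$pos)
    if (is.unsorted(ord)) {
      calls <- calls[, ord, drop = FALSE]
      sites <- sites[ord, , drop = FALSE]
    }
    dp <- unlist(tapply(sites$pos, sites$scaffold, function(p) diff(p) <= 0))
    if (any(dp)) stop("positions must be strictly increasing within scaffold")
  }
  rownames(calls) <- samples$id
  colnames(calls) <- sites$snp_id
  rownames(sites) <- NULL
  rownames(samples) <- NULL
  structure(list(calls = calls, sites = sites, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "individuals x",
      ncol(x$calls), "sites\n")
  tb <- table(x$samples$group)
  cat("groups:", paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "), "\n")
  if (ncol(x$calls)) {
    cr <- mean(!is.na(x$calls))
    cat(sprintf("call rate: %.3f over %d scaffolds\n", cr,
                length(unique(x$sites$scaffold))))
  }
  invisible(x)
}

#' Number of sites / samples in a genotype matrix
#' @param gm A `genotype_matrix`.
#' @return Integer count.
#' @export
n_sites <- function(gm) ncol(gm$calls)

#' @rdname n_sites
#' @export
n_samples <- function(gm) nrow(gm$calls)

#' Subset a genotype matrix
#'
#' @param gm A `genotype_matrix`.
#' @param samples Row (individual) index, logical or integer; default all.
#' @param sites Column (site) index, logical or integer; default all.
#' @return A new `genotype_matrix`.
#' @export
gm_subset <- function(gm, samples = NULL, sites = NULL) {
  if (is.null(samples)) samples <- seq_len(nrow(gm$calls))
  if (is.null(sites)) sites <- seq_len(ncol(gm$calls))
  genotype_matrix(gm$calls[samples, sites, drop = FALSE],
                  gm$sites[sites, , drop = FALSE],
                  gm$samples[samples, , drop = FALSE])
}

#' Row indices of the individuals in a set of groups
#' @param gm A `genotype_matrix`.
#' @param groups Character vector of group labels.
#' @return Integer vector of row indices (in sample order).
#' @export
group_rows <- function(gm, groups) {
  unknown <- setdiff(groups, unique(gm$samples$group))
  if (length(unknown))
    stop("unknown group label(s): ", paste(unknown, collapse = ", "))
  which(gm$samples$group %in% groups)
}

#' Pooled alternate-allele frequency per site
#'
#' Computed over called genotypes only; missing calls never contribute to
#' allele counts. Sites with zero called individuals return `NA`.
#'
#' @param gm A `genotype_matrix`.
#' @param rows Optional row subset.
#' @return Numeric vector, one frequency per site.
#' @export
alt_freq <- function(gm, rows = NULL) {
  m <- if (is.null(rows)) gm$calls else gm$calls[rows, , drop = FALSE]
  called <- colSums(!is.na(m))
  alt <- colSums(m, na.rm = TRUE)
  ifelse(called > 0, alt / (2 * called), NA_real_)
}

#' Minor-allele frequency per site (pooled)
#' @inheritParams alt_freq
#' @return Numeric vector in \[0, 0.5\].
#' @export
maf <- function(gm, rows = NULL) {
  p <- alt_freq(gm, rows)
  pmin(p, 1 - p)
}
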