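#' Nei's (1972) standard genetic distance between groups
#'
#' For each pair of groups the normalized identity over biallelic loci is
#' `I = J_xy / sqrt(J_x J_y)` with `J_xy = mean(p_x p_y + q_x q_y)`,
#' `J_x = mean(p_x^2 + q_x^2)` and `J_y` analogous, and the distance is
#' `D = -ln(I)`. Loci with no called individuals in either group of a
#' pair are excluded pairwise. When `I = 0` (all shared loci fixed for
#' opposite alleles) the distance is reported as `+Inf` rather than an
#' error, so matrices remain constructible; [nj_tree()] rejects such
#' matrices.
#'
#' @param gm A [genotype_matrix()].
#' @param groups Character vector of group labels.
#' @return Symmetric numeric matrix of distances with zero diagonal.
#' @export
neis_distance <- function(gm, groups) {
  freqs <- vapply(groups, function(g) alt_freq(gm, group_rows(gm, g)),
                  numeric(n_sites(gm)))
  k <- length(groups)
  D <- matrix(0, k, k, dimnames = list(groups, groups))
  for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k)) {
    px <- freqs[, i]; py <- freqs[, j]
    use <- !is.na(px) & !is.na(py)
    if (!any(use))
      stop("no shared called loci between ", groups[i], " and ", groups[j])
    px <- px[use]; py <- py[use]
    jxy <- mean(px * py + (1 - px) * (1 - py))
    jx <- mean(px^2 + (1 - px)^2)
    jy <- mean(py^2 + (1 - py)^2)
    I <- jxy / sqrt(jx * jy)
    D[i, j] <- D[j, i] <- if (I <= 0) Inf else -log(I)
  }
  D
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei neighbour joining (Studier-Keppler criterion, via
#' \pkg{ape}). Negative branch lengths, which neighbour joining can
#' produce on non-additive matrices, are clamped to zero with the excess
#' moved to the adjacent branch descending from the same node, so that
#' path lengths through that node are preserved.
#'
#' @param dist Square symmetric numeric matrix with zero diagonal and
#'   finite entries, size >= 3.
#' @param labels Optional tip labels; default taken from `dist` dimnames.
#' @return A newick string (unrooted tree), with the `phylo` object
#'   attached as attribute `"phylo"`.
#' @export
nj_tree <- function(dist, labels = NULL) {
  dist <- as.matrix(dist)
  if (nrow(dist) != ncol(dist)) stop("distance matrix must be square")
  if (nrow(dist) < 3) stop("need at least 3 taxa")
  if (!isTRUE(all.equal(dist, t(dist), tolerance = 1e-8,
                        check.attributes = FALSE)))
    stop("distance matrix must be symmetric")
  if (any(abs(diag(dist)) > 1e-12)) stop("diagonal must be zero")
  if (any(!is.finite(dist)))
    stop("distance matrix contains non-finite entries")
  if (!is.null(labels)) dimnames(dist) <- list(labels, labels)
  if (is.null(rownames(dist)))
    dimnames(dist) <- list(paste0("t", seq_len(nrow(dist))),
                           paste0("t", seq_len(nrow(dist))))
  tr <- ape::nj(stats::as.dist(dist))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1L]
    sib <- setdiff(which(tr$edge[, 1L] == parent), e)
    if (length(sib)) {
      excess <- tr$edge.length[e]
      tr$edge.length[sib[1L]] <- tr$edge.length[sib[1L]] + excess
    }
    tr$edge.length[e] <- 0
  }
  nwk <- ape::write.tree(tr)
  attr(nwk, "phylo") <- tr
  nwk
}

#' PCA of a genotype matrix
#'
#' Each site is centred by its mean call and scaled by
#' `sqrt(p_hat (1 - p_hat))` with `p_hat` the pooled alternate-allele
#' frequency; missing calls are imputed with the site mean (zero after
#' centring). Coordinates are the projections onto the top-`k`
#' eigenvectors of the resulting covariance. Monomorphic and fully
#' missing sites are dropped before decomposition.
#'
#' @param gm A [genotype_matrix()].
#' @param k Number of components, `k <= n_samples(gm)`.
#' @return A list with `coords` (individuals x k, dimnames kept) and
#'   `explained` (proportion of variance per returned axis).
#' @export
pca_genotypes <- function(gm, k = 2L) {
  if (k > n_samples(gm)) stop("k exceeds the number of individuals")
  p <- alt_freq(gm)
  use <- !is.na(p) & p > 0 & p < 1
  if (!any(use)) stop("no polymorphic sites: zero-variance matrix")
  m <- gm$calls[, use, drop = FALSE]
  p <- p[use]
  X <- sweep(m, 2L, 2 * p)
  X[is.na(X)] <- 0
  X <- sweep(X, 2L, sqrt(p * (1 - p)), "/")
  sv <- svd(X)
  if (max(sv$d) < 1e-10) stop("zero-variance matrix")
  coords <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  rownames(coords) <- gm$samples$id
  colnames(coords) <- paste0("PC", seq_len(k))
  list(coords = coords, explained = (sv$d^2 / sum(sv$d^2))[seq_len(k)])
}
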