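#' Assign scaffolds to chromosome classes
#'
#' Avian convention: autosomal scaffolds longer than `threshold_bp`
#' (strictly greater; default 20 Mb) are macrochromosomes, shorter ones
#' microchromosomes; scaffolds named in `z_names` are the Z sex
#' chromosome regardless of length.
#'
#' @param chrommap `data.frame` with columns `name` and `length`
#'   (optionally `class`, used only to default `z_names`).
#' @param threshold_bp Macro/micro length cutoff (default 2e7).
#' @param z_names Character vector of Z scaffold names; defaults to rows
#'   whose `class` column equals `"Z"` when present.
#' @return Named character vector: scaffold -> one of `"macro"`,
#'   `"micro"`, `"Z"`.
#' @export
assign_chrom_class <- function(chrommap, threshold_bp = 2e7,
                               z_names = NULL) {
  stopifnot(all(c("name", "length") %in% names(chrommap)))
  if (any(chrommap$length <= 0)) stop("scaffold lengths must be positive")
  if (is.null(z_names))
    z_names <- if ("class" %in% names(chrommap))
      chrommap$name[chrommap$class == "Z"] else character(0)
  absent <- setdiff(z_names, chrommap$name)
  if (length(absent))
    stop("Z scaffold(s) absent from table: ", paste(absent, collapse = ", "))
  cls <- ifelse(chrommap$name %in% z_names, "Z",
                ifelse(chrommap$length > threshold_bp, "macro", "micro"))
  stats::setNames(cls, chrommap$name)
}

#' Chromosome-class enrichment chi-square test
#'
#' Tests whether SNP groupings (divergent / parallel / other selected /
#' not selected) are distributed independently of chromosome class
#' (macro / micro / Z) with the standard Pearson chi-square test of
#' independence on the 4 x 3 contingency table. Pearson residuals
#' `(obs - exp)/sqrt(exp)` and per-cell shares of the chi-square
#' statistic are reported for mosaic-style display. Groupings or classes
#' with zero total are collapsed (dropped) with a warning; expected
#' counts below 5 trigger a warning but no automatic exact test.
#'
#' @param snp_groups Named character vector: SNP id -> grouping among
#'   `c("divergent", "parallel", "other_selected", "not_selected")`.
#' @param classes Named character vector: SNP id -> chromosome class.
#'   Every SNP in `snp_groups` must be present.
#' @return A list with `table`, `chi2`, `df`, `p`, `residuals`,
#'   `contributions`, and `n`.
#' @export
enrichment_chisq <- function(snp_groups, classes) {
  miss <- setdiff(names(snp_groups), names(classes))
  if (length(miss))
    stop(length(miss), " SNP(s) lack a chromosome class, e.g. ", miss[1])
  grp <- factor(snp_groups, levels = c("divergent", "parallel",
                                       "other_selected", "not_selected"))
  cls <- factor(classes[names(snp_groups)],
                levels = c("macro", "micro", "Z"))
  if (anyNA(grp)) stop("unknown grouping label")
  if (anyNA(cls)) stop("unknown chromosome class label")
  tab <- table(grp, cls)
  zr <- rowSums(tab) == 0
  zc <- colSums(tab) == 0
  if (any(zr) || any(zc)) {
    warning("collapsing empty grouping/class level(s): ",
            paste(c(rownames(tab)[zr], colnames(tab)[zc]), collapse = ", "))
    tab <- tab[!zr, !zc, drop = FALSE]
  }
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("need at least two groupings and two classes with data")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(ct$expected < 5))
    warning("expected count(s) below 5; chi-square approximation is rough")
  chi2 <- unname(ct$statistic)
  contrib <- if (chi2 > 0) (ct$observed - ct$expected)^2 / ct$expected / chi2
             else array(0, dim(tab), dimnames(tab))
  list(table = unclass(tab), chi2 = chi2, df = unname(ct$parameter),
       p = ct$p.value, residuals = unclass(ct$residuals),
       contributions = unclass(contrib), n = sum(tab))
}

#' Bioinformatic sexing from autosomal vs. Z inbreeding coefficients
#'
#' For each individual, the method-of-moments inbreeding coefficient
#' `F = 1 - H_obs / H_exp` is computed separately on autosomal and
#' Z-linked polymorphic sites, where `H_obs` is the fraction of that
#' individual's called sites that are heterozygous and `H_exp` the mean
#' of `2 p (1 - p)` over the same sites (`p` the pooled allele
#' frequency). Because ZW females are hemizygous on Z, their Z calls are
#' homozygous and `F_Z` approaches 1 while `F_auto` stays near 0:
#' an individual is called female when `F_Z - F_auto > delta`, male
#' otherwise, and unknown when fewer than `min_z_sites` Z sites are
#' called.
#'
#' @param gm A [genotype_matrix()].
#' @param classmap Named vector from [assign_chrom_class()]; must place
#'   at least one of `gm`'s scaffolds on Z.
#' @param delta Decision threshold on `F_Z - F_auto` (default 0.3).
#' @param min_z_sites Minimum called Z sites for a call (default 10).
#' @return `data.frame` with columns `individual`, `F_auto`, `F_Z`,
#'   `n_z_called`, `call`.
#' @export
infer_sex <- function(gm, classmap, delta = 0.3, min_z_sites = 10L) {
  cls <- classmap[gm$sites$scaffold]
  if (anyNA(cls)) stop("unclassified scaffold(s) in genotype matrix")
  p <- alt_freq(gm)
  poly <- !is.na(p) & p > 0 & p < 1
  is_z <- cls == "Z" & poly
  is_auto <- cls != "Z" & poly
  if (!any(cls == "Z")) stop("no Z-linked sites under the class map")
  if (!any(is_z) || !any(is_auto))
    stop("need at least one polymorphic Z and one polymorphic autosomal site")
  fhat <- function(row, cols) {
    g <- gm$calls[row, cols]
    called <- !is.na(g)
    if (!any(called)) return(c(f = NA_real_, n = 0))
    hobs <- mean(g[called] == 1L)
    hexp <- mean(2 * p[cols][called] * (1 - p[cols][called]))
    c(f = 1 - hobs / hexp, n = sum(called))
  }
  res <- t(vapply(seq_len(n_samples(gm)), function(i) {
    fa <- fhat(i, which(is_auto))
    fz <- fhat(i, which(is_z))
    c(fa[["f"]], fz[["f"]], fz[["n"]])
  }, numeric(3)))
  call <- ifelse(res[, 3] < min_z_sites | is.na(res[, 2]) | is.na(res[, 1]),
                 "unknown",
                 ifelse(res[, 2] - res[, 1] > delta, "female", "male"))
  data.frame(individual = gm$samples$id, F_auto = res[, 1],
             F_Z = res[, 2], n_z_called = as.integer(res[, 3]),
             call = call, stringsAsFactors = FALSE)
}

#' Interaction ANOVA of major-allele frequency
#'
#' Tests whether major-allele frequency is associated with the
#' interaction between SNP location (Z vs. autosome) and selection
#' status (selected vs. not), as a data-artefact check: outlier methods
#' lean on allele frequencies, so a location-by-status interaction would
#' signal bias (e.g. from hemizygous female Z calls). The interaction is
#' tested by model comparison — additive versus full two-way linear
#' model — giving `F = ((RSS_add - RSS_full)/df1) / (RSS_full/df2)` with
#' `df1 = 1` and `df2 = N - 4` for the complete two-by-two layout.
#'
#' @param maf Numeric vector of major-allele frequencies in \[0.5, 1\].
#' @param location Factor/character, two levels (e.g. `"Z"`,
#'   `"autosome"`), aligned with `maf`.
#' @param selected Factor/character, two levels (e.g. `"yes"`, `"no"`),
#'   aligned with `maf`.
#' @return A list with `F`, `df1`, `df2`, `p`.
#' @export
interaction_anova <- function(maf, location, selected) {
  location <- factor(location)
  selected <- factor(selected)
  if (nlevels(location) < 2 || nlevels(selected) < 2)
    stop("both factors need two observed levels")
  cells <- table(location, selected)
  if (any(cells == 0))
    stop("empty factor cell; interaction is not estimable")
  if (any(cells == 1))
    warning("factor cell(s) with a single SNP; interaction F is unstable")
  full <- stats::lm(maf ~ location * selected)
  add <- stats::lm(maf ~ location + selected)
  rss_full <- sum(stats::residuals(full)^2)
  rss_add <- sum(stats::residuals(add)^2)
  df1 <- add$df.residual - full$df.residual
  df2 <- full$df.residual
  Fval <- ((rss_add - rss_full) / df1) / (rss_full / df2)
  list(F = Fval, df1 = df1, df2 = df2,
       p = stats::pf(Fval, df1, df2, lower.tail = FALSE))
}
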