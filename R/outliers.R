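#' Outlier SNP set
#'
#' A named pairwise comparison together with the SNPs flagged as
#' candidate targets of selection in it, their scores, and the detection
#' method(s) that flagged each SNP (`"fst_window"` for the window scan,
#' `"external"` for imported calls).
#'
#' @param comparison Comparison label (e.g. `"UK-HS"`).
#' @param members Character vector of SNP ids.
#' @param scores Named numeric vector keyed exactly by `members`.
#' @param method_tags Named list keyed exactly by `members`; each element
#'   a character vector drawn from `c("fst_window", "external")`.
#' @return An object of class `outlier_set`.
#' @export
outlier_set <- function(comparison, members = character(0),
                        scores = stats::setNames(numeric(0), character(0)),
                        method_tags = list()) {
  members <- unique(as.character(members))
  if (!setequal(names(scores), members) ||
      !setequal(names(method_tags), members))
    stop("scores and method_tags must be keyed exactly by members")
  structure(list(comparison = comparison, members = members,
                 scores = scores[members],
                 method_tags = method_tags[members]),
            class = "outlier_set")
}

#' @export
print.outlier_set <- function(x, ...) {
  cat("outlier_set [", x$comparison, "]: ", length(x$members),
      " SNP(s)\n", sep = "")
  invisible(x)
}

#' Select top-percentile F_ST windows
#'
#' Returns the windows whose `weighted` value is greater than or equal
#' to the `q`-quantile (linear-interpolation quantile) of all weighted
#' values.
#'
#' @param windows Window table from [windowed_fst()] (non-empty).
#' @param q Quantile in (0, 1); default 0.99 (top 1% of windows).
#' @return The selected subset of `windows`.
#' @export
percentile_windows <- function(windows, q = 0.99) {
  if (!nrow(windows)) stop("empty window list")
  stopifnot(q > 0, q < 1)
  thr <- stats::quantile(windows$weighted, q, type = 7, names = FALSE)
  windows[windows$weighted >= thr, , drop = FALSE]
}

#' Knee threshold of a ranked statistic
#'
#' Algorithmic stand-in for choosing, by eye, the value at which a
#' descending-sorted statistic plateaus. Rank and value are min-max
#' normalized to \[0, 1\] and the break point is the point at maximum
#' perpendicular distance from the chord joining the first and last
#' points — on the curves this scan produces, the elbow where the
#' initial decline (or cliff) meets the flat tail. The threshold is the
#' value at the break's upper edge: the break point itself when it lies
#' above the chord (end of an initial plateau), and the preceding rank
#' when it lies below (first point past the cliff). With fewer than 3
#' values, or all values equal, the minimum is returned so that
#' everything is retained.
#'
#' @param values Numeric vector, sorted in decreasing order (re-sorted
#'   if not).
#' @return A single threshold, always an element of `values`.
#' @export
plateau_threshold <- function(values) {
  if (!length(values)) stop("empty value list")
  values <- sort(values, decreasing = TRUE)
  n <- length(values)
  if (n < 3L || max(values) == min(values)) return(min(values))
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (values - min(values)) / (max(values) - min(values))
  # chord runs from (0, 1) to (1, 0); |y + x - 1| is proportional to the
  # perpendicular distance from it
  excess <- y + x - 1
  i <- which.max(abs(excess))
  if (excess[i] < 0) i <- i - 1L   # below the chord: cut above the break
  values[max(i, 1L)]
}

#' F_ST window-scan outlier SNPs for one pairwise comparison
#'
#' Composes the scan: per-site Weir-Cockerham F_ST, sliding windows,
#' top-percentile window selection, then a ranked-value knee threshold
#' over the SNPs falling inside the selected windows. SNPs covered by
#' several overlapping selected windows are counted once. Members are
#' the in-window SNPs whose per-site `theta` is `>=` the knee value (the
#' knee SNP itself is retained); a manual `threshold` overrides the
#' knee.
#'
#' @param gm A [genotype_matrix()].
#' @param pop1,pop2 Group-label sets of the two pools.
#' @param window_bp,step_bp,min_sites Window parameters, see
#'   [windowed_fst()].
#' @param q Window percentile, see [percentile_windows()].
#' @param threshold Optional manual per-site F_ST cutoff replacing the
#'   knee rule.
#' @param comparison Label stored on the returned set.
#' @return An [outlier_set()] with members tagged `"fst_window"` and
#'   per-site `theta` as score.
#' @export
fst_outliers <- function(gm, pop1, pop2, window_bp = 900000L,
                         step_bp = 10000L, min_sites = 1L, q = 0.99,
                         threshold = NULL,
                         comparison = paste(paste(pop1, collapse = "+"),
                                            paste(pop2, collapse = "+"),
                                            sep = "-")) {
  fst <- site_fst_wc(gm, pop1, pop2)
  win <- windowed_fst(fst, window_bp, step_bp, min_sites)
  if (!nrow(win)) return(outlier_set(comparison))
  sel <- percentile_windows(win, q)
  fst <- fst[!is.na(fst$theta), , drop = FALSE]
  in_sel <- logical(nrow(fst))
  for (s in unique(sel$scaffold)) {
    w <- sel[sel$scaffold == s, , drop = FALSE]
    i <- which(fst$scaffold == s)
    if (!length(i)) next
    in_sel[i] <- in_sel[i] | vapply(fst$pos[i], function(p)
      any(p >= w$start & p <= w$end), logical(1))
  }
  cand <- fst[in_sel, , drop = FALSE]
  if (!nrow(cand)) return(outlier_set(comparison))
  thr <- if (is.null(threshold))
    plateau_threshold(sort(cand$theta, decreasing = TRUE)) else threshold
  hit <- cand[cand$theta >= thr, , drop = FALSE]
  outlier_set(comparison, hit$snp_id,
              scores = stats::setNames(hit$theta, hit$snp_id),
              method_tags = stats::setNames(
                rep(list("fst_window"), nrow(hit)), hit$snp_id))
}

#' Import an external (BayeScan-style) outlier table
#'
#' Reads a whitespace-separated outlier table in the BayeScan output
#' dialect (row index followed by columns including `qval` and `fst`)
#' and keeps rows with q-value at or below the false-discovery-rate
#' threshold.
#'
#' @param path Path to the table.
#' @param snp_ids Character vector mapping row index `i` to its SNP id.
#' @param q_threshold FDR cutoff on the q-value column (default 0.05).
#' @param comparison Label stored on the returned set.
#' @return An [outlier_set()] with members tagged `"external"`; scores
#'   are the table's `fst` column when present, otherwise `1 - qval`.
#' @export
import_external <- function(path, snp_ids, q_threshold = 0.05,
                            comparison = "external") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty outlier table: ", path)
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  qcol <- which(tolower(header) %in% c("qval", "q_value", "qvalue"))
  if (!length(qcol)) stop("missing q-value column in ", path)
  fcol <- which(tolower(header) == "fst")
  # BayeScan headers omit a name for the index column
  ntok <- length(header) + 1L
  members <- character(0); scores <- numeric(0)
  for (k in seq_along(lines)[-1]) {
    tok <- strsplit(trimws(lines[k]), "\\s+")[[1]]
    if (length(tok) != ntok || anyNA(suppressWarnings(as.numeric(tok))))
      stop("malformed row at line ", k, " of ", path)
    idx <- as.integer(tok[1])
    if (is.na(idx) || idx < 1 || idx > length(snp_ids))
      stop("row index ", tok[1], " at line ", k, " has no SNP id mapping")
    qval <- as.numeric(tok[1L + qcol])
    if (qval <= q_threshold) {
      members <- c(members, snp_ids[idx])
      scores <- c(scores, if (length(fcol)) as.numeric(tok[1L + fcol])
                  else 1 - qval)
    }
  }
  names(scores) <- members
  outlier_set(comparison, members, scores,
              stats::setNames(rep(list("external"), length(members)),
                              members))
}

#' Pool two outlier sets of the same comparison
#'
#' Member union; method tags are merged per SNP; when a SNP carries a
#' window-scan score in either set, that score is kept, otherwise the
#' first available score is used.
#'
#' @param a,b [outlier_set()]s with identical `comparison` labels.
#' @return The pooled [outlier_set()].
#' @export
pool_outliers <- function(a, b) {
  stopifnot(inherits(a, "outlier_set"), inherits(b, "outlier_set"))
  if (!identical(a$comparison, b$comparison))
    stop("mismatched comparison labels: ", a$comparison, " vs ",
         b$comparison)
  members <- union(a$members, b$members)
  scores <- numeric(0); tags <- list()
  for (m in members) {
    ta <- if (m %in% a$members) a$method_tags[[m]] else character(0)
    tb <- if (m %in% b$members) b$method_tags[[m]] else character(0)
    tags[[m]] <- sort(unique(c(ta, tb)))
    sa <- if (m %in% a$members) a$scores[[m]] else NA_real_
    sb <- if (m %in% b$members) b$scores[[m]] else NA_real_
    scores[[m]] <-
      if ("fst_window" %in% ta) sa
      else if ("fst_window" %in% tb) sb
      else if (!is.na(sa)) sa else sb
  }
  outlier_set(a$comparison, members, scores, tags)
}
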