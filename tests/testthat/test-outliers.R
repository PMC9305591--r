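fake_windows <- function(weighted) {
  data.frame(scaffold = rep("s", length(weighted)),
             start = seq_along(weighted),
             end = rep(10, length(weighted)),
             n_sites = rep(1L, length(weighted)),
             weighted = weighted, mean = weighted)
}

test_that("percentile window selection uses the interpolated quantile", {
  win <- fake_windows(as.numeric(1:100))
  sel <- percentile_windows(win, 0.99)
  # interpolated 99% quantile of 1..100 is 99.01 -> only the top window
  expect_equal(sel$weighted, 100)
  expect_equal(percentile_windows(fake_windows(rep(2, 5)), 0.99)$weighted,
               rep(2, 5))
  expect_error(percentile_windows(fake_windows(numeric(0)), 0.99), "empty")
  # monotonicity: raising q never enlarges the selection
  set.seed(2)
  w <- fake_windows(runif(200))
  sizes <- vapply(c(0.5, 0.9, 0.99),
                  function(q) nrow(percentile_windows(w, q)), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("plateau threshold sits at the knee of the ranked curve", {
  # independent exhaustive chord-distance oracle (explicit point-to-line
  # distance, then the cut at the break's upper edge)
  knee_oracle <- function(v) {
    v <- sort(v, decreasing = TRUE)
    n <- length(v)
    x <- (seq_len(n) - 1) / (n - 1)
    y <- (v - min(v)) / (max(v) - min(v))
    d <- vapply(seq_len(n), function(i)
      abs(1 * x[i] + 1 * y[i] - 1) / sqrt(2), numeric(1))
    i <- which.max(d)
    above <- y[i] > 1 - x[i]
    v[if (above) i else max(i - 1, 1)]
  }
  # plateau then cliff: cut at the last plateau value
  expect_equal(plateau_threshold(c(1.0, 0.95, 0.9, 0.3, 0.29, 0.28)), 0.9)
  cases <- list(c(1.0, 0.95, 0.9, 0.3, 0.29, 0.28),
                c(10, 9.5, 9, 8.7, 3, 1, 0.5, 0.2, 0.1),
                exp(-seq(0, 5, length.out = 40)),
                c(5, rev(cumsum(runif(30)))))
  for (v in cases) {
    expect_equal(plateau_threshold(v), knee_oracle(v))
    expect_true(plateau_threshold(v) %in% v)   # always an element
  }
  expect_equal(plateau_threshold(rep(0.4, 10)), 0.4)  # constant fallback
  expect_equal(plateau_threshold(c(0.9, 0.2)), 0.2)   # two-value fallback
  expect_error(plateau_threshold(numeric(0)), "empty")
})

test_that("fst_outliers recovers a constructed divergent region", {
  set.seed(31)
  n <- 20
  p_bg <- runif(180, 0.3, 0.7)
  # background: same frequency in both pools; region: near-fixed difference
  calls1 <- matrix(rbinom(n * 180, 2, rep(p_bg, each = n)), nrow = n)
  calls2 <- matrix(rbinom(n * 180, 2, rep(p_bg, each = n)), nrow = n)
  reg1 <- matrix(rbinom(n * 5, 2, 0.01), nrow = n)
  reg2 <- matrix(rbinom(n * 5, 2, 0.99), nrow = n)
  pos_bg <- sort(sample(setdiff(1:9000000, 4500000:4600000), 180))
  pos_rg <- seq(4500000, 4540000, by = 10000)
  ord <- order(c(pos_bg, pos_rg))
  calls <- cbind(rbind(calls1, calls2), rbind(reg1, reg2))[, ord]
  gm <- quick_gm(calls, groups = rep(c("p1", "p2"), each = n),
                 pos = c(pos_bg, pos_rg)[ord])
  region_ids <- gm$sites$snp_id[gm$sites$pos %in% pos_rg]
  o <- fst_outliers(gm, "p1", "p2", window_bp = 900000L, step_bp = 10000L)
  # the whole region is recovered; at most one window-sharing neighbour
  # may ride along at the knee boundary
  expect_true(all(region_ids %in% o$members))
  expect_lte(length(setdiff(o$members, region_ids)), 1L)
  fst <- site_fst_wc(gm, "p1", "p2")
  top <- fst$snp_id[which.max(fst$theta)]
  expect_true(top %in% o$members)
  expect_gte(min(o$scores[region_ids]), max(0.9, o$scores[[top]] - 0.1))
  expect_true(all(vapply(o$method_tags, identical, logical(1),
                         "fst_window")))
  # same individuals on both sides: no positive differentiation is flagged
  gm_same <- quick_gm(cbind(rbind(calls1, calls1)),
                      groups = rep(c("p1", "p2"), each = n),
                      pos = pos_bg)
  o2 <- fst_outliers(gm_same, "p1", "p2")
  expect_lte(length(o2$members), 180 * 0.10)
  if (length(o2$members)) expect_true(all(o2$scores <= 0))
})

test_that("SNPs in overlapping selected windows are counted once", {
  # two strong sites 10 kb apart share many 900-kb windows
  n <- 10
  calls <- cbind(c(rep(0L, n), rep(2L, n)), c(rep(0L, n), rep(2L, n)))
  gm <- quick_gm(calls, groups = rep(c("p1", "p2"), each = n),
                 pos = c(5000000L, 5010000L))
  o <- fst_outliers(gm, "p1", "p2")
  expect_equal(sort(o$members), sort(unique(o$members)))
  expect_lte(length(o$members), 2L)
})

test_that("external outlier import honours the FDR threshold", {
  d <- withr::local_tempdir()
  f <- file.path(d, "bs_fst.txt")
  writeLines(c("  prob log10(PO)  qval alpha fst",
               "1 0.91 1.2 0.040 0.5 0.21",
               "2 0.50 0.1 0.060 0.1 0.05",
               "3 0.99 2.0 0.001 0.9 0.40"), f)
  ids <- c("snpA", "snpB", "snpC")
  o <- import_external(f, snp_ids = ids, q_threshold = 0.05,
                       comparison = "UK-HS")
  expect_setequal(o$members, c("snpA", "snpC"))   # 0.04 in, 0.06 out
  expect_equal(o$scores[["snpA"]], 0.21)
  expect_true(all(vapply(o$method_tags, identical, logical(1), "external")))
  writeLines(c("prob qval", "1 0.01 extra tokens here"), f)
  expect_error(import_external(f, ids), "line 2")
  writeLines(c("prob alpha fst", "1 0.9 0.1 0.2"), f)
  expect_error(import_external(f, ids), "q-value")
  writeLines(c("prob qval", "9 0.9 0.01"), f)
  expect_error(import_external(f, c("a", "b")), "mapping")
})

test_that("pooling outlier sets merges members, tags and scores", {
  mk <- function(ids, scores, tag, cmp = "UK-HS")
    outlier_set(cmp, ids, stats::setNames(scores, ids),
                stats::setNames(rep(list(tag), length(ids)), ids))
  a <- mk(c("s1", "s2", "s3"), c(0.5, 0.6, 0.7), "fst_window")
  b <- mk(c("s3", "s4", "s5", "s6"), c(0.9, 0.2, 0.3, 0.4), "external")
  ab <- pool_outliers(a, b)
  expect_equal(length(ab$members), 6L)
  expect_setequal(ab$method_tags[["s3"]], c("external", "fst_window"))
  expect_equal(ab$scores[["s3"]], 0.7)  # window statistic wins
  # pooling with an empty set is the identity
  e <- outlier_set("UK-HS")
  ae <- pool_outliers(a, e)
  expect_setequal(ae$members, a$members)
  expect_equal(ae$scores[a$members], a$scores[a$members])
  expect_error(pool_outliers(a, mk("x", 1, "external", cmp = "AUe-HS")),
               "mismatched")
})
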