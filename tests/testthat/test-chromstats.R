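test_that("chromosome classes follow the 20-Mb rule with Z override", {
  cm <- data.frame(name = c("c1", "c2", "cZ", "c20"),
                   length = c(25e6, 5e6, 8e6, 20e6))
  cls <- assign_chrom_class(cm, z_names = "cZ")
  expect_equal(unname(cls[c("c1", "c2", "cZ")]), c("macro", "micro", "Z"))
  expect_equal(unname(cls[["c20"]]), "micro")   # strict > at the threshold
  expect_error(assign_chrom_class(cm, z_names = "missing"), "absent")
  expect_error(assign_chrom_class(data.frame(name = "x", length = -1)),
               "positive")
})

test_that("enrichment chi-square matches the hand formula on a 4x3 table", {
  counts <- matrix(c(5, 3, 2,
                     8, 6, 4,
                     30, 20, 10,
                     400, 300, 200), nrow = 4, byrow = TRUE)
  groups <- rep(c("divergent", "parallel", "other_selected",
                  "not_selected"), times = rowSums(counts))
  classes <- unlist(lapply(1:4, function(i)
    rep(c("macro", "micro", "Z"), times = counts[i, ])))
  ids <- sprintf("s%04d", seq_along(groups))
  res <- suppressWarnings(                      # small expected cells
    enrichment_chisq(stats::setNames(groups, ids),
                     stats::setNames(classes, ids)))
  # direct transcription of sum (obs - exp)^2 / exp
  exp_tab <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  expect_equal(res$chi2, sum((counts - exp_tab)^2 / exp_tab))
  expect_equal(res$df, 6L)
  expect_equal(res$residuals,
               (counts - exp_tab) / sqrt(exp_tab), ignore_attr = TRUE)
  expect_equal(sum(res$contributions), 1)
  # margins: sum of residual * sqrt(exp) over any row is zero
  expect_equal(max(abs(rowSums(res$residuals * sqrt(exp_tab)))), 0,
               tolerance = 1e-9)
  # permutation invariance
  perm <- sample(seq_along(groups))
  res2 <- suppressWarnings(
    enrichment_chisq(stats::setNames(groups[perm], ids[perm]),
                     stats::setNames(classes[perm], ids[perm])))
  expect_equal(res2$chi2, res$chi2)
})

test_that("identical class proportions give a zero statistic", {
  groups <- rep(c("divergent", "parallel", "other_selected",
                  "not_selected"), each = 30)
  classes <- rep(rep(c("macro", "micro", "Z"), each = 10), times = 4)
  ids <- sprintf("s%03d", seq_along(groups))
  res <- suppressWarnings(
    enrichment_chisq(stats::setNames(groups, ids),
                     stats::setNames(classes, ids)))
  expect_equal(res$chi2, 0)
  expect_true(all(res$residuals == 0))
})

test_that("empty groupings collapse with a warning", {
  groups <- rep(c("divergent", "not_selected"), each = 40)
  classes <- rep(rep(c("macro", "micro"), each = 20), 2)
  ids <- sprintf("s%03d", seq_along(groups))
  expect_warning(
    res <- enrichment_chisq(stats::setNames(groups, ids),
                            stats::setNames(classes, ids)),
    "collapsing")
  expect_equal(dim(res$table), c(2L, 2L))
  expect_equal(res$df, 1L)
})

test_that("hemizygous Z coding separates the sexes", {
  set.seed(12)
  n_auto <- 150; n_z <- 150; n_ind <- 30
  p_a <- runif(n_auto, 0.2, 0.8); p_z <- runif(n_z, 0.2, 0.8)
  auto <- matrix(rbinom(n_ind * n_auto, 2, rep(p_a, each = n_ind)), n_ind)
  z <- matrix(rbinom(n_ind * n_z, 2, rep(p_z, each = n_ind)), n_ind)
  female <- seq_len(n_ind) <= 15
  z[female, ] <- 2L * matrix(rbinom(15 * n_z, 1, rep(p_z, each = 15)), 15)
  calls <- cbind(auto, z)
  gm <- genotype_matrix(
    calls,
    data.frame(snp_id = sprintf("s%03d", 1:(n_auto + n_z)),
               scaffold = rep(c("a1", "zz"), c(n_auto, n_z)),
               pos = c(seq_len(n_auto), seq_len(n_z)) * 1000L,
               ref = "A", alt = "G", stringsAsFactors = FALSE),
    data.frame(id = sprintf("i%02d", 1:n_ind), group = "g",
               stringsAsFactors = FALSE))
  classmap <- c(a1 = "macro", zz = "Z")
  sx <- infer_sex(gm, classmap, delta = 0.3)
  expect_equal(sx$call, rep(c("female", "male"), each = 15))
  expect_true(all(sx$F_Z[1:15] - sx$F_auto[1:15] > 0.3))
  # too few called Z sites -> unknown
  gm2 <- gm
  gm2$calls[1, (n_auto + 4):(n_auto + n_z)] <- NA   # 3 Z calls left
  expect_equal(infer_sex(gm2, classmap)$call[1], "unknown")
  expect_error(infer_sex(gm, c(a1 = "macro", zz = "micro")), "no Z")
})

test_that("interaction ANOVA reproduces the balanced closed form", {
  set.seed(3)
  n_cell <- 25
  means <- c(aa = 0.7, ab = 0.8, ba = 0.75, bb = 0.95)
  loc <- rep(rep(c("autosome", "Z"), each = 2 * n_cell))
  selc <- rep(rep(c("no", "yes"), each = n_cell), 2)
  y <- rnorm(4 * n_cell, rep(means, each = n_cell), 0.05)
  got <- interaction_anova(y, loc, selc)
  # textbook closed form for the balanced 2x2 interaction
  cellm <- tapply(y, list(loc, selc), mean)
  ss_int <- n_cell *
    (cellm[1, 1] - cellm[1, 2] - cellm[2, 1] + cellm[2, 2])^2 / 4
  sse <- sum((y - cellm[cbind(loc, selc)])^2)
  expect_equal(got$F, ss_int / (sse / (4 * n_cell - 4)), tolerance = 1e-9)
  expect_equal(got$df1, 1L)
  expect_equal(got$df2, 4 * n_cell - 4)       # df2 = N - 4
  expect_lt(got$p, 0.01)                      # a real interaction is found
  # matches R's own model-comparison F as an extra cross-check
  av <- stats::anova(stats::lm(y ~ factor(loc) * factor(selc)))
  expect_equal(got$F, av["factor(loc):factor(selc)", "F value"])
  expect_error(interaction_anova(y, rep("Z", length(y)), selc),
               "two observed levels")
})
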