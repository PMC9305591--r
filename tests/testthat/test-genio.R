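make_vcf <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  f <- file.path(dir, "x.vcf")
  writeLines(lines, f)
  f
}

vcf_header <- c(
  "##fileformat=VCFv4.2",
  "##contig=<ID=sc1,length=1000000>",
  paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "indA", "indB"), collapse = "\t"))

test_that("read_vcf matches a hand transcription of a small VCF", {
  f <- make_vcf(c(vcf_header,
    "sc1\t100\ts1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1",
    "sc1\t200\ts2\tC\tT\t.\tPASS\t.\tGT\t1/1\t./.",
    "sc1\t300\ts3\tG\tA\t.\tPASS\t.\tGT\t1|0\t1/1"))
  pm <- file.path(dirname(f), "pm.tsv")
  writeLines(c("indA\tg1", "indB\tg2"), pm)
  gm <- read_vcf(f, pm)
  expect_equal(unname(gm$calls),
               matrix(c(0L, 1L, 2L, NA, 1L, 2L), nrow = 2))
  expect_equal(gm$sites$snp_id, c("s1", "s2", "s3"))
  expect_equal(gm$sites$pos, c(100L, 200L, 300L))
  expect_equal(gm$samples$group, c("g1", "g2"))
})

test_that("header-only VCF yields zero sites with popmap samples", {
  f <- make_vcf(vcf_header)
  pm <- file.path(dirname(f), "pm.tsv")
  writeLines(c("indA\tg1", "indB\tg2"), pm)
  gm <- read_vcf(f, pm)
  expect_equal(n_sites(gm), 0L)
  expect_equal(gm$samples$id, c("indA", "indB"))
})

test_that("multiallelic and non-SNP records are skipped, absent samples error", {
  f <- make_vcf(c(vcf_header,
    "sc1\t100\ts1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1",
    "sc1\t200\ts2\tC\tT,G\t.\tPASS\t.\tGT\t1/1\t0/0",
    "sc1\t300\ts3\tGA\tG\t.\tPASS\t.\tGT\t0/0\t0/0"))
  pm <- file.path(dirname(f), "pm.tsv")
  writeLines(c("indA\tg1", "indB\tg2"), pm)
  expect_message(gm <- read_vcf(f, pm), "skipped 2")
  expect_equal(gm$sites$snp_id, "s1")
  writeLines("indA\tg1", pm)
  expect_error(read_vcf(f, pm), "indB")
})

test_that("write_fixture then read_vcf is the identity", {
  sim <- simulate_invasion(sim_config(seed = 21L, n_loci_neutral = 120L,
                                      n_loci_parallel = 3L,
                                      n_loci_divergent = 3L))
  d <- withr::local_tempdir()
  p <- write_fixture(sim$gm, sim$truth, d)
  gm2 <- read_vcf(p[["vcf"]], p[["popmap"]])
  expect_identical(gm2$calls, sim$gm$calls)
  expect_identical(gm2$sites, sim$gm$sites)
  expect_identical(gm2$samples$group, sim$gm$samples$group)
  truth_tab <- utils::read.table(p[["truth_loci"]], header = TRUE,
                                 sep = "\t", stringsAsFactors = FALSE)
  expect_equal(nrow(truth_tab), n_sites(sim$gm))
  cm <- read_chrommap(p[["chrommap"]])
  expect_equal(cm$name, sim$truth$scaffolds$name)
})

test_that("HWE exact test matches hand-enumerated configurations", {
  # (1,0,1): het in {0,2} with weights 2 and 4 -> p(obs) = 1/3
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3)
  expect_equal(hwe_exact_test(5, 0, 0), 1)   # monomorphic
  p50 <- hwe_exact_test(0, 50, 0)
  expect_equal(p50, hwe_oracle(0, 50, 0), tolerance = 1e-10)
  expect_lt(p50, 0.001)
  expect_error(hwe_exact_test(-1, 2, 0), ">= 0")
  expect_error(hwe_exact_test(0, 0, 0), "at least one")
})

test_that("filter_sites applies the missingness, MAF and HWE rules", {
  calls <- cbind(
    c(rep(0L, 8), rep(1L, 8), rep(NA, 4)),  # call rate 0.8 -> missingness
    c(rep(0L, 20)),                         # MAF 0 -> MAF rule
    c(rep(0L, 10), rep(2L, 10)),            # HWE p << 0.001 -> HWE rule
    c(rep(0L, 12), rep(1L, 6), 2L, 2L))     # passes all three
  gm <- quick_gm(calls, groups = rep("g", 20))
  spec <- filter_spec(max_missing_fraction = 0.10, maf_min = 0.025,
                      hwe_min_p = 0.001)
  expect_lt(hwe_exact_test(10, 0, 10), 0.001)
  out <- suppressMessages(filter_sites(gm, spec))
  expect_equal(out$sites$snp_id, "snp0004")
  # HWE switch keeps the fixed-difference-style site
  out2 <- suppressMessages(filter_sites(gm, spec, use_hwe = FALSE))
  expect_setequal(out2$sites$snp_id, c("snp0003", "snp0004"))
  # idempotence
  again <- suppressMessages(filter_sites(out, spec))
  expect_identical(again$calls, out$calls)
})

test_that("MAF boundary: pooled minor allele frequency below 2.5% is removed", {
  # 20 individuals, 1 alt allele in 40 -> MAF 0.025 kept; 0 alt removed
  calls <- cbind(c(1L, rep(0L, 19)), rep(0L, 20), c(2L, 1L, rep(0L, 18)))
  gm <- quick_gm(calls, groups = rep("g", 20))
  expect_equal(unname(maf(gm)), c(0.025, 0, 0.075))
  out <- suppressMessages(filter_sites(gm, filter_spec(), use_hwe = FALSE))
  expect_setequal(out$sites$snp_id, c("snp0001", "snp0003"))
})

test_that("comparison_subset enforces per-pool call floors and MAF", {
  set.seed(42)
  n_hist <- 10; n_cont <- 12
  calls <- matrix(1L, n_hist + n_cont, 3)
  calls[, 1] <- c(rep(NA, 6), rep(0L, 4), rbinom(n_cont, 2, 0.5))  # 4/10 hist
  calls[, 2] <- c(rep(c(0L, NA), 5), rbinom(n_cont, 2, 0.5))       # 5/10 hist
  calls[, 3] <- c(rep(0L, n_hist), rep(0L, n_cont))                # MAF 0
  gm <- quick_gm(calls, groups = rep(c("HS", "CT"), c(n_hist, n_cont)))
  out <- suppressMessages(
    comparison_subset(gm, "HS", "CT", min_called_a = 5, min_called_b = 5,
                      maf_min = 0.025))
  expect_equal(out$sites$snp_id, "snp0002")
  expect_setequal(out$samples$group, c("HS", "CT"))
  expect_lte(n_sites(out), n_sites(gm))
  expect_error(comparison_subset(gm, "HS", "HS"), "overlapping")
  expect_error(comparison_subset(gm, "HS", "nope"), "unknown group")
})
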