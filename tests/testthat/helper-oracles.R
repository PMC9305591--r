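# Independent oracles, written as literal transcriptions of the reference
# formulas with generic r and scalar loops, deliberately not sharing code
# with the package implementation.

# Weir & Cockerham (1984) variance components from per-population genotype
# vectors (values 0/1/2, NA = missing).
wc_oracle <- function(geno_list) {
  r <- length(geno_list)
  n <- p <- h <- numeric(r)
  for (i in seq_len(r)) {
    g <- geno_list[[i]][!is.na(geno_list[[i]])]
    n[i] <- length(g)
    p[i] <- sum(g) / (2 * length(g))
    h[i] <- sum(g == 1) / length(g)
  }
  nbar <- sum(n) / r
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc,
       theta = if (a + b + cc > 0) a / (a + b + cc) else NA_real_)
}

# Exact conditional HWE probabilities by full enumeration with plain
# factorials (valid for n <= 170).
hwe_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * n - nA
  hets <- seq(nA %% 2, min(nA, na), by = 2)
  w <- vapply(hets, function(h)
    factorial(n) / (factorial((nA - h) / 2) * factorial(h) *
                    factorial((na - h) / 2)) * 2^h, numeric(1))
  prob <- w / sum(w)
  p_obs <- prob[hets == nAa]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-12)]))
}

# A random two-population toy site: genotype vectors with missingness.
random_site <- function(n1 = sample(2:12, 1), n2 = sample(2:12, 1)) {
  p <- runif(1, 0.05, 0.95)
  g1 <- rbinom(n1, 2, p)
  g2 <- rbinom(n2, 2, runif(1, 0.05, 0.95))
  if (n1 > 3) g1[sample(n1, 1)] <- NA
  list(g1 = g1, g2 = g2)
}

# Build a two-group genotype matrix from a list of per-site genotype pairs.
gm_from_sites <- function(sites, scaffold = "s1", spacing = 1000L) {
  n1 <- length(sites[[1]]$g1)
  n2 <- length(sites[[1]]$g2)
  calls <- vapply(sites, function(s) c(s$g1, s$g2), numeric(n1 + n2))
  meta <- data.frame(
    snp_id = sprintf("snp%04d", seq_along(sites)),
    scaffold = scaffold,
    pos = seq_along(sites) * spacing,
    ref = "A", alt = "G", stringsAsFactors = FALSE)
  samples <- data.frame(
    id = sprintf("i%03d", seq_len(n1 + n2)),
    group = rep(c("p1", "p2"), c(n1, n2)), stringsAsFactors = FALSE)
  genotype_matrix(calls, meta, samples)
}

# Small helper: genotype matrix from an explicit call matrix.
quick_gm <- function(calls, groups, scaffold = "s1",
                     pos = seq_len(ncol(calls)) * 1000L) {
  genotype_matrix(
    calls,
    data.frame(snp_id = sprintf("snp%04d", seq_len(ncol(calls))),
               scaffold = scaffold, pos = as.integer(pos),
               ref = "A", alt = "G", stringsAsFactors = FALSE),
    data.frame(id = sprintf("i%03d", seq_len(nrow(calls))),
               group = groups, stringsAsFactors = FALSE))
}
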