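#' Default scaffold layout for the simulator
#'
#' An avian-style karyotype: ten macrochromosomes (> 20 Mb), twelve
#' microchromosomes, and a single Z sex chromosome, totalling ~1.08 Gb —
#' the scale of a songbird assembly — so that a few thousand
#' reduced-representation SNPs give the sparse site density (a few
#' variants per 900-kb window) typical of DArTseq/RADseq panels.
#'
#' @return `data.frame` with columns `name`, `length`, `class`.
#' @export
default_scaffolds <- function() {
  data.frame(
    name = c(paste0("scaf_ma", 1:10), paste0("scaf_mi", 1:12), "scaf_Z"),
    length = c(200e6, 155e6, 120e6, 90e6, 75e6, 65e6, 55e6, 45e6, 35e6,
               25e6,
               18e6, 16e6, 15e6, 14e6, 13e6, 12e6, 11e6, 10e6, 9e6, 8e6,
               7e6, 6e6,
               75e6),
    class = c(rep("macro", 10), rep("micro", 12), "Z"),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Parameters of the forward Wright-Fisher invasion simulator. The
#' demography mirrors a two-continent invasion sampled at two time
#' points: an ancestral deme is sampled at generation 0 (the historical,
#' museum-era sample), after which a native lineage and two independently
#' founded invasive lineages evolve for `generations` generations under
#' genic selection and binomial drift before contemporary sampling.
#'
#' Selection regimes: `parallel` loci experience `s_parallel` in the
#' native and both invasive demes; `divergent` (invasive) loci experience
#' `s_divergent` in the two invasive demes only; `divergent_native` loci
#' experience `s_divergent` in the native deme only; `neutral` loci drift.
#'
#' @param seed Integer RNG seed. The stream is partitioned per stage
#'   (demography / genotype sampling / missingness) so that toggling
#'   missingness does not perturb genotypes.
#' @param n_loci_neutral,n_loci_parallel,n_loci_divergent,n_loci_divergent_native
#'   Locus counts per selection regime (`n_loci_divergent` are the
#'   invasive-divergent loci).
#' @param scaffolds `data.frame` with `name`, `length` (bp) and `class`
#'   (one of `"macro"`, `"micro"`, `"Z"`).
#' @param generations Generations between the historical and contemporary
#'   samples. Default 50, i.e. roughly 150 years at a ~3-year songbird
#'   generation time.
#' @param Ne_ancestral,Ne_native,Ne_invasive Effective sizes (diploid
#'   individuals) of the ancestral/native and invasive demes.
#' @param founder_size_east,founder_size_south Diploid founder counts of
#'   the two invasive demes; each is founded by an independent binomial
#'   draw of `2 * founder_size` alleles from the ancestral deme.
#' @param s_parallel,s_divergent Genic selection coefficients per
#'   generation (>= 0); allele-frequency update `p' = p(1+s)/(1+ps)`
#'   before drift.
#' @param sample_sizes Named integer vector of individuals per sampling
#'   group. Defaults to the study design: one historical group (`HS`),
#'   three contemporary native groups (`MW`, `NC`, `AW`), and two
#'   contemporary invasive groups (`OR` east, `MV` south).
#' @param miss_hist,miss_contemp Per-call missingness probabilities for
#'   historical and contemporary individuals; the historical default is
#'   high because degraded museum DNA yields far more missing data.
#' @param error_rate Per-call allele-flip probability.
#' @param ancestral_freq_law Founding allele-frequency distribution:
#'   `c(shape1, shape2, lower, upper)` of a truncated Beta. The default
#'   Beta(0.8, 0.8) on \[0.05, 0.95\] gives a realistic U-shaped folded
#'   spectrum while guaranteeing polymorphism at founding.
#' @param burnin Drift generations in the ancestral deme before the
#'   historical sample is taken.
#' @param substructure_generations Extra drift generations applied to an
#'   independent replicate of the native deme from which the third native
#'   sampling group is drawn, emulating weak native-range substructure.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_loci_neutral = 5000L,
                       n_loci_parallel = 20L,
                       n_loci_divergent = 20L,
                       n_loci_divergent_native = 0L,
                       scaffolds = default_scaffolds(),
                       generations = 50L,
                       Ne_ancestral = 10000L,
                       Ne_native = 10000L,
                       Ne_invasive = 5000L,
                       founder_size_east = 200L,
                       founder_size_south = 200L,
                       s_parallel = 0.1,
                       s_divergent = 0.1,
                       sample_sizes = c(HS = 10L, MW = 15L, NC = 15L,
                                        AW = 15L, OR = 13L, MV = 15L),
                       miss_hist = 0.5,
                       miss_contemp = 0.05,
                       error_rate = 0.001,
                       ancestral_freq_law = c(shape1 = 0.8, shape2 = 0.8,
                                              lower = 0.05, upper = 0.95),
                       burnin = 10L,
                       substructure_generations = 5L) {
  cfg <- list(seed = as.integer(seed),
              n_loci_neutral = as.integer(n_loci_neutral),
              n_loci_parallel = as.integer(n_loci_parallel),
              n_loci_divergent = as.integer(n_loci_divergent),
              n_loci_divergent_native = as.integer(n_loci_divergent_native),
              scaffolds = scaffolds,
              generations = as.integer(generations),
              Ne_ancestral = as.integer(Ne_ancestral),
              Ne_native = as.integer(Ne_native),
              Ne_invasive = as.integer(Ne_invasive),
              founder_size_east = as.integer(founder_size_east),
              founder_size_south = as.integer(founder_size_south),
              s_parallel = s_parallel,
              s_divergent = s_divergent,
              sample_sizes = sample_sizes,
              miss_hist = miss_hist,
              miss_contemp = miss_contemp,
              error_rate = error_rate,
              ancestral_freq_law = ancestral_freq_law,
              burnin = as.integer(burnin),
              substructure_generations = as.integer(substructure_generations))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_loci_neutral, cfg$n_loci_parallel, cfg$n_loci_divergent,
              cfg$n_loci_divergent_native, cfg$generations, cfg$burnin,
              cfg$substructure_generations, cfg$Ne_ancestral, cfg$Ne_native,
              cfg$Ne_invasive, cfg$founder_size_east, cfg$founder_size_south)
  if (any(counts < 0) || any(is.na(counts)))
    stop("counts and sizes must be non-negative")
  if (sum(cfg$n_loci_neutral, cfg$n_loci_parallel, cfg$n_loci_divergent,
          cfg$n_loci_divergent_native) < 1L)
    stop("at least one locus is required")
  probs <- c(cfg$miss_hist, cfg$miss_contemp, cfg$error_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$s_parallel < 0 || cfg$s_divergent < 0)
    stop("selection coefficients must be >= 0")
  sc <- cfg$scaffolds
  if (!all(c("name", "length", "class") %in% names(sc)))
    stop("scaffolds need columns name, length, class")
  if (any(sc$length <= 0)) stop("scaffold lengths must be positive")
  if (!all(sc$class %in% c("macro", "micro", "Z")))
    stop("scaffold class must be one of macro, micro, Z")
  req <- c("HS", "MW", "NC", "AW", "OR", "MV")
  miss <- setdiff(req, names(cfg$sample_sizes))
  if (length(miss))
    stop("sample_sizes missing group(s): ", paste(miss, collapse = ", "))
  if (any(cfg$sample_sizes[req] < 1))
    stop("zero sample size for required group: ",
         paste(req[cfg$sample_sizes[req] < 1], collapse = ", "))
  invisible(cfg)
}

# Deterministic genic-selection allele frequency update.
wf_select <- function(p, s) p * (1 + s) / (1 + p * s)

# One generation of binomial drift at diploid size Ne.
wf_drift <- function(p, Ne) stats::rbinom(length(p), 2L * Ne, p) / (2 * Ne)

#' Run the Wright-Fisher invasion simulation
#'
#' Simulates the demography described in [sim_config()], draws genotypes
#' for the six sampling groups, and applies group-specific missingness
#' and per-call allele-flip error. Z-linked calls of female individuals
#' are drawn haploid and recorded as the corresponding homozygote
#' (hemizygous ZW coding); error flips on those calls preserve
#' homozygosity.
#'
#' @param config A `sim_config`.
#' @return A list with elements `gm` (a [genotype_matrix()]) and `truth`
#'   (a `truth_set`: per-locus regime, per-deme allele-frequency
#'   trajectories, per-sample sex and group, and the scaffold table).
#' @export
simulate_invasion <- function(config) {
  validate_sim_config(config)
  cfg <- config
  n_loci <- cfg$n_loci_neutral + cfg$n_loci_parallel + cfg$n_loci_divergent +
    cfg$n_loci_divergent_native

  set.seed(cfg$seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 3L)

  ## ---- stage 1: demography -------------------------------------------
  set.seed(stage_seeds[1L])

  # locus layout: placement proportional to scaffold length
  sc <- cfg$scaffolds
  scaf_idx <- sample.int(nrow(sc), n_loci, replace = TRUE,
                         prob = sc$length / sum(sc$length))
  pos <- floor(stats::runif(n_loci, min = 1, max = sc$length[scaf_idx])) + 0
  sites <- data.frame(snp_id = "", scaffold = sc$name[scaf_idx],
                      pos = as.integer(pos), ref = "A", alt = "G",
                      stringsAsFactors = FALSE)
  ord <- order(match(sites$scaffold, sc$name), sites$pos)
  sites <- sites[ord, , drop = FALSE]
  # de-duplicate positions within scaffold by nudging forward
  for (s in unique(sites$scaffold)) {
    i <- which(sites$scaffold == s)
    p <- sites$pos[i]
    while (any(d <- duplicated(p))) p[d] <- p[d] + 1L
    sites$pos[i] <- sort(p)
  }
  sites$snp_id <- sprintf("snp_%05d", seq_len(n_loci))

  regime <- sample(rep(c("neutral", "parallel", "divergent_invasive",
                         "divergent_native"),
                       times = c(cfg$n_loci_neutral, cfg$n_loci_parallel,
                                 cfg$n_loci_divergent,
                                 cfg$n_loci_divergent_native)))
  names(regime) <- sites$snp_id

  # founding frequencies: truncated Beta
  law <- cfg$ancestral_freq_law
  lo <- stats::pbeta(law[["lower"]], law[["shape1"]], law[["shape2"]])
  hi <- stats::pbeta(law[["upper"]], law[["shape1"]], law[["shape2"]])
  p0 <- stats::qbeta(stats::runif(n_loci, lo, hi),
                     law[["shape1"]], law[["shape2"]])
  # Selection acts on standing variation: the favoured (alternate) allele
  # starts as the minor allele, so a sustained frequency shift is possible
  # at every selected locus.
  is_sel <- regime != "neutral"
  p0[is_sel] <- pmin(p0[is_sel], 1 - p0[is_sel])

  # ancestral burn-in (drift only)
  p_anc <- p0
  for (g in seq_len(cfg$burnin)) p_anc <- wf_drift(p_anc, cfg$Ne_ancestral)

  # selection coefficient per locus and deme
  s_native <- ifelse(regime == "parallel", cfg$s_parallel,
                     ifelse(regime == "divergent_native", cfg$s_divergent, 0))
  s_invasive <- ifelse(regime == "parallel", cfg$s_parallel,
                       ifelse(regime == "divergent_invasive",
                              cfg$s_divergent, 0))

  founder_draw <- function(founder_size) {
    stats::rbinom(n_loci, 2L * founder_size, p_anc) / (2 * founder_size)
  }
  traj <- list(
    native = matrix(NA_real_, cfg$generations + 1L, n_loci),
    invasive_east = matrix(NA_real_, cfg$generations + 1L, n_loci),
    invasive_south = matrix(NA_real_, cfg$generations + 1L, n_loci)
  )
  p_nat <- p_anc
  p_east <- founder_draw(cfg$founder_size_east)
  p_south <- founder_draw(cfg$founder_size_south)
  traj$native[1L, ] <- p_nat
  traj$invasive_east[1L, ] <- p_east
  traj$invasive_south[1L, ] <- p_south
  for (g in seq_len(cfg$generations)) {
    p_nat <- wf_drift(wf_select(p_nat, s_native), cfg$Ne_native)
    p_east <- wf_drift(wf_select(p_east, s_invasive), cfg$Ne_invasive)
    p_south <- wf_drift(wf_select(p_south, s_invasive), cfg$Ne_invasive)
    traj$native[g + 1L, ] <- p_nat
    traj$invasive_east[g + 1L, ] <- p_east
    traj$invasive_south[g + 1L, ] <- p_south
  }
  # independent drift replicate of the native deme (weak substructure)
  p_nat_rep <- p_nat
  for (g in seq_len(cfg$substructure_generations))
    p_nat_rep <- wf_drift(p_nat_rep, cfg$Ne_native)

  ## ---- stage 2: genotype sampling ------------------------------------
  set.seed(stage_seeds[2L])
  groups <- c("HS", "MW", "NC", "AW", "OR", "MV")
  deme_freq <- list(HS = p_anc, MW = p_nat, NC = p_nat, AW = p_nat_rep,
                    OR = p_east, MV = p_south)
  n_by_group <- as.integer(cfg$sample_sizes[groups])
  ids <- unlist(lapply(seq_along(groups), function(i)
    sprintf("%s_%02d", groups[i], seq_len(n_by_group[i]))))
  samples <- data.frame(id = ids,
                        group = rep(groups, n_by_group),
                        stringsAsFactors = FALSE)
  sex <- sample(c("male", "female"), nrow(samples), replace = TRUE)
  names(sex) <- samples$id

  is_z_site <- sc$class[match(sites$scaffold, sc$name)] == "Z"
  calls <- matrix(NA_integer_, nrow(samples), n_loci,
                  dimnames = list(samples$id, sites$snp_id))
  for (g in groups) {
    rows <- which(samples$group == g)
    pg <- deme_freq[[g]]
    m <- matrix(stats::rbinom(length(rows) * n_loci, 2L,
                              rep(pg, each = length(rows))),
                nrow = length(rows))
    fem <- sex[samples$id[rows]] == "female"
    if (any(fem) && any(is_z_site)) {
      nz <- sum(is_z_site)
      hap <- matrix(stats::rbinom(sum(fem) * nz, 1L,
                                  rep(pg[is_z_site], each = sum(fem))),
                    nrow = sum(fem))
      m[fem, is_z_site] <- 2L * hap
    }
    calls[rows, ] <- m
  }

  ## ---- stage 3: missingness and error --------------------------------
  set.seed(stage_seeds[3L])
  if (cfg$error_rate > 0) {
    flip <- matrix(stats::runif(length(calls)) < cfg$error_rate,
                   nrow(calls), ncol(calls))
    hemi <- (sex[rownames(calls)] == "female") %o% is_z_site
    up <- stats::runif(length(calls)) < 0.5   # direction for het flips
    idx <- which(flip & !hemi)
    if (length(idx)) {
      v <- calls[idx]
      calls[idx] <- ifelse(v == 1L, ifelse(up[idx], 0L, 2L), 1L)
    }
    idx <- which(flip & hemi)
    if (length(idx)) calls[idx] <- 2L - calls[idx]
  }
  miss_p <- ifelse(samples$group == "HS", cfg$miss_hist, cfg$miss_contemp)
  drop <- matrix(stats::runif(length(calls)), nrow(calls)) <
    matrix(miss_p, nrow(calls), ncol(calls))
  calls[drop] <- NA_integer_

  gm <- genotype_matrix(calls, sites, samples)
  truth <- structure(list(
    locus_regime = regime[gm$sites$snp_id],
    trajectories = c(list(ancestral_final = p_anc,
                          native_replicate_final = p_nat_rep), traj),
    sample_sex = sex,
    sample_group = stats::setNames(samples$group, samples$id),
    scaffolds = sc
  ), class = "truth_set")
  list(gm = gm, truth = truth)
}

#' @export
print.truth_set <- function(x, ...) {
  cat("truth_set:", length(x$locus_regime), "loci;",
      length(x$sample_sex), "individuals\n")
  print(table(x$locus_regime))
  invisible(x)
}
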