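#' Pipeline configuration
#'
#' Bundles inputs, group-role assignments, and analysis parameters for
#' [run_pipeline()]. Inputs may be given as file paths (`vcf`, `popmap`,
#' `chrommap`) or as in-memory objects (`gm`, `chrom_table`), e.g.
#' straight from [simulate_invasion()].
#'
#' @param vcf,popmap,chrommap Input file paths (see [read_vcf()],
#'   [read_chrommap()]); ignored when `gm`/`chrom_table` are supplied.
#' @param gm Optional [genotype_matrix()] used instead of reading files.
#' @param chrom_table Optional scaffold table (`name`, `length`,
#'   `class`) used instead of reading `chrommap`.
#' @param roles Named list assigning group labels to the six roles:
#'   `historical` (one label), `native` (the contemporary native labels,
#'   pooled), `invasive_east`, `invasive_south`.
#' @param external Optional named list of external outlier tables, keyed
#'   by comparison label (`"UK-HS"`, `"AUe-HS"`, `"AUs-HS"`, `"UK-AUe"`,
#'   `"UK-AUs"`); each element a list with `path` and optional
#'   `q_threshold`.
#' @param filter [filter_spec()] applied (with HWE) on the
#'   population-structure path.
#' @param min_called_hist,min_called_contemp Per-pool call-count floors
#'   for the comparison subsets (defaults 5 and 5).
#' @param window_bp,step_bp,min_sites,q Window-scan parameters.
#' @param n_boot Bootstrap replicates for pairwise multi-locus F_ST.
#' @param delta_sex Sexing threshold, see [infer_sex()].
#' @param macro_threshold_bp Macro/micro cutoff, see
#'   [assign_chrom_class()].
#' @param seed Seed for every stochastic step (the F_ST bootstrap).
#' @param outdir Optional output directory; when given, all report
#'   tables are written there as tab-separated text.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf = NULL, popmap = NULL, chrommap = NULL,
                            gm = NULL, chrom_table = NULL,
                            roles = list(historical = "HS",
                                         native = c("MW", "NC", "AW"),
                                         invasive_east = "OR",
                                         invasive_south = "MV"),
                            external = list(),
                            filter = filter_spec(),
                            min_called_hist = 5L,
                            min_called_contemp = 5L,
                            window_bp = 900000L, step_bp = 10000L,
                            min_sites = 1L, q = 0.99,
                            n_boot = 200L, delta_sex = 0.3,
                            macro_threshold_bp = 2e7,
                            seed = 1L, outdir = NULL) {
  cfg <- as.list(environment())
  req <- c("historical", "native", "invasive_east", "invasive_south")
  miss <- setdiff(req, names(roles))
  if (length(miss))
    stop("roles missing: ", paste(miss, collapse = ", "))
  all_roles <- unlist(roles[req])
  if (anyDuplicated(all_roles))
    stop("role group labels must be disjoint")
  if (is.null(gm) && (is.null(vcf) || is.null(popmap)))
    stop("either gm or vcf+popmap must be supplied")
  if (is.null(chrom_table) && is.null(chrommap))
    stop("either chrom_table or chrommap must be supplied")
  structure(cfg, class = "pipeline_config")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

outlier_table <- function(o) {
  data.frame(snp_id = o$members,
             score = unname(o$scores[o$members]),
             tags = vapply(o$method_tags[o$members], paste,
                           character(1), collapse = ";"),
             comparison = o$comparison, stringsAsFactors = FALSE)
}

#' Run the full temporal selection-scan pipeline
#'
#' Executes, in order: input reading and role validation; the
#' population-structure battery on the HWE-filtered matrix (pairwise
#' multi-locus F_ST with bootstrap significance, Nei's distance,
#' neighbour-joining tree, PCA); construction of the five pairwise
#' comparison subsets (native vs. historical, each invasive
#' subpopulation vs. historical, native vs. each invasive
#' subpopulation); the F_ST window outlier scan per comparison, pooled
#' with any imported external outlier sets; classification of outliers
#' into divergent / parallel / single-comparison categories per invasive
#' subpopulation, then pooled; and the chromosome-class statistics
#' (enrichment chi-square, bioinformatic sexing, major-allele-frequency
#' interaction ANOVA). A manifest of every parameter and seed is
#' included; the same configuration and seed reproduce the report
#' exactly.
#'
#' For the enrichment test each tested SNP receives one grouping with
#' precedence divergent > parallel > other selected > not selected (a
#' SNP can be pooled into several categories across subpopulations).
#'
#' @param config A [pipeline_config()].
#' @return A list (class `tfst_report`) with elements `structure`,
#'   `comparisons`, `outliers`, `classification`, `chromstats`, and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  gm <- if (!is.null(cfg$gm)) cfg$gm else read_vcf(cfg$vcf, cfg$popmap)
  chrom <- if (!is.null(cfg$chrom_table)) cfg$chrom_table
           else read_chrommap(cfg$chrommap)
  roles <- cfg$roles
  groups_present <- unique(gm$samples$group)
  absent <- setdiff(unlist(roles), groups_present)
  if (length(absent))
    stop("role group(s) absent from data: ", paste(absent, collapse = ", "))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }

  ## ---- population structure ------------------------------------------
  structure_rep <- stage("structure", {
    gm_struct <- filter_sites(gm, cfg$filter, use_hwe = TRUE)
    grp <- c(roles$historical, roles$native, roles$invasive_east,
             roles$invasive_south)
    ml <- multilocus_fst(gm_struct, grp, n_boot = cfg$n_boot,
                         seed = cfg$seed)
    nd <- neis_distance(gm_struct, grp)
    nwk <- if (all(is.finite(nd))) nj_tree(nd) else NA_character_
    pca <- pca_genotypes(gm_struct, k = min(2L, n_samples(gm_struct)))
    list(n_sites = n_sites(gm_struct), fst = ml$fst, fst_p = ml$p,
         neis_d = nd, tree = nwk, pca = pca)
  })

  ## ---- comparison subsets and outlier scans --------------------------
  # selection path: global floor of called historical individuals + MAF
  sel_gm <- stage("selection_file", {
    hist_rows <- group_rows(gm, roles$historical)
    called_h <- colSums(!is.na(gm$calls[hist_rows, , drop = FALSE]))
    mf <- maf(gm)
    gm_subset(gm, sites = called_h >= cfg$min_called_hist &
                !is.na(mf) & mf >= cfg$filter$maf_min)
  })
  comp_def <- list(
    "UK-HS" = list(a = roles$historical, b = roles$native,
                   min_a = cfg$min_called_hist,
                   min_b = cfg$min_called_contemp),
    "AUe-HS" = list(a = roles$historical, b = roles$invasive_east,
                    min_a = cfg$min_called_hist,
                    min_b = cfg$min_called_contemp),
    "AUs-HS" = list(a = roles$historical, b = roles$invasive_south,
                    min_a = cfg$min_called_hist,
                    min_b = cfg$min_called_contemp),
    "UK-AUe" = list(a = roles$native, b = roles$invasive_east,
                    min_a = cfg$min_called_contemp,
                    min_b = cfg$min_called_contemp),
    "UK-AUs" = list(a = roles$native, b = roles$invasive_south,
                    min_a = cfg$min_called_contemp,
                    min_b = cfg$min_called_contemp))
  comparisons <- list()
  outliers <- list()
  for (cmp in names(comp_def)) {
    d <- comp_def[[cmp]]
    sub <- stage(paste0("subset[", cmp, "]"),
                 comparison_subset(sel_gm, d$a, d$b, d$min_a, d$min_b,
                                   maf_min = cfg$filter$maf_min))
    o <- stage(paste0("fst_outliers[", cmp, "]"),
               fst_outliers(sub, d$a, d$b, window_bp = cfg$window_bp,
                            step_bp = cfg$step_bp,
                            min_sites = cfg$min_sites, q = cfg$q,
                            comparison = cmp))
    if (cmp %in% names(cfg$external)) {
      ext <- cfg$external[[cmp]]
      qt <- if (is.null(ext$q_threshold)) 0.05 else ext$q_threshold
      o <- stage(paste0("import_external[", cmp, "]"),
                 pool_outliers(o, import_external(
                   ext$path, snp_ids = sub$sites$snp_id,
                   q_threshold = qt, comparison = cmp)))
    }
    comparisons[[cmp]] <- list(n_sites = n_sites(sub),
                               snp_ids = sub$sites$snp_id)
    outliers[[cmp]] <- o
  }

  ## ---- classification ------------------------------------------------
  east <- stage("classify[east]",
                classify_pairwise(outliers[["UK-HS"]], outliers[["AUe-HS"]],
                                  outliers[["UK-AUe"]]))
  south <- stage("classify[south]",
                 classify_pairwise(outliers[["UK-HS"]], outliers[["AUs-HS"]],
                                   outliers[["UK-AUs"]]))
  pooled <- pool_subpops(east, south)
  counts <- classification_counts(pooled)

  ## ---- chromosome-class statistics -----------------------------------
  chromstats_rep <- stage("chromstats", {
    classmap <- assign_chrom_class(chrom,
                                   threshold_bp = cfg$macro_threshold_bp)
    tested <- sort(unique(unlist(lapply(comparisons, `[[`, "snp_ids"))))
    grouping <- vapply(tested, function(id) {
      cats <- pooled[[id]]
      if (is.null(cats)) "not_selected"
      else if ("divergent" %in% cats) "divergent"
      else if ("parallel" %in% cats) "parallel"
      else "other_selected"
    }, character(1))
    site_class <- stats::setNames(
      classmap[gm$sites$scaffold], gm$sites$snp_id)
    enr <- enrichment_chisq(grouping, site_class)
    sexing <- infer_sex(gm, classmap, delta = cfg$delta_sex)
    p <- alt_freq(gm)[match(tested, gm$sites$snp_id)]
    anova <- tryCatch(
      interaction_anova(
        maf = pmax(p, 1 - p),
        location = ifelse(site_class[tested] == "Z", "Z", "autosome"),
        selected = ifelse(grouping == "not_selected", "no", "yes")),
      error = function(e) {
        warning("interaction ANOVA not estimable: ", conditionMessage(e))
        list(F = NA_real_, df1 = NA_integer_, df2 = NA_integer_,
             p = NA_real_)
      })
    list(enrichment = enr, sexing = sexing, anova = anova,
         grouping = grouping)
  })

  manifest <- cfg[setdiff(names(cfg), c("gm", "chrom_table"))]
  manifest$roles <- roles
  report <- structure(list(structure = structure_rep,
                           comparisons = comparisons,
                           outliers = outliers,
                           classification = list(east = east, south = south,
                                                 pooled = pooled,
                                                 counts = counts),
                           chromstats = chromstats_rep,
                           manifest = manifest),
                      class = "tfst_report")
  if (!is.null(cfg$outdir)) write_report(report, cfg$outdir)
  report
}

#' @export
print.tfst_report <- function(x, ...) {
  cat("temporalfst report\n")
  cat("  comparisons:", paste(sprintf(
    "%s (%d sites, %d outliers)", names(x$comparisons),
    vapply(x$comparisons, `[[`, integer(1), "n_sites"),
    vapply(x$outliers, function(o) length(o$members), integer(1))),
    collapse = "; "), "\n")
  cat("  classification:",
      paste(sprintf("%s=%d", names(x$classification$counts),
                    x$classification$counts), collapse = ", "), "\n")
  e <- x$chromstats$enrichment
  cat(sprintf("  enrichment: chi2(%d) = %.2f, p = %.3g, N = %d\n",
              e$df, e$chi2, e$p, e$n))
  a <- x$chromstats$anova
  cat(sprintf("  interaction ANOVA: F(%d,%d) = %.3g, p = %.3g\n",
              a$df1, a$df2, a$F, a$p))
  invisible(x)
}

#' Write a pipeline report as tab-separated text files
#'
#' @param report A `tfst_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ot <- do.call(rbind, lapply(report$outliers, outlier_table))
  write_tsv(ot, file.path(dir, "outliers.tsv"))
  cl <- rbind(
    data.frame(snp_id = names(report$classification$east), subpop = "east",
               category = unname(report$classification$east)),
    data.frame(snp_id = names(report$classification$south), subpop = "south",
               category = unname(report$classification$south)))
  write_tsv(cl, file.path(dir, "classification.tsv"))
  pooled <- report$classification$pooled
  write_tsv(data.frame(snp_id = names(pooled),
                       categories = vapply(pooled, paste, character(1),
                                           collapse = ";")),
            file.path(dir, "classification_pooled.tsv"))
  write_tsv(data.frame(category = names(report$classification$counts),
                       n = unname(report$classification$counts)),
            file.path(dir, "classification_counts.tsv"))
  e <- report$chromstats$enrichment
  mt <- function(m) data.frame(grouping = rownames(m), as.data.frame.matrix(m))
  write_tsv(mt(e$table), file.path(dir, "enrichment_table.tsv"))
  write_tsv(mt(e$residuals), file.path(dir, "enrichment_residuals.tsv"))
  write_tsv(mt(e$contributions),
            file.path(dir, "enrichment_contributions.tsv"))
  write_tsv(report$chromstats$sexing, file.path(dir, "sexing.tsv"))
  s <- report$structure
  wm <- function(m, f) write_tsv(data.frame(group = rownames(m),
                                            as.data.frame.matrix(m)),
                                 file.path(dir, f))
  wm(s$fst, "pairwise_fst.tsv")
  wm(s$fst_p, "pairwise_fst_p.tsv")
  wm(s$neis_d, "neis_distance.tsv")
  if (!is.na(s$tree)) writeLines(s$tree, file.path(dir, "nj_tree.nwk"))
  write_tsv(data.frame(individual = rownames(s$pca$coords),
                       s$pca$coords), file.path(dir, "pca_coords.tsv"))
  a <- report$chromstats$anova
  summary_lines <- c(
    sprintf("tested_snps\t%d", e$n),
    sprintf("enrichment_chi2\t%.6g", e$chi2),
    sprintf("enrichment_df\t%d", e$df),
    sprintf("enrichment_p\t%.6g", e$p),
    sprintf("anova_F\t%.6g", a$F),
    sprintf("anova_df1\t%d", a$df1),
    sprintf("anova_df2\t%d", a$df2),
    sprintf("anova_p\t%.6g", a$p))
  writeLines(summary_lines, file.path(dir, "summary_stats.tsv"))
  m <- report$manifest
  flat <- function(v) paste(unlist(v), collapse = ",")
  writeLines(c("# run manifest",
               vapply(names(m), function(k) paste0(k, "\t", flat(m[[k]])),
                      character(1))),
             file.path(dir, "manifest.tsv"))
  invisible(dir)
}
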