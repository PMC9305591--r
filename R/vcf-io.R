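#' Read a VCF and a population map into a genotype matrix
#'
#' Parses a VCF (v4.x) with `GT` genotypes through \pkg{vcfR} and attaches
#' group labels from a two-column tab-separated population map
#' (`individual<TAB>group`). Genotypes are mapped 0/0 -> 0, 0/1 or
#' 1/0 -> 1, 1/1 -> 2 and ./. -> missing (phased separators accepted).
#' Multiallelic and non-SNP records are skipped with a message giving the
#' count.
#'
#' @param vcf Path to a VCF file.
#' @param popmap Path to the population map. Every sample in the VCF must
#'   appear in it.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(vcf, popmap) {
  pm <- read_popmap(popmap)
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  sample_ids <- colnames(v@gt)[-1L]
  if (is.null(sample_ids))  # header-only file: vcfR keeps colnames anyway
    sample_ids <- character(0)
  absent <- setdiff(sample_ids, pm$id)
  if (length(absent))
    stop("sample(s) absent from popmap: ", paste(absent, collapse = ", "))
  samples <- pm[match(sample_ids, pm$id), , drop = FALSE]

  if (nrow(fix) == 0L) {
    return(genotype_matrix(
      matrix(NA_integer_, length(sample_ids), 0L),
      data.frame(snp_id = character(0), scaffold = character(0),
                 pos = integer(0), ref = character(0), alt = character(0),
                 stringsAsFactors = FALSE),
      samples))
  }

  keep <- !is.na(fix$ALT) & !grepl(",", fix$ALT, fixed = TRUE) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L
  n_skip <- sum(!keep)
  if (n_skip > 0)
    message("read_vcf: skipped ", n_skip, " multiallelic/non-SNP record(s)")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]

  code <- function(x) {
    x <- gsub("|", "/", x, fixed = TRUE)
    out <- rep(NA_integer_, length(x))
    out[x %in% "0/0"] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x %in% "1/1"] <- 2L
    bad <- !is.na(x) & !(x %in% c("0/0", "0/1", "1/0", "1/1", "./.", "."))
    if (any(bad))
      stop("unparseable GT value(s): ",
           paste(unique(x[bad]), collapse = ", "))
    out
  }
  calls <- t(matrix(code(as.vector(gt)), nrow = nrow(gt)))  # ind x sites
  ids <- fix$ID
  if (any(is.na(ids)) || any(ids == "."))
    ids <- ifelse(is.na(ids) | ids == ".",
                  paste0(fix$CHROM, "_", fix$POS), ids)
  sites <- data.frame(snp_id = ids, scaffold = fix$CHROM,
                      pos = as.integer(fix$POS), ref = fix$REF,
                      alt = fix$ALT, stringsAsFactors = FALSE)
  genotype_matrix(calls, sites, samples)
}

#' Read a population map
#' @param path Two-column tab-separated file `individual<TAB>group`, with
#'   or without a header line.
#' @return `data.frame` with columns `id`, `group`.
#' @export
read_popmap <- function(path) {
  tb <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("id", "group"))
  if (nrow(tb) && identical(tolower(tb$id[1]), "individual"))
    tb <- tb[-1L, , drop = FALSE]
  rownames(tb) <- NULL
  tb
}

#' Read a scaffold-to-chromosome-class map
#' @param path Three-column tab-separated file
#'   `scaffold<TAB>length_bp<TAB>class`, with or without a header line.
#' @return `data.frame` with columns `name`, `length`, `class`.
#' @export
read_chrommap <- function(path) {
  tb <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("name", "length", "class"))
  if (nrow(tb) && identical(tolower(tb$name[1]), "scaffold"))
    tb <- tb[-1L, , drop = FALSE]
  tb$length <- as.numeric(tb$length)
  rownames(tb) <- NULL
  tb
}

# Serialize a genotype matrix as VCF v4.2 text (GT only).
write_vcf_gt <- function(gm, path, scaffolds = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines(paste0("##fileDate=", format(Sys.Date(), "%Y%m%d")), con)
  writeLines("##source=temporalfst", con)
  if (!is.null(scaffolds))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", scaffolds$name,
                       as.integer(scaffolds$length)), con)
  writeLines('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gm$samples$id), collapse = "\t"), con)
  if (n_sites(gm) == 0L) return(invisible(path))
  gt_code <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(n_sites(gm)), function(j) {
    g <- gm$calls[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    paste(c(gm$sites$scaffold[j], gm$sites$pos[j], gm$sites$snp_id[j],
            gm$sites$ref[j], gm$sites$alt[j], ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Write a simulated data set as plain-text fixture files
#'
#' Emits, under `dir`: `genotypes.vcf` (VCF v4.2, GT field only, contig
#' headers carrying scaffold lengths), `popmap.tsv`, `chrommap.tsv`, and
#' the ground-truth tables `truth_loci.tsv` (`snp_id<TAB>regime`) and
#' `truth_samples.tsv` (`individual<TAB>sex<TAB>group`). Reading the VCF
#' and popmap back through [read_vcf()] reproduces the genotype matrix
#' exactly.
#'
#' @param gm A non-empty [genotype_matrix()].
#' @param truth The matching `truth_set` from [simulate_invasion()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_fixture <- function(gm, truth, dir) {
  if (n_sites(gm) == 0L || n_samples(gm) == 0L)
    stop("cannot write an empty genotype matrix")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             popmap = file.path(dir, "popmap.tsv"),
             chrommap = file.path(dir, "chrommap.tsv"),
             truth_loci = file.path(dir, "truth_loci.tsv"),
             truth_samples = file.path(dir, "truth_samples.tsv"))
  write_vcf_gt(gm, paths[["vcf"]], scaffolds = truth$scaffolds)
  utils::write.table(gm$samples, paths[["popmap"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(truth$scaffolds[, c("name", "length", "class")],
                     paths[["chrommap"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(snp_id = names(truth$locus_regime),
               regime = unname(truth$locus_regime)),
    paths[["truth_loci"]], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(individual = names(truth$sample_sex),
               sex = unname(truth$sample_sex),
               group = unname(truth$sample_group[names(truth$sample_sex)])),
    paths[["truth_samples"]], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
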