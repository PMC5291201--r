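#' Write a dosage VCF
#'
#' Plain-text VCF 4.2 with GT (hard calls from rounded dosages) and DS
#' (dosage) sample fields, plus per-variant HWE p-value and imputation info
#' score in INFO. Coordinates are 1-based, the format's native convention.
#'
#' @param variants Tibble with `variant_id`, `chrom`, `pos`, `hwe_p`,
#'   `info_score`.
#' @param dosages Matrix, samples x variants; column order must match
#'   `variants`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_vcf <- function(variants, dosages, file) {
  stopifnot(nrow(variants) == ncol(dosages))
  samples <- rownames(dosages)
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", unique(variants$chrom), ">"),
    "##INFO=<ID=HWE,Number=1,Type=Float,Description=\"Hardy-Weinberg chi-square p-value\">",
    "##INFO=<ID=IMPINFO,Number=1,Type=Float,Description=\"Imputation info score\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of the alternate allele\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  gt_codes <- c("0/0", "0/1", "1/1")
  rows <- vapply(seq_len(nrow(variants)), function(i) {
    ds <- dosages[, i]
    gt <- gt_codes[pmin(pmax(round(ds), 0), 2) + 1]
    cells <- paste0(gt, ":", formatC(ds, format = "g", digits = 8))
    paste(c(variants$chrom[i], format(variants$pos[i], scientific = FALSE),
            variants$variant_id[i], "A", "G", ".", "PASS",
            sprintf("HWE=%.6g;IMPINFO=%.6g",
                    variants$hwe_p[i], variants$info_score[i]),
            "GT:DS", cells), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), file)
  invisible(file)
}

#' Read a dosage VCF
#'
#' Reads genotypes through vcfR, preferring the DS field and falling back to
#' allele counts from GT. MAF is recomputed from the dosages of the analyzed
#' sample (minor-allele folded), never taken from file metadata.
#'
#' @param file VCF path.
#' @return List with `variants` (tibble: `variant_id`, `chrom`, `pos`,
#'   `maf`, `info_score`, `hwe_p`) and `dosages` (samples x variants).
#' @export
read_vcf <- function(file) {
  vcf <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  ds <- tryCatch(
    vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE),
    error = function(e) NULL)
  if (is.null(ds) || all(is.na(ds))) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    ds <- matrix(vapply(gt, function(g) {
      sum(as.integer(strsplit(g, "[/|]")[[1]]))
    }, numeric(1)), nrow = nrow(gt), dimnames = dimnames(gt))
  }
  dosages <- t(ds)
  colnames(dosages) <- fix[, "ID"]
  hwe <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = "HWE")))
  info <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = "IMPINFO")))
  variants <- tibble(
    variant_id = unname(fix[, "ID"]),
    chrom = unname(fix[, "CHROM"]),
    pos = as.numeric(fix[, "POS"]),
    maf = dosage_maf(dosages),
    info_score = if (length(info)) info else NA_real_,
    hwe_p = if (length(hwe)) hwe else NA_real_)
  list(variants = variants, dosages = dosages)
}

#' Write / read BED3 island annotations
#'
#' BED is 0-based half-open, matching the package's internal convention, so
#' coordinates pass through unchanged.
#'
#' @param islands Tibble with `chrom`, `start`, `end` (and optional
#'   `island_id` written as the BED name column).
#' @param file Path.
#' @return The path (write) or a tibble (read).
#' @export
write_bed <- function(islands, file) {
  df <- data.frame(chrom = islands$chrom,
                   start = format(islands$start, scientific = FALSE, trim = TRUE),
                   end = format(islands$end, scientific = FALSE, trim = TRUE))
  if ("island_id" %in% names(islands)) df$name <- islands$island_id
  readr::write_tsv(df, file, col_names = FALSE)
  invisible(file)
}

#' @rdname write_bed
#' @export
read_bed <- function(file) {
  df <- readr::read_tsv(file, col_names = FALSE, show_col_types = FALSE,
                        progress = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  out <- tibble(chrom = as.character(df$chrom),
                start = as.numeric(df$start), end = as.numeric(df$end))
  if (ncol(df) >= 4) out$island_id <- as.character(df[[4]])
  out
}

#' Write a simulated fixture to standard files
#'
#' Emits the file set the pipeline consumes: a dosage VCF, a BED3 island
#' file, TSV probe manifest / methylation matrix / covariate table, a TSV
#' known-mQTL list (index SNPs implied by the scenarios) and a JSON truth
#' file. Files round-trip losslessly through [read_fixture_set()] (dosage
#' and methylation matrices to write precision).
#'
#' @param sim An `mqtl_sim` object from [simulate_mqtl_data()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_fixture_set <- function(sim, outdir) {
  stopifnot(inherits(sim, "mqtl_sim"))
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(outdir)) abort(paste0("Cannot create directory ", outdir))
  }
  p <- function(f) file.path(outdir, f)
  write_vcf(sim$variants, sim$dosages, p("genotypes.vcf"))
  write_bed(sim$islands, p("islands.bed"))
  readr::write_tsv(sim$probes, p("probes.tsv"), progress = FALSE)
  meth <- as_tibble(sim$methylation, rownames = "probe_id")
  readr::write_tsv(meth, p("methylation.tsv"), progress = FALSE)
  readr::write_tsv(sim$covariates, p("covariates.tsv"), progress = FALSE)
  readr::write_tsv(sim_known_mqtl(sim), p("known_mqtl.tsv"), progress = FALSE)
  truth <- purrr::map(seq_len(nrow(sim$truth)), function(i) {
    r <- sim$truth[i, ]
    list(probe_id = r$probe_id, island_id = r$island_id, mode = r$mode,
         variant_ids = as.list(r$variant_ids[[1]]),
         beta = as.list(r$beta[[1]]),
         index_variant = r$index_variant, index_beta = r$index_beta,
         alpha0 = r$alpha0, alpha = as.list(r$alpha[[1]]),
         noise_sd = r$noise_sd)
  })
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(outdir)
}

#' Read a fixture directory
#'
#' Inverse of [write_fixture_set()].
#'
#' @param dir Directory written by [write_fixture_set()].
#' @return List with `variants`, `dosages`, `islands`, `probes`,
#'   `methylation`, `covariates`, `known_mqtl`, `truth`.
#' @export
read_fixture_set <- function(dir) {
  p <- function(f) file.path(dir, f)
  vcf <- read_vcf(p("genotypes.vcf"))
  islands <- read_bed(p("islands.bed"))
  probes <- readr::read_tsv(p("probes.tsv"), show_col_types = FALSE,
                            progress = FALSE)
  meth_df <- readr::read_tsv(p("methylation.tsv"), show_col_types = FALSE,
                             progress = FALSE)
  meth <- as.matrix(meth_df[, -1])
  rownames(meth) <- meth_df$probe_id
  covariates <- readr::read_tsv(p("covariates.tsv"), show_col_types = FALSE,
                                progress = FALSE)
  known <- readr::read_tsv(p("known_mqtl.tsv"), show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(
                             snp_id = readr::col_character(),
                             chrom = readr::col_character(),
                             pos = readr::col_double(),
                             probe_id = readr::col_character()))
  raw <- jsonlite::fromJSON(p("truth.json"), simplifyVector = FALSE)
  truth <- bind_rows(purrr::map(raw, function(r) {
    tibble(probe_id = r$probe_id,
           island_id = if (is.null(r$island_id)) NA_character_ else r$island_id,
           mode = r$mode,
           variant_ids = list(as.character(unlist(r$variant_ids))),
           beta = list(as.numeric(unlist(r$beta))),
           index_variant = if (is.null(r$index_variant)) NA_character_ else r$index_variant,
           index_beta = r$index_beta, alpha0 = r$alpha0,
           alpha = list(as.numeric(unlist(r$alpha))),
           noise_sd = r$noise_sd)
  }))
  list(variants = vcf$variants, dosages = vcf$dosages, islands = islands,
       probes = probes, methylation = meth, covariates = covariates,
       known_mqtl = known, truth = truth)
}
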