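#' Write cohort genotypes as a plain-text VCF (v4.2, GT field)
#'
#' @param geno A `cohort_genotypes`.
#' @param path Output path (uncompressed `.vcf`).
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(geno, path) {
  gt_code <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=pubgrowth",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", geno$ids), collapse = "\t")
  )
  g <- t(geno$g)  # M x N
  body <- vapply(seq_len(nrow(g)), function(m) {
    calls <- ifelse(is.na(g[m, ]), "./.", gt_code[g[m, ] + 1L])
    paste(c(geno$variants$chrom[m], geno$variants$pos[m],
            geno$variants$id[m], geno$variants$ref[m],
            geno$variants$alt[m], ".", "PASS", ".", "GT", calls),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF into a `cohort_genotypes`
#'
#' Parses with vcfR and converts GT calls to additive dosages (alternate
#' allele count; any missing or half-missing call becomes NA). Sex is not
#' encoded in VCF, so it must be supplied (or defaults to NA).
#'
#' @param path VCF path (plain or gzipped).
#' @param sex Optional integer vector (0/1) in sample order.
#' @return A `cohort_genotypes`.
#' @export
read_cohort_vcf <- function(path, sex = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  g01 <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt))
  alt_count <- function(s) {
    a <- strsplit(s, "[/|]")[[1]]
    if (any(a == ".") || length(a) != 2) return(NA_integer_)
    sum(a != "0")
  }
  codes <- unique(as.vector(gt))
  lut <- setNames(vapply(codes, alt_count, integer(1)), codes)
  g01 <- t(matrix(lut[as.vector(gt)], nrow = nrow(gt)))
  fix <- vcfR::getFIX(v)
  variants <- tibble::tibble(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"], id = fix[, "ID"]
  )
  ids <- colnames(gt)
  if (is.null(sex)) sex <- rep(NA_integer_, length(ids))
  new_cohort_genotypes(g01, variants, ids, sex)
}

#' Write longitudinal heights as TSV
#' @param heights Tibble `id`, `sex`, `age_years`, `height_cm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_heights_tsv <- function(heights, path) {
  readr::write_tsv(heights, path)
  invisible(path)
}

#' Read longitudinal heights from TSV
#' @param path TSV with columns `id`, `sex`, `age_years`, `height_cm`.
#' @return Heights tibble.
#' @export
read_heights_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    id = readr::col_character(),
                    sex = readr::col_integer(),
                    age_years = readr::col_double(),
                    height_cm = readr::col_double()))
}

#' Write local-ancestry dosages as TSV (variants x samples)
#' @param la A `local_ancestry`.
#' @param variant_ids Variant ids for the row names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_local_ancestry_tsv <- function(la, variant_ids, path) {
  m <- t(la$dosage)
  df <- dplyr::bind_cols(tibble::tibble(variant = variant_ids),
                         tibble::as_tibble(m, .name_repair = ~ la$ids))
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read local-ancestry dosages from TSV (variants x samples)
#' @param path TSV written by [write_local_ancestry_tsv()].
#' @return A `local_ancestry` with dosage only (no haplotype labels).
#' @export
read_local_ancestry_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  ids <- setdiff(names(df), "variant")
  dosage <- t(as.matrix(df[, ids]))
  storage.mode(dosage) <- "integer"
  rownames(dosage) <- ids
  structure(list(dosage = dosage, hap1 = NULL, hap2 = NULL,
                 labels = NULL, ids = ids,
                 native_labels = c("Mapuche", "Aymara"),
                 n_switches = NULL),
            class = "local_ancestry")
}

#' Write global-ancestry proportions as TSV
#' @param q Ancestry tibble (`id` plus proportion columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ancestry_tsv <- function(q, path) {
  readr::write_tsv(q, path)
  invisible(path)
}

#' Read global-ancestry proportions from TSV
#' @param path TSV written by [write_ancestry_tsv()].
#' @return Ancestry tibble.
#' @export
read_ancestry_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write simulation ground truth as JSON
#' @param truth A `sim_truth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read simulation ground truth from JSON
#' @param path JSON written by [write_sim_truth_json()].
#' @return A `sim_truth`.
#' @export
read_sim_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$causal <- tibble::as_tibble(x$causal)
  x$effects <- tibble::as_tibble(x$effects)
  structure(x, class = "sim_truth")
}

#' Write panel allele frequencies as TSV
#' @param panel A `reference_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_tsv <- function(panel, path) {
  df <- dplyr::bind_cols(
    panel$variants,
    tibble::as_tibble(t(panel$freqs), .name_repair = ~ panel$labels),
    tibble::tibble(genetic_pos = panel$genetic_pos))
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read panel allele frequencies from TSV
#' @param path TSV written by [write_panel_tsv()].
#' @return A `reference_panel`.
#' @export
read_panel_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  meta <- c("chrom", "pos", "ref", "alt", "id", "genetic_pos")
  labels <- setdiff(names(df), meta)
  freqs <- t(as.matrix(df[, labels]))
  rownames(freqs) <- labels
  structure(list(K = length(labels), labels = labels, freqs = freqs,
                 variants = df[, c("chrom", "pos", "ref", "alt", "id")],
                 genetic_pos = df$genetic_pos, ancestral = NULL),
            class = "reference_panel")
}
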