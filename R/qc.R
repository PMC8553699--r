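#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test: given the observed allele counts, every
#' compatible heterozygote count is enumerated, each configuration's
#' conditional probability computed (hypergeometric-style, via log
#' factorials), and the P-value is the sum of probabilities not exceeding
#' that of the observed configuration. This follows the standard exact
#' formulation used by GWAS QC tools.
#'
#' @param n_hom_ref Count of reference homozygotes.
#' @param n_het Count of heterozygotes.
#' @param n_hom_alt Count of alternate homozygotes.
#' @return Two-sided exact P-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  if (any(c(n_hom_ref, n_het, n_hom_alt) < 0)) {
    stop("genotype counts must be non-negative")
  }
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0) stop("at least one genotype must be observed")
  n_a <- n_het + 2L * min(n_hom_ref, n_hom_alt)  # rarer allele count
  n_b <- 2L * n - n_a
  if (n_a == 0) return(1)
  # heterozygote counts share the parity of the rarer allele count
  hets <- seq.int(n_a %% 2L, n_a, by = 2L)
  # log P(het = h | allele counts) up to a constant:
  # n! / (hom_a! h! hom_b!) * 2^h / (2n)! * na! * nb!
  hom_a <- (n_a - hets) / 2
  hom_b <- (n_b - hets) / 2
  logp <- hets * log(2) - lfactorial(hom_a) - lfactorial(hets) -
    lfactorial(hom_b)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- match(n_het, hets)
  if (is.na(obs)) stop("observed heterozygote count incompatible with alleles")
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

genotype_counts <- function(gvec) {
  c(sum(gvec == 0L, na.rm = TRUE), sum(gvec == 1L, na.rm = TRUE),
    sum(gvec == 2L, na.rm = TRUE))
}

qc_log_row <- function(filter, axis, removed, threshold = NA_character_) {
  tibble::tibble(filter = filter, axis = axis, removed = as.integer(removed),
                 threshold = as.character(threshold))
}

subset_variants <- function(geno, keep) {
  new_cohort_genotypes(geno$g[, keep, drop = FALSE],
                       geno$variants[keep, , drop = FALSE],
                       geno$ids, geno$sex)
}

subset_samples <- function(geno, keep) {
  new_cohort_genotypes(geno$g[keep, , drop = FALSE], geno$variants,
                       geno$ids[keep], geno$sex[keep])
}

#' Variant-level quality-control filters
#'
#' Removes variants in this fixed order: missingness above `miss_thresh`;
#' duplicated physical positions (the first variant at a position is
#' kept); strand-ambiguous A/T and C/G pairs; exact Hardy-Weinberg
#' P-value below `hwe_thresh`. Each step is itemized in the report.
#'
#' @param geno A `cohort_genotypes`.
#' @param miss_thresh Maximum tolerated per-variant missingness.
#' @param hwe_thresh HWE exact P-value below which a variant is removed.
#' @param drop_ambiguous Drop A/T and C/G variants?
#' @param drop_duplicate_pos Drop repeated chrom+position entries?
#' @return List `geno` (filtered) and `report` (tibble log, one row per
#'   filter with removal counts).
#' @export
apply_variant_filters <- function(geno, miss_thresh = 0.05,
                                  hwe_thresh = 1e-6,
                                  drop_ambiguous = TRUE,
                                  drop_duplicate_pos = TRUE) {
  report <- list()

  miss <- colMeans(is.na(geno$g))
  keep <- miss <= miss_thresh
  report$missing <- qc_log_row("variant_missingness", "variant",
                               sum(!keep), miss_thresh)
  geno <- subset_variants(geno, keep)

  if (drop_duplicate_pos) {
    keep <- !duplicated(geno$variants[, c("chrom", "pos")])
    report$dup <- qc_log_row("duplicate_position", "variant", sum(!keep))
    geno <- subset_variants(geno, keep)
  }

  if (drop_ambiguous) {
    ra <- paste0(geno$variants$ref, geno$variants$alt)
    keep <- !ra %in% c("AT", "TA", "CG", "GC")
    report$amb <- qc_log_row("ambiguous_strand", "variant", sum(!keep))
    geno <- subset_variants(geno, keep)
  }

  hwe_p <- apply(geno$g, 2, function(gv) {
    cnt <- genotype_counts(gv)
    if (sum(cnt) == 0) return(NA_real_)
    hwe_exact_test(cnt[1], cnt[2], cnt[3])
  })
  keep <- is.na(hwe_p) | hwe_p >= hwe_thresh
  report$hwe <- qc_log_row("hwe_exact", "variant", sum(!keep), hwe_thresh)
  geno <- subset_variants(geno, keep)

  list(geno = geno, report = dplyr::bind_rows(report))
}

#' Sample-level quality-control filters
#'
#' Removes samples whose genotype call rate is below `call_rate_thresh`,
#' then samples whose heterozygosity rate (heterozygous calls over
#' non-missing calls) lies more than `het_sd` standard deviations from
#' the cohort mean.
#'
#' @param geno A `cohort_genotypes`.
#' @param call_rate_thresh Minimum per-sample call rate.
#' @param het_sd Heterozygosity outlier cutoff in SD units.
#' @return List `geno` (filtered) and `report` (tibble log).
#' @export
apply_sample_filters <- function(geno, call_rate_thresh = 0.98,
                                 het_sd = 3) {
  if (nrow(geno$g) < 2) stop("need at least 2 samples")
  report <- list()

  call_rate <- rowMeans(!is.na(geno$g))
  keep <- call_rate >= call_rate_thresh
  report$cr <- qc_log_row("call_rate", "sample", sum(!keep),
                          call_rate_thresh)
  geno <- subset_samples(geno, keep)
  if (nrow(geno$g) < 2) stop("fewer than 2 samples after call-rate filter")

  het <- rowMeans(geno$g == 1L, na.rm = TRUE) /
    pmax(rowMeans(!is.na(geno$g)), 1e-12)
  mu <- mean(het); s <- sd(het)
  keep <- if (s == 0) rep(TRUE, length(het)) else abs(het - mu) <= het_sd * s
  report$het <- qc_log_row("heterozygosity_outlier", "sample", sum(!keep),
                           paste0("+/-", het_sd, " SD"))
  geno <- subset_samples(geno, keep)
  if (nrow(geno$g) < 2) stop("fewer than 2 samples after heterozygosity filter")

  list(geno = geno, report = dplyr::bind_rows(report))
}

#' Method-of-moments IBD estimates for sample pairs
#'
#' PLINK-style moment estimator: per pair, identity-by-state counts are
#' combined with expected IBS probabilities under IBD states 0/1/2
#' (computed from sample allele frequencies) to estimate
#' `P(IBD = 0, 1, 2)`, clipped to `[0, 1]` and renormalized;
#' `PI_HAT = P(IBD=2) + P(IBD=1) / 2`.
#'
#' @param geno A `cohort_genotypes`.
#' @param pairs Optional 2-column matrix of sample indices; default all
#'   pairs.
#' @return Tibble: `id1`, `id2`, `k0`, `k1`, `k2`, `pi_hat`, `n_snps`.
#' @export
ibd_estimate <- function(geno, pairs = NULL) {
  g <- geno$g
  n <- nrow(g)
  if (is.null(pairs)) {
    pairs <- t(utils::combn(n, 2))
  }
  p <- colMeans(g, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1 & !is.na(p)
  if (!any(poly)) stop("no polymorphic variants for IBD estimation")
  g <- g[, poly, drop = FALSE]
  p <- p[poly]; q <- 1 - p
  # expected per-locus IBS-state probabilities given IBD state
  e0_ibs0 <- 2 * p^2 * q^2
  e0_ibs1 <- 4 * p^3 * q + 4 * p * q^3
  e1_ibs1 <- 2 * p^2 * q + 2 * p * q^2
  e0_ibs2 <- p^4 + q^4 + 4 * p^2 * q^2
  e1_ibs2 <- p^2 + q^2  # p^3 + q^3 + p^2 q + p q^2

  # all pairwise IBS-state counts and expected sums via cross-products of
  # genotype indicator matrices (missing entries contribute zero)
  nm <- !is.na(g)
  G0 <- nm & g == 0L; G1 <- nm & g == 1L; G2 <- nm & g == 2L
  storage.mode(G0) <- "double"; storage.mode(G1) <- "double"
  storage.mode(G2) <- "double"; storage.mode(nm) <- "double"
  N_ibs0 <- G0 %*% t(G2); N_ibs0 <- N_ibs0 + t(N_ibs0)
  N_ibs2 <- G0 %*% t(G0) + G1 %*% t(G1) + G2 %*% t(G2)
  M_pair <- nm %*% t(nm)
  N_ibs1 <- M_pair - N_ibs0 - N_ibs2
  wsum <- function(e) nm %*% (e * t(nm))  # sum of e over both-called loci
  S00 <- wsum(e0_ibs0); S01 <- wsum(e0_ibs1); S11 <- wsum(e1_ibs1)
  S02 <- wsum(e0_ibs2); S12 <- wsum(e1_ibs2)

  i <- pairs[, 1]; j <- pairs[, 2]
  pick <- cbind(i, j)
  k0 <- N_ibs0[pick] / S00[pick]
  k1 <- (N_ibs1[pick] - k0 * S01[pick]) / S11[pick]
  k2 <- (N_ibs2[pick] - k0 * S02[pick] - k1 * S12[pick]) / M_pair[pick]
  k0 <- pmin(pmax(k0, 0), 1)
  k1 <- pmin(pmax(k1, 0), 1)
  k2 <- pmin(pmax(k2, 0), 1)
  tot <- k0 + k1 + k2
  tibble::tibble(id1 = geno$ids[i], id2 = geno$ids[j],
                 k0 = k0 / tot, k1 = k1 / tot, k2 = k2 / tot,
                 pi_hat = (k2 + k1 / 2) / tot, n_snps = M_pair[pick])
}

#' Relatedness pruning by pairwise IBD
#'
#' Estimates PI_HAT for every sample pair and, for each pair above
#' `pi_hat_thresh`, removes one member chosen uniformly at random
#' (seeded). Pairs are processed in decreasing PI_HAT order; a pair is
#' skipped if one member was already removed.
#'
#' @param geno A `cohort_genotypes`.
#' @param pi_hat_thresh PI_HAT above which a pair is considered related.
#' @param seed Integer RNG seed for the random member choice.
#' @return List `geno` (pruned), `report` (tibble log) and `ibd` (the
#'   pairwise estimates).
#' @export
ibd_prune <- function(geno, pi_hat_thresh = 0.2, seed = 1L) {
  if (ncol(geno$g) < 100) {
    warning("fewer than 100 variants; IBD estimates will be noisy")
  }
  ibd <- ibd_estimate(geno)
  flagged <- dplyr::arrange(
    dplyr::filter(ibd, .data$pi_hat > pi_hat_thresh),
    dplyr::desc(.data$pi_hat))
  set.seed(seed)
  removed <- character(0)
  if (nrow(flagged) > 0) {
    for (r in seq_len(nrow(flagged))) {
      pair <- c(flagged$id1[r], flagged$id2[r])
      if (any(pair %in% removed)) next
      removed <- c(removed, pair[sample.int(2, 1)])
    }
  }
  keep <- !geno$ids %in% removed
  report <- qc_log_row("ibd_relatedness", "sample", sum(!keep),
                       pi_hat_thresh)
  list(geno = subset_samples(geno, keep), report = report, ibd = ibd)
}

#' Exclude boys without measurements past a minimum age
#'
#' Removes male individuals whose last recorded measurement is before
#' `min_last_age` (boys followed only into early puberty cannot support
#' spurt-landmark estimation); a last measurement at exactly
#' `min_last_age` is retained. Girls are never touched.
#'
#' @param heights Long-format heights tibble.
#' @param min_last_age Minimum last-measurement age (years) for boys.
#' @return List `heights` (filtered) and `report` (tibble log).
#' @export
boys_age_filter <- function(heights, min_last_age = 12) {
  last_age <- dplyr::summarise(
    dplyr::group_by(heights, .data$id, .data$sex),
    last = max(.data$age_years), .groups = "drop")
  drop_ids <- last_age$id[last_age$sex == 0 & last_age$last < min_last_age]
  report <- qc_log_row("boys_min_last_age", "sample", length(drop_ids),
                       min_last_age)
  list(heights = dplyr::filter(heights, !.data$id %in% drop_ids),
       report = report, removed_ids = drop_ids)
}

#' Allele frequency, carrier count and genotype correlation
#'
#' Frequency is alternate alleles over twice the non-missing sample
#' count (reported raw; the cohort tables round to 3 decimals). Carriers
#' are samples with at least one alternate allele. Optionally reports
#' the Pearson correlation of two variants' genotype vectors over their
#' shared non-missing samples.
#'
#' @param geno A `cohort_genotypes`.
#' @param variant_id Variant to summarize.
#' @param other_id Optional second variant for the genotype correlation.
#' @return Tibble: `id`, `n_nonmissing`, `alt_freq`, `carriers`, and
#'   `cor_with`/`cor` when `other_id` is given.
#' @export
allele_stats <- function(geno, variant_id, other_id = NULL) {
  j <- match(variant_id, geno$variants$id)
  if (is.na(j)) stop("unknown variant id: ", variant_id)
  gv <- geno$g[, j]
  nm <- sum(!is.na(gv))
  if (nm == 0) stop("variant is missing in all samples")
  out <- tibble::tibble(
    id = variant_id,
    n_nonmissing = nm,
    alt_freq = sum(gv, na.rm = TRUE) / (2 * nm),
    carriers = sum(gv >= 1L, na.rm = TRUE)
  )
  if (!is.null(other_id)) {
    j2 <- match(other_id, geno$variants$id)
    if (is.na(j2)) stop("unknown variant id: ", other_id)
    gv2 <- geno$g[, j2]
    ok <- !is.na(gv) & !is.na(gv2)
    out$cor_with <- other_id
    out$cor <- stats::cor(gv[ok], gv2[ok])
  }
  out
}
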