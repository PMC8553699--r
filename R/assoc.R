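#' @importFrom stats pt complete.cases
NULL

#' Specify the per-SNP association model
#'
#' The full model regresses a pubertal phenotype on intercept, sex
#' (`x1`, 0 male / 1 female), global Mapuche ancestry proportion (`x2`),
#' Native American local-ancestry dosage at the SNP (`x3`), additive
#' genotype (`x4`), the sex-by-genotype interaction (`x1 x4`) and a sixth
#' term that defaults to the genotype-by-local-ancestry interaction
#' (`x4 x3`). Setting `literal_equation = TRUE` replaces that last term
#' with the sex-by-local-ancestry interaction (`x1 x3`) instead. The
#' reduced model (used for imputed SNPs, where local ancestry is
#' unavailable) drops every local-ancestry term.
#'
#' @param model `"full"` or `"reduced"`.
#' @param literal_equation Use sex-by-local-ancestry as the sixth term.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(model = c("full", "reduced"),
                       literal_equation = FALSE) {
  model <- match.arg(model)
  structure(list(model = model, literal_equation = literal_equation),
            class = "model_spec")
}

build_design <- function(x1, x2, x3, x4, spec) {
  if (spec$model == "full") {
    inter6 <- if (spec$literal_equation) x1 * x3 else x4 * x3
    X <- cbind(`(Intercept)` = 1, sex = x1, global_mapuche = x2,
               local_native = x3, genotype = x4, `sex:genotype` = x1 * x4,
               inter6 = inter6)
    colnames(X)[7] <- if (spec$literal_equation) "sex:local_native" else
      "genotype:local_native"
  } else {
    X <- cbind(`(Intercept)` = 1, sex = x1, global_mapuche = x2,
               genotype = x4, `sex:genotype` = x1 * x4)
  }
  X
}

assoc_row_names <- function(spec) {
  full <- spec$model == "full"
  betas <- if (full) paste0("beta", 0:6) else paste0("beta", c(0:2, 4:5))
  c("n", "mac", "rank_deficient",
    "beta_gt", "se_gt", "p_gt",
    "beta_gtxsex", "se_gtxsex", "p_gtxsex",
    "beta_female", "se_female", "p_female",
    if (full) c("beta_gtxla", "se_gtxla", "p_gtxla"),
    as.vector(rbind(betas, paste0("se_", betas))))
}

# lean per-SNP fit returning a named numeric vector (run_gwas hot path)
snp_fit_core <- function(ph, x1, x2, x3, x4, spec, row_names) {
  ok <- complete.cases(ph, x1, x2, x3, x4)
  n <- sum(ok)
  mac <- minor_allele_count(x4[ok])
  if (n < 10) stop("fewer than 10 complete cases")
  out <- setNames(rep(NA_real_, length(row_names)), row_names)
  out["n"] <- n; out["mac"] <- mac; out["rank_deficient"] <- 1
  X <- build_design(x1[ok], x2[ok], x3[ok], x4[ok], spec)
  y <- ph[ok]
  p <- ncol(X)
  qr_x <- qr(X)
  if (qr_x$rank < p || n <= p) return(out)
  out["rank_deficient"] <- 0
  beta <- qr.coef(qr_x, y)
  res <- y - X %*% beta
  sigma2 <- sum(res^2) / (n - p)
  Sigma <- sigma2 * chol2inv(qr.R(qr_x))
  se <- sqrt(diag(Sigma))
  df <- n - p
  wald <- function(est, s) 2 * pt(abs(est / s), df = df,
                                  lower.tail = FALSE)
  i_gt <- 4L + (spec$model == "full")  # genotype column index
  i_sx <- i_gt + 1L                    # sex:genotype column index
  est_f <- beta[i_gt] + beta[i_sx]
  se_f <- sqrt(Sigma[i_gt, i_gt] + Sigma[i_sx, i_sx] +
                 2 * Sigma[i_gt, i_sx])
  out["beta_gt"] <- beta[i_gt]; out["se_gt"] <- se[i_gt]
  out["p_gt"] <- wald(beta[i_gt], se[i_gt])
  out["beta_gtxsex"] <- beta[i_sx]; out["se_gtxsex"] <- se[i_sx]
  out["p_gtxsex"] <- wald(beta[i_sx], se[i_sx])
  out["beta_female"] <- est_f; out["se_female"] <- se_f
  out["p_female"] <- wald(est_f, se_f)
  betas <- if (spec$model == "full") paste0("beta", 0:6) else
    paste0("beta", c(0:2, 4:5))
  out[betas] <- beta
  out[paste0("se_", betas)] <- se
  if (spec$model == "full") {
    out["beta_gtxla"] <- beta[p]; out["se_gtxla"] <- se[p]
    out["p_gtxla"] <- wald(beta[p], se[p])
  }
  out
}

#' Fit the per-SNP interaction model at one variant
#'
#' Ordinary least squares with Wald t tests on `n - p` degrees of
#' freedom, covariance `sigma^2 (X'X)^{-1}`. Three hypothesis tests are
#' reported per SNP: the female genotype effect via the linear contrast
#' `beta_gt + beta_gtxsex` (test i), the male genotype effect `beta_gt`
#' (test ii) and the sex-by-genotype interaction `beta_gtxsex` (test
#' iii); under the full model the genotype-by-local-ancestry coefficient
#' is tested as well. Rank-deficient designs (monomorphic SNP, constant
#' local ancestry) yield a flagged NA row rather than an error.
#'
#' @param ph Phenotype vector.
#' @param x1 Sex covariate (0 male / 1 female).
#' @param x2 Global Mapuche ancestry proportions.
#' @param x3 Local-ancestry dosages at this SNP (ignored for reduced).
#' @param x4 Additive genotypes at this SNP (NA = missing, dropped).
#' @param spec A [model_spec()].
#' @return One-row tibble of estimates, standard errors and P-values.
#' @export
fit_snp_model <- function(ph, x1, x2, x3, x4, spec = model_spec()) {
  if (spec$model == "reduced") x3 <- rep(0, length(ph))
  nms <- assoc_row_names(spec)
  row <- snp_fit_core(ph, x1, x2, x3, x4, spec, nms)
  out <- tibble::as_tibble(as.list(row))
  out$n <- as.integer(out$n)
  out$mac <- as.integer(out$mac)
  out$rank_deficient <- out$rank_deficient == 1
  out
}

minor_allele_count <- function(g) {
  g <- g[!is.na(g)]
  ac <- sum(g)
  as.integer(min(ac, 2 * length(g) - ac))
}

#' Genome-wide association scan over all variants
#'
#' Fits the per-SNP model at every variant with minor-allele count at
#' least `mac_min`, in variant order. Ids must align exactly across the
#' phenotype table, genotypes, local ancestry and global ancestry; a
#' mismatch is an error before any fit.
#'
#' @param phen Phenotype tibble (`id`, `sex`, and the phenotype columns).
#' @param geno A `cohort_genotypes`.
#' @param la A `local_ancestry` (ignored under the reduced model; may be
#'   NULL then).
#' @param q Global-ancestry tibble with a `Mapuche` column.
#' @param phenotype Which phenotype to test: `"pv"`, `"apv"` or `"hapv"`.
#' @param spec A [model_spec()].
#' @param mac_min Minimum minor-allele count for a variant to be tested.
#' @return Tibble with one row per tested variant: variant metadata plus
#'   the [fit_snp_model()] columns.
#' @export
run_gwas <- function(phen, geno, la = NULL, q, phenotype = c("pv", "apv",
                                                             "hapv"),
                     spec = model_spec(), mac_min = 1) {
  phenotype <- match.arg(phenotype)
  keep <- match(phen$id, geno$ids)
  if (anyNA(keep)) stop("phenotype ids missing from genotypes")
  if (!all(phen$id %in% q$id)) stop("phenotype ids missing from ancestry")
  if (spec$model == "full") {
    if (is.null(la)) stop("full model requires local ancestry")
    if (!identical(dim(la$dosage), dim(geno$g))) {
      stop("local ancestry and genotypes disagree on dimensions")
    }
  }
  g <- geno$g[keep, , drop = FALSE]
  dos <- if (spec$model == "full") la$dosage[keep, , drop = FALSE] else NULL
  x1 <- geno$sex[keep]
  x2 <- q$Mapuche[match(phen$id, q$id)]
  ph <- phen[[phenotype]]

  macs <- apply(g, 2, minor_allele_count)
  test_idx <- which(macs >= mac_min)
  nms <- assoc_row_names(spec)
  zero_x3 <- rep(0, length(ph))
  rows <- vapply(test_idx, function(j) {
    x3 <- if (is.null(dos)) zero_x3 else dos[, j]
    snp_fit_core(ph, x1, x2, x3, g[, j], spec, nms)
  }, numeric(length(nms)))
  meta <- geno$variants[test_idx, c("id", "chrom", "pos", "ref", "alt")]
  stats <- tibble::as_tibble(t(rows))
  stats$n <- as.integer(stats$n)
  stats$mac <- as.integer(stats$mac)
  stats$rank_deficient <- stats$rank_deficient == 1
  out <- dplyr::bind_cols(meta, stats)
  out$phenotype <- phenotype
  out
}

#' Effect of global ancestry on a pubertal phenotype
#'
#' Ordinary least squares of the phenotype on an intercept, sex
#' (optional) and the global Mapuche proportion; the Mapuche coefficient
#' is the average phenotype difference between a fully European and a
#' fully Mapuche individual.
#'
#' @param ph Phenotype vector.
#' @param sex Sex covariate (0/1); set `adjust_sex = FALSE` to omit.
#' @param q_mapuche Global Mapuche proportions.
#' @param adjust_sex Include sex in the model (default TRUE).
#' @return One-row tibble: `effect`, `se`, `p`, `n`.
#' @export
ancestry_effect_regression <- function(ph, sex, q_mapuche,
                                       adjust_sex = TRUE) {
  ok <- complete.cases(ph, sex, q_mapuche)
  if (sum(ok) < 10) stop("fewer than 10 complete cases")
  qv <- q_mapuche[ok]
  if (stats::sd(qv) == 0) stop("constant ancestry proportion: effect not identifiable")
  X <- if (adjust_sex) cbind(1, sex[ok], qv) else cbind(1, qv)
  y <- ph[ok]
  n <- length(y); p <- ncol(X)
  qr_x <- qr(X)
  beta <- qr.coef(qr_x, y)
  res <- y - X %*% beta
  sigma2 <- sum(res^2) / (n - p)
  se <- sqrt(diag(sigma2 * chol2inv(qr.R(qr_x))))
  i <- p  # ancestry is the last column
  tibble::tibble(effect = beta[i], se = se[i],
                 p = 2 * pt(abs(beta[i] / se[i]), df = n - p,
                            lower.tail = FALSE),
                 n = n)
}

#' Label association P-values by significance tier
#'
#' Adds a `sig_<test>` column per P-value column: `"genome-wide"` for
#' `P < gw`, `"nominal"` for `P < nominal`, else `"none"`. Inequalities
#' are strict.
#'
#' @param results Association tibble with `p_*` columns.
#' @param gw Genome-wide significance threshold.
#' @param nominal Nominal (suggestive) threshold.
#' @return The input with one label column per test.
#' @export
classify_significance <- function(results, gw = 5e-8, nominal = 1e-6) {
  pcols <- grep("^p_", names(results), value = TRUE)
  for (pc in pcols) {
    lab <- dplyr::case_when(
      is.na(results[[pc]]) ~ NA_character_,
      results[[pc]] < gw ~ "genome-wide",
      results[[pc]] < nominal ~ "nominal",
      TRUE ~ "none"
    )
    results[[sub("^p_", "sig_", pc)]] <- lab
  }
  results
}

#' Plot-ready Manhattan table
#'
#' Long-format `-log10(P)` per test with a cumulative genome coordinate;
#' rows with `-log10(P)` below `min_neglogp` are omitted (the flat floor
#' of a Manhattan plot carries no information).
#'
#' @param results Association tibble with `chrom`, `pos` and `p_*`
#'   columns.
#' @param min_neglogp Smallest `-log10(P)` retained.
#' @return Tibble: `chrom`, `pos`, `cum_pos`, `test`, `neglog10p`.
#' @export
manhattan_export <- function(results, min_neglogp = 2) {
  pcols <- grep("^p_", names(results), value = TRUE)
  empty <- tibble::tibble(chrom = character(), pos = integer(),
                          cum_pos = numeric(), test = character(),
                          neglog10p = numeric())
  if (nrow(results) == 0) return(empty)
  chroms <- unique(results$chrom)
  spans <- purrr::map_dbl(chroms, function(ch) {
    max(results$pos[results$chrom == ch])
  })
  offsets <- setNames(cumsum(c(0, spans[-length(spans)])), chroms)
  long <- tidyr::pivot_longer(
    results[, c("chrom", "pos", pcols)],
    cols = dplyr::all_of(pcols), names_to = "test", values_to = "p")
  long <- dplyr::filter(long, !is.na(.data$p))
  long$neglog10p <- -log10(long$p)
  long$cum_pos <- long$pos + unname(offsets[long$chrom])
  out <- dplyr::filter(long, .data$neglog10p >= min_neglogp)
  out[, c("chrom", "pos", "cum_pos", "test", "neglog10p")]
}

#' Manhattan plot of a GWAS result table
#'
#' @param results Association tibble from [run_gwas()].
#' @param test Which P-value column to plot (default `"p_gt"`).
#' @param min_neglogp Smallest `-log10(P)` shown.
#' @param gw,nominal Reference significance thresholds.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(results, test = "p_gt", min_neglogp = 2,
                           gw = 5e-8, nominal = 1e-6) {
  tab <- manhattan_export(results, min_neglogp = min_neglogp)
  tab <- dplyr::filter(tab, .data$test == sub("^p_", "p_", !!test))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$cum_pos,
                                    y = .data$neglog10p,
                                    colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(gw), linetype = "dashed",
                        colour = "red") +
    ggplot2::geom_hline(yintercept = -log10(nominal), linetype = "dotted",
                        colour = "grey40") +
    ggplot2::labs(x = "cumulative position (bp)",
                  y = expression(-log[10](italic(P))))
}
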