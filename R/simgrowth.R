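#' Configuration of simulated causal and ancestry effects
#'
#' Collects the ground-truth effect structure used by [simulate_growth()].
#' Causal SNP effects act through the shape-invariant transform: `tempo_*`
#' shifts (years per allele, sex-specific) move the individual's timing
#' and hence APV; `logvel_*` effects (per allele, sex-specific) add to the
#' log velocity scale and hence multiply PV by `exp(-logvel)`. Global
#' Mapuche ancestry shifts timing by `theta_apv` (years per unit
#' proportion) and height by `theta_hapv` (cm per unit proportion),
#' matching the cohort-level average effects of -0.73 years on APV and
#' -4.3 cm on HAPV per unit Mapuche proportion.
#'
#' @param causal Tibble with columns `id`, `tempo_m`, `tempo_f`,
#'   `logvel_m`, `logvel_f` (one row per causal SNP); may be empty.
#' @param theta_apv Years of APV shift per unit Mapuche proportion.
#' @param theta_hapv cm of HAPV shift per unit Mapuche proportion.
#' @param sd_alpha SD of the size random effect (cm).
#' @param sd_beta SD of the tempo random effect (years).
#' @param sd_gamma SD of the log-velocity random effect.
#' @return A list of class `growth_truth_config`.
#' @export
growth_truth_config <- function(causal = NULL,
                                theta_apv = -0.73, theta_hapv = -4.3,
                                sd_alpha = 4, sd_beta = 0.6,
                                sd_gamma = 0.1) {
  if (is.null(causal)) {
    causal <- tibble::tibble(id = character(), tempo_m = numeric(),
                             tempo_f = numeric(), logvel_m = numeric(),
                             logvel_f = numeric())
  }
  needed <- c("id", "tempo_m", "tempo_f", "logvel_m", "logvel_f")
  if (!all(needed %in% names(causal))) {
    stop("causal table needs columns: ", paste(needed, collapse = ", "))
  }
  structure(list(causal = causal, theta_apv = theta_apv,
                 theta_hapv = theta_hapv, sd_alpha = sd_alpha,
                 sd_beta = sd_beta, sd_gamma = sd_gamma),
            class = "growth_truth_config")
}

#' A male-specific causal effect on peak height velocity
#'
#' Helper building a one-SNP causal table in which the allele lowers PV in
#' boys by `pv_effect` cm/year (for a carrier at the mean velocity scale)
#' and has no effect in girls, mimicking the opposite-sign male/female
#' pattern of the strongest cohort associations.
#'
#' The allele scales the velocity transform (`logvel`) to change PV and
#' carries a compensating tempo shift `-(exp(logvel) - 1) * APV0` so a
#' single-copy carrier's APV stays at their baseline: the variant changes
#' how fast the spurt is, not when it happens.
#'
#' @param id Variant id of the causal SNP.
#' @param pv_effect PV change in boys per allele, cm/year (negative slows
#'   the spurt).
#' @param sex_specific If `TRUE` (default) girls carry no effect.
#' @return Causal tibble usable in [growth_truth_config()].
#' @export
causal_pv_effect <- function(id, pv_effect = -2.5, sex_specific = TRUE) {
  lm_m <- base_curve_landmarks(base_curve_params(0))
  lm_f <- base_curve_landmarks(base_curve_params(1))
  lv_m <- -log(1 + pv_effect / lm_m[["PV0"]])
  tm_m <- -(exp(lv_m) - 1) * lm_m[["APV0"]]
  lv_f <- if (sex_specific) 0 else -log(1 + pv_effect / lm_f[["PV0"]])
  tm_f <- if (sex_specific) 0 else -(exp(lv_f) - 1) * lm_f[["APV0"]]
  tibble::tibble(id = id, tempo_m = tm_m, tempo_f = tm_f,
                 logvel_m = lv_m, logvel_f = lv_f)
}

#' Simulate longitudinal heights under the shape-invariant growth model
#'
#' Generates height records `y_it = alpha_i + theta_hapv q_i +
#' h((t - B_i) / exp(G_i)) + N(0, noise_sd^2)` on a fixed visit schedule,
#' where `h` is the sex-specific double-logistic base curve,
#' `B_i = beta_i + theta_apv q_i + sum(g tempo)` collects all timing
#' shifts and `G_i = gamma_i + sum(g logvel)` all velocity-scale effects.
#' Random effects `alpha, beta, gamma` are independent normals. The
#' returned truth contains the closed-form landmarks
#' `PV_i = PV0 exp(-G_i)`, `APV_i = B_i + exp(G_i) APV0`,
#' `HAPV_i = alpha_i + theta_hapv q_i + HAPV0`.
#'
#' Missing genotype calls at causal SNPs contribute no effect (treated as
#' zero copies).
#'
#' @param geno A `cohort_genotypes` (provides sex and causal genotypes).
#' @param q Global-ancestry tibble (`Mapuche` column used).
#' @param truth_config A [growth_truth_config()].
#' @param schedule Measurement ages in years; default 6-monthly visits
#'   from 5.0 to 16.5.
#' @param noise_sd Measurement noise SD in cm.
#' @param seed Integer RNG seed.
#' @return List with `heights` (tibble: id, sex, age_years, height_cm)
#'   and `truth` (list of class `sim_truth`).
#' @export
simulate_growth <- function(geno, q, truth_config = growth_truth_config(),
                            schedule = seq(5, 16.5, by = 0.5),
                            noise_sd = 0.5, seed = 1L) {
  if (length(schedule) == 0) stop("schedule must be non-empty")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  tc <- truth_config
  if (nrow(tc$causal) > 0 &&
      !all(tc$causal$id %in% geno$variants$id)) {
    stop("causal variant id not present among variants")
  }
  N <- length(geno$ids)
  qm <- ancestry_matrix(q)
  if (!identical(rownames(qm), geno$ids)) {
    qm <- qm[match(geno$ids, rownames(qm)), , drop = FALSE]
  }
  q_map <- unname(qm[, "Mapuche"])
  set.seed(seed)
  alpha <- rnorm(N, 0, tc$sd_alpha)
  beta <- rnorm(N, 0, tc$sd_beta)
  gamma <- rnorm(N, 0, tc$sd_gamma)

  tempo_snp <- numeric(N)
  logvel_snp <- numeric(N)
  if (nrow(tc$causal) > 0) {
    for (r in seq_len(nrow(tc$causal))) {
      gvec <- geno$g[, tc$causal$id[r]]
      gvec[is.na(gvec)] <- 0L
      tempo <- ifelse(geno$sex == 0, tc$causal$tempo_m[r],
                      tc$causal$tempo_f[r])
      logvel <- ifelse(geno$sex == 0, tc$causal$logvel_m[r],
                       tc$causal$logvel_f[r])
      tempo_snp <- tempo_snp + gvec * tempo
      logvel_snp <- logvel_snp + gvec * logvel
    }
  }
  B <- beta + tc$theta_apv * q_map + tempo_snp
  G <- gamma + logvel_snp
  hshift <- tc$theta_hapv * q_map

  lm_m <- base_curve_landmarks(base_curve_params(0))
  lm_f <- base_curve_landmarks(base_curve_params(1))
  land <- rbind(lm_m, lm_f)[geno$sex + 1L, , drop = FALSE]

  n_t <- length(schedule)
  heights <- matrix(0, N, n_t)
  pm <- base_curve_params(0); pf <- base_curve_params(1)
  for (i in seq_len(N)) {
    p <- if (geno$sex[i] == 0) pm else pf
    tt <- (schedule - B[i]) / exp(G[i])
    heights[i, ] <- alpha[i] + hshift[i] + base_curve_height(tt, p)
  }
  if (noise_sd > 0) heights <- heights + rnorm(N * n_t, 0, noise_sd)

  out <- tibble::tibble(
    id = rep(geno$ids, each = n_t),
    sex = rep(geno$sex, each = n_t),
    age_years = rep(schedule, times = N),
    height_cm = as.vector(t(heights))
  )
  truth <- structure(list(
    causal = tc$causal, theta_apv = tc$theta_apv,
    theta_hapv = tc$theta_hapv, seed = seed,
    effects = tibble::tibble(
      id = geno$ids, sex = geno$sex,
      alpha = alpha, beta = beta, gamma = gamma,
      tempo_total = B, logvel_total = G,
      pv = unname(land[, "PV0"] * exp(-G)),
      apv = unname(B + exp(G) * land[, "APV0"]),
      hapv = unname(alpha + hshift + land[, "HAPV0"])
    )
  ), class = "sim_truth")
  list(heights = out, truth = truth)
}
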