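# Shared fixture builders. Heavy simulated cohorts are cached in an
# environment so several test files can reuse one realization.

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, build(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# bare genotype container from a matrix
make_geno <- function(g, pos = NULL, ref = NULL, alt = NULL,
                      chrom = "1", sex = NULL, ids = NULL) {
  m <- ncol(g)
  variants <- tibble::tibble(
    chrom = chrom,
    pos = if (is.null(pos)) seq_len(m) * 1000L else as.integer(pos),
    ref = if (is.null(ref)) rep("A", m) else ref,
    alt = if (is.null(alt)) rep("C", m) else alt,
    id = sprintf("v%04d", seq_len(m))
  )
  pubgrowth:::new_cohort_genotypes(
    g, variants,
    ids = if (is.null(ids)) sprintf("s%04d", seq_len(nrow(g))) else ids,
    sex = if (is.null(sex)) rep(0L, nrow(g)) else as.integer(sex))
}

# recovery cohort at the standard experiment settings: 400 individuals,
# effect SDs alpha 4 cm / beta 0.6 yr / gamma 0.15, 0.5 cm noise
recovery_cohort <- function() {
  cache_get("recovery", function() {
    panel <- simulate_reference_freqs(4, 200, c(0.12, 0.12, 0.05, 0.05),
                                      seed = 1)
    q <- simulate_admixture(400, seed = 2)
    la <- simulate_local_ancestry(q, panel, generations = 15, seed = 3)
    colnames(la$dosage) <- panel$variants$id
    geno <- simulate_genotypes(panel, la, seed = 4)
    tc <- growth_truth_config(sd_alpha = 4, sd_beta = 0.6,
                              sd_gamma = 0.15)
    sim <- simulate_growth(geno, q, tc, noise_sd = 0.5, seed = 5)
    list(panel = panel, q = q, la = la, geno = geno,
         heights = sim$heights, truth = sim$truth)
  })
}

# growth fits on the recovery cohort, fitted once
recovery_fits <- function() {
  cache_get("recovery_fits", function() {
    rc <- recovery_cohort()
    list(male = fit_growth_model(rc$heights, sex = 0, max_iter = 60),
         female = fit_growth_model(rc$heights, sex = 1, max_iter = 60))
  })
}

# random regression design for per-SNP model checks
sim_design <- function(n, seed, p_geno = 0.3) {
  set.seed(seed)
  list(x1 = rbinom(n, 1, 0.5), x2 = runif(n),
       x3 = rbinom(n, 2, 0.45), x4 = rbinom(n, 2, p_geno),
       ph = rnorm(n))
}

# independent enumeration oracle for the exact HWE test: conditional
# probability of each heterozygote count via plain factorial arithmetic
hwe_enum_oracle <- function(a, h, b) {
  n <- a + h + b
  na <- h + 2 * min(a, b)
  if (na == 0) return(1)
  hets <- seq(na %% 2, na, by = 2)
  prob <- vapply(hets, function(k) {
    ha <- (na - k) / 2
    hb <- n - k - ha
    factorial(n) / (factorial(ha) * factorial(k) * factorial(hb)) * 2^k
  }, numeric(1))
  prob <- prob / sum(prob)
  p_obs <- prob[match(h, hets)]
  sum(prob[prob <= p_obs * (1 + 1e-12)])
}

# cohort at generator defaults and study size, for ancestry-effect
# recovery (fitted once, cached)
theta_cohort <- function() {
  cache_get("theta", function() {
    panel <- simulate_reference_freqs(4, 100, c(0.12, 0.12, 0.05, 0.05),
                                      seed = 61)
    q <- simulate_admixture(900, seed = 62)
    la <- simulate_local_ancestry(q, panel, generations = 15, seed = 63)
    colnames(la$dosage) <- panel$variants$id
    geno <- simulate_genotypes(panel, la, seed = 64)
    sim <- simulate_growth(geno, q, growth_truth_config(), seed = 65)
    dp <- derive_phenotypes(sim$heights, max_iter = 60)
    list(q = q, truth = sim$truth, phenotypes = dp$phenotypes)
  })
}

# noiseless single-sex cohort with known effects, for identity checks
noiseless_cohort <- function() {
  cache_get("noiseless", function() {
    panel <- simulate_reference_freqs(4, 20, c(0.1, 0.1, 0.05, 0.05),
                                      seed = 11)
    q <- simulate_admixture(60, seed = 12)
    la <- simulate_local_ancestry(q, panel, generations = 15, seed = 13)
    colnames(la$dosage) <- panel$variants$id
    geno <- simulate_genotypes(panel, la, seed = 14)
    geno$sex <- rep(0L, 60)  # one sex only
    tc <- growth_truth_config(theta_apv = 0, theta_hapv = 0,
                              sd_alpha = 3, sd_beta = 0.3,
                              sd_gamma = 0.1)
    sim <- simulate_growth(geno, q, tc, noise_sd = 0, seed = 15)
    list(heights = sim$heights, truth = sim$truth)
  })
}
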