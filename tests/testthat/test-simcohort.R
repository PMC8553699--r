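test_that("reference panel frequencies behave across divergence regimes", {
  # single population: frequencies stay inside [0, 1]
  p1 <- simulate_reference_freqs(1, 500, 0.2, seed = 1)
  expect_equal(dim(p1$freqs), c(1L, 500L))
  expect_true(all(p1$freqs >= 0 & p1$freqs <= 1))

  # near-zero divergence: population freqs hug the ancestral freq
  p0 <- simulate_reference_freqs(2, 1000, c(1e-4, 1e-4), seed = 2)
  expect_lt(max(abs(sweep(p0$freqs, 2, p0$ancestral))), 0.05)

  # positions strictly increasing, 1 cM/Mb genetic map
  expect_true(all(diff(p1$variants$pos) > 0))
  expect_equal(p1$genetic_pos, p1$variants$pos * 1e-8)

  expect_error(simulate_reference_freqs(0, 10, 0.1), "positive")
  expect_error(simulate_reference_freqs(2, 10, c(0.1, 1.2)), "divergence")
})

test_that("pairwise divergence statistic matches the Balding-Nichols expectation", {
  # E[(f1 - f2)^2 / (pbar (1 - pbar))] ~ F1 + F2; package value at one
  # seed against a direct re-simulation oracle averaged over 10 seeds
  stat <- function(f1, f2) {
    pbar <- (f1 + f2) / 2
    mean((f1 - f2)^2 / (pbar * (1 - pbar)))
  }
  pk <- simulate_reference_freqs(2, 10000, c(0.1, 0.1), seed = 1)
  s_pkg <- stat(pk$freqs[1, ], pk$freqs[2, ])
  oracle <- vapply(1:10, function(s) {
    set.seed(1000 + s)
    p <- runif(10000, 0.05, 0.95)
    f1 <- rbeta(10000, p * 9, (1 - p) * 9)  # (1 - F) / F = 9 at F = 0.1
    f2 <- rbeta(10000, p * 9, (1 - p) * 9)
    stat(f1, f2)
  }, numeric(1))
  expect_equal(s_pkg, 0.2, tolerance = 0.02 / 0.2)
  expect_equal(mean(oracle), s_pkg, tolerance = 0.02)
})

test_that("Dirichlet admixture proportions sit on the simplex with the right means", {
  q <- simulate_admixture(10000, 20 * c(0.438, 0.026, 0.521, 0.015),
                          seed = 1)
  qm <- as.matrix(q[, -1])
  expect_true(all(abs(rowSums(qm) - 1) < 1e-9))
  expect_true(all(qm >= 0 & qm <= 1))
  expect_equal(unname(colMeans(qm)), c(0.438, 0.026, 0.521, 0.015),
               tolerance = 0.01 / 0.438)

  # degenerate concentration pins everyone to the first ancestry
  qd <- simulate_admixture(50, c(1e6, 1e-6, 1e-6, 1e-6), seed = 2)
  expect_true(all(as.matrix(qd[, -1])[, 1] > 0.999))

  expect_error(simulate_admixture(10, c(1, -1, 1, 1)), "positive")
})

test_that("local-ancestry tracts have the global proportions as stationary law", {
  panel <- simulate_reference_freqs(4, 10000, rep(0.1, 4), seed = 3,
                                    spacing_bp = 5e5)
  q <- tibble::tibble(id = sprintf("i%d", 1:5),
                      Mapuche = 0.30, Aymara = 0.15,
                      European = 0.50, African = 0.05)
  la <- simulate_local_ancestry(q, panel, generations = 50, seed = 4)
  native <- rowMeans(la$dosage) / 2
  expect_true(all(abs(native - 0.45) < 0.02))

  # no recombination: each haplotype is single-ancestry
  la0 <- simulate_local_ancestry(q, panel, generations = 1e-9, seed = 5)
  expect_true(all(apply(la0$hap1, 1, function(x) length(unique(x))) == 1))
  expect_true(all(apply(la0$dosage, 1, function(x) length(unique(x))) == 1))

  # pure Native ancestry forces dosage 2 everywhere
  qp <- tibble::tibble(id = "i1", Mapuche = 1, Aymara = 0,
                       European = 0, African = 0)
  lap <- simulate_local_ancestry(qp, panel, generations = 10, seed = 6)
  expect_true(all(lap$dosage == 2L))

  expect_error(simulate_local_ancestry(q, panel, generations = 0), "positive")
})

test_that("mean switch count tracks generations times genetic length", {
  panel <- simulate_reference_freqs(4, 2000, rep(0.1, 4), seed = 7)
  q <- simulate_admixture(500, seed = 8)
  la <- simulate_local_ancestry(q, panel, generations = 10, seed = 9)
  L <- diff(range(panel$genetic_pos))
  expected <- sum(1 - exp(-10 * diff(panel$genetic_pos)))
  expect_equal(expected, 10 * L, tolerance = 0.01)
  expect_equal(mean(la$n_switches), expected, tolerance = 0.1)
})

test_that("genotypes are Bernoulli draws from the tract ancestry's frequency", {
  panel <- simulate_reference_freqs(1, 50, 0.2, seed = 10)
  q <- tibble::tibble(id = sprintf("i%d", 1:5000), pop1 = 1)
  la <- simulate_local_ancestry(q, panel, generations = 10, seed = 11,
                                native_labels = "pop1")
  p0 <- panel
  p0$freqs[] <- 0
  expect_true(all(simulate_genotypes(p0, la, seed = 12)$g == 0L))
  p1 <- panel
  p1$freqs[] <- 1
  expect_true(all(simulate_genotypes(p1, la, seed = 13)$g == 2L))
  p3 <- panel
  p3$freqs[] <- 0.3
  g <- simulate_genotypes(p3, la, seed = 14)$g
  expect_equal(mean(g) / 2, 0.3, tolerance = 0.01 / 0.3)

  # missingness sprinkled at the requested rate
  gm <- simulate_genotypes(p3, la, missing_rate = 0.05, seed = 15)$g
  expect_equal(mean(is.na(gm)), 0.05, tolerance = 0.1)
})

test_that("noiseless growth with zero effects reproduces the base curve exactly", {
  panel <- simulate_reference_freqs(4, 10, rep(0.1, 4), seed = 16)
  q <- simulate_admixture(20, seed = 17)
  la <- simulate_local_ancestry(q, panel, generations = 10, seed = 18)
  geno <- simulate_genotypes(panel, la, seed = 19)
  tc <- growth_truth_config(theta_apv = 0, theta_hapv = 0,
                            sd_alpha = 0, sd_beta = 0, sd_gamma = 0)
  sim <- simulate_growth(geno, q, tc, noise_sd = 0, seed = 20)
  for (s in 0:1) {
    hh <- dplyr::filter(sim$heights, sex == s)
    expect_equal(hh$height_cm,
                 base_curve_height(hh$age_years, base_curve_params(s)),
                 tolerance = 1e-12)
  }
  lm0 <- base_curve_landmarks(base_curve_params(0))
  tr <- dplyr::filter(sim$truth$effects, sex == 0)
  expect_equal(tr$pv, rep(lm0[["PV0"]], nrow(tr)))
  expect_equal(tr$apv, rep(lm0[["APV0"]], nrow(tr)))
  expect_equal(tr$hapv, rep(lm0[["HAPV0"]], nrow(tr)))
})

test_that("simulated truth landmarks agree with numerically differentiated curves", {
  rc <- recovery_cohort()
  tr <- rc$truth$effects
  h <- 1e-5
  for (i in c(1, 57, 200, 388)) {
    p <- base_curve_params(tr$sex[i])
    B <- tr$tempo_total[i]; G <- tr$logvel_total[i]
    qmap <- rc$q$Mapuche[match(tr$id[i], rc$q$id)]
    yfun <- function(t) {
      tr$alpha[i] + rc$truth$theta_hapv * qmap +
        base_curve_height((t - B) / exp(G), p)
    }
    vfun <- function(t) (yfun(t + h) - yfun(t - h)) / (2 * h)
    opt <- optimize(vfun, interval = B + exp(G) * c(9, 16),
                    maximum = TRUE, tol = 1e-10)
    expect_equal(opt$maximum, tr$apv[i], tolerance = 1e-6)
    expect_equal(opt$objective, tr$pv[i], tolerance = 1e-6)
    expect_equal(yfun(opt$maximum), tr$hapv[i], tolerance = 1e-6)
  }
})

test_that("ancestry timing effects shift APV by theta per unit Mapuche proportion", {
  panel <- simulate_reference_freqs(4, 10, rep(0.1, 4), seed = 21)
  q <- tibble::tibble(id = sprintf("i%d", 1:2),
                      Mapuche = c(1, 0), Aymara = 0,
                      European = c(0, 1), African = 0)
  la <- simulate_local_ancestry(q, panel, generations = 10, seed = 22)
  geno <- simulate_genotypes(panel, la, seed = 23)
  geno$sex <- c(0L, 0L)
  tc <- growth_truth_config(theta_apv = -0.73, theta_hapv = -4.3,
                            sd_alpha = 0, sd_beta = 0, sd_gamma = 0)
  sim <- simulate_growth(geno, q, tc, noise_sd = 0, seed = 24)
  tr <- sim$truth$effects
  expect_equal(tr$apv[1] - tr$apv[2], -0.73, tolerance = 1e-12)
  expect_equal(tr$hapv[1] - tr$hapv[2], -4.3, tolerance = 1e-12)
})

test_that("identical seeds give bit-identical cohorts", {
  build <- function() {
    panel <- simulate_reference_freqs(4, 100, rep(0.1, 4), seed = 31)
    q <- simulate_admixture(30, seed = 32)
    la <- simulate_local_ancestry(q, panel, generations = 15, seed = 33)
    geno <- simulate_genotypes(panel, la, missing_rate = 0.01, seed = 34)
    sim <- simulate_growth(geno, q, seed = 35)
    list(panel, q, la, geno, sim)
  }
  expect_identical(build(), build())
})
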