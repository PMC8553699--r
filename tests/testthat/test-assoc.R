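test_that("per-SNP OLS matches a direct normal-equations solve", {
  for (seed in 1:5) {
    d <- sim_design(50, seed)
    fit <- fit_snp_model(d$ph, d$x1, d$x2, d$x3, d$x4)
    X <- cbind(1, d$x1, d$x2, d$x3, d$x4, d$x1 * d$x4, d$x4 * d$x3)
    beta <- solve(t(X) %*% X, t(X) %*% d$ph)
    res <- d$ph - X %*% beta
    sig2 <- sum(res^2) / (50 - 7)
    se <- sqrt(diag(sig2 * solve(t(X) %*% X)))
    expect_equal(unname(unlist(fit[paste0("beta", 0:6)])),
                 drop(beta), tolerance = 1e-8)
    expect_equal(unname(unlist(fit[paste0("se_beta", 0:6)])),
                 se, tolerance = 1e-8)
  }
})

test_that("female contrast equals the sex-recoded genotype test exactly", {
  for (seed in 1:10) {
    d <- sim_design(300, seed + 20)
    f1 <- fit_snp_model(d$ph, d$x1, d$x2, d$x3, d$x4)
    f2 <- fit_snp_model(d$ph, 1 - d$x1, d$x2, d$x3, d$x4)
    expect_equal(f1$beta_female, f2$beta_gt, tolerance = 1e-10)
    expect_equal(f1$se_female, f2$se_gt, tolerance = 1e-10)
    expect_equal(f1$p_female, f2$p_gt, tolerance = 1e-10)
    # the reported female effect is the sum of the two effect columns
    expect_identical(f1$beta_female, f1$beta4 + f1$beta5)
  }
})

test_that("null SNPs reach nominal type-I error", {
  n <- 500
  set.seed(100)
  x1 <- rbinom(n, 1, 0.5); x2 <- runif(n); x3 <- rbinom(n, 2, 0.45)
  hits <- vapply(1:1000, function(i) {
    x4 <- rbinom(n, 2, runif(1, 0.05, 0.5))
    fit_snp_model(rnorm(n), x1, x2, x3, x4)$p_gt < 0.05
  }, logical(1))
  expect_equal(mean(hits), 0.05, tolerance = 0.02 / 0.05)
})

test_that("type-I error holds when genotype tracks local ancestry", {
  # confounding structure: allele frequency depends on local ancestry
  # and the phenotype depends on local ancestry but not the genotype
  n <- 600
  set.seed(101)
  x1 <- rbinom(n, 1, 0.5); x2 <- runif(n)
  hits <- vapply(1:500, function(i) {
    x3 <- rbinom(n, 2, 0.45)
    x4 <- rbinom(n, 2, 0.15 + 0.15 * x3)
    ph <- 0.5 * x3 + rnorm(n)
    fit_snp_model(ph, x1, x2, x3, x4)$p_gt < 0.05
  }, logical(1))
  mc_se <- sqrt(0.05 * 0.95 / 500)
  expect_lt(abs(mean(hits) - 0.05), 2 * mc_se + 1e-9)
})

test_that("degenerate designs give flagged NA rows, small n errors", {
  d <- sim_design(100, 7)
  fit <- fit_snp_model(d$ph, d$x1, d$x2, d$x3, rep(0, 100))
  expect_true(fit$rank_deficient)
  expect_true(is.na(fit$p_gt))
  expect_error(fit_snp_model(d$ph[1:5], d$x1[1:5], d$x2[1:5], d$x3[1:5],
                             d$x4[1:5]), "10 complete cases")
})

test_that("genome-wide scan respects MAC floor and model spec", {
  set.seed(102)
  n <- 80; m <- 40
  g <- matrix(rbinom(n * m, 2, runif(m, 0.02, 0.4)[col(matrix(0, n, m))]),
              n, m)
  geno <- make_geno(g, sex = rbinom(n, 1, 0.5))
  la <- structure(list(dosage = matrix(rbinom(n * m, 2, 0.45), n, m),
                       ids = geno$ids), class = "local_ancestry")
  q <- tibble::tibble(id = geno$ids, Mapuche = runif(n))
  phen <- tibble::tibble(id = geno$ids, sex = geno$sex, pv = rnorm(n))
  res <- run_gwas(phen, geno, la, q, "pv", mac_min = 10)
  macs <- apply(g, 2, pubgrowth:::minor_allele_count)
  expect_setequal(res$id, geno$variants$id[macs >= 10])
  expect_true(all(res$mac >= 10))
  expect_true(all(c("beta3", "beta6", "p_gtxla") %in% names(res)))
  expect_true(all(res$p_gt > 0 & res$p_gt <= 1, na.rm = TRUE))

  red <- run_gwas(phen, geno, NULL, q, "pv", spec = model_spec("reduced"))
  expect_false(any(c("beta3", "beta6", "p_gtxla") %in% names(red)))

  # misaligned ids abort before fitting
  bad <- phen; bad$id[1] <- "stranger"
  expect_error(run_gwas(bad, geno, la, q, "pv"), "ids")
})

test_that("the literal-equation switch swaps the sixth interaction term", {
  d <- sim_design(200, 8)
  f_gt <- fit_snp_model(d$ph, d$x1, d$x2, d$x3, d$x4,
                        spec = model_spec("full"))
  f_lit <- fit_snp_model(d$ph, d$x1, d$x2, d$x3, d$x4,
                         spec = model_spec("full", literal_equation = TRUE))
  X_lit <- cbind(1, d$x1, d$x2, d$x3, d$x4, d$x1 * d$x4, d$x1 * d$x3)
  beta <- solve(t(X_lit) %*% X_lit, t(X_lit) %*% d$ph)
  expect_equal(f_lit$beta6, beta[7], tolerance = 1e-8)
  expect_false(isTRUE(all.equal(f_gt$beta6, f_lit$beta6)))
})

test_that("a planted male-specific effect dominates the genotype test", {
  # n = 900, rare allele (about 40 copies), effect only in boys
  n <- 900
  ranked_first <- vapply(1:20, function(seed) {
    set.seed(300 + seed)
    x1 <- rbinom(n, 1, 0.5); x2 <- runif(n)
    m <- 200
    g <- matrix(rbinom(n * m, 2, 0.022), n, m)
    x3 <- rbinom(n, 2, 0.45)
    ph <- 0.2 * x3 + rnorm(n, sd = 0.9)
    ph <- ph - 2.5 * g[, 1] * (x1 == 0)
    p_gt <- vapply(seq_len(m), function(j) {
      fit_snp_model(ph, x1, x2, x3, g[, j])$p_gt
    }, numeric(1))
    which.min(p_gt) == 1 && p_gt[1] < 5e-8
  }, logical(1))
  expect_gte(mean(ranked_first), 0.8)
})

test_that("permuting phenotypes destroys the signal", {
  n <- 900
  clean <- vapply(1:5, function(seed) {
    set.seed(400 + seed)
    x1 <- rbinom(n, 1, 0.5); x2 <- runif(n); x3 <- rbinom(n, 2, 0.45)
    g <- matrix(rbinom(n * 1000, 2, 0.2), n, 1000)
    ph <- sample(rnorm(n))  # permuted labels: pure noise
    p_gt <- vapply(seq_len(1000), function(j) {
      fit_snp_model(ph, x1, x2, x3, g[, j])$p_gt
    }, numeric(1))
    min(p_gt) > 5e-8
  }, logical(1))
  expect_gte(mean(clean), 0.95)
})

test_that("ancestry-effect regression recovers the simulated slope", {
  n <- 900
  set.seed(110)
  sex <- rbinom(n, 1, 0.5)
  qv <- as.matrix(simulate_admixture(n, seed = 111)[, "Mapuche"])[, 1]
  apv <- 12 - 1.9 * sex - 0.73 * qv + rnorm(n, sd = 0.8)
  est <- ancestry_effect_regression(apv, sex, qv)
  expect_lt(abs(est$effect - (-0.73)), 2 * est$se)
  expect_error(ancestry_effect_regression(apv, sex, rep(0.4, n)),
               "constant")
})

test_that("null ancestry effects are calibrated across seeds", {
  n <- 300
  covered <- vapply(1:100, function(seed) {
    set.seed(500 + seed)
    sex <- rbinom(n, 1, 0.5)
    qv <- runif(n)
    ph <- 10 + 0.5 * sex + rnorm(n)
    est <- ancestry_effect_regression(ph, sex, qv)
    abs(est$effect) < 2 * est$se
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("significance tiers follow the strict thresholds", {
  tab <- tibble::tibble(chrom = "10", pos = 1:4 * 100L,
                        p_gt = c(1.2e-8, 6.3e-8, 1e-5, 5e-8))
  lab <- classify_significance(tab)
  expect_equal(lab$sig_gt,
               c("genome-wide", "nominal", "none", "nominal"))
})

test_that("published association tables classify as reported", {
  t1 <- readr::read_tsv(system.file("extdata", "pv_hits_table.tsv",
                                    package = "pubgrowth"),
                        show_col_types = FALSE)
  lab <- classify_significance(t1)
  expect_equal(sum(lab$sig_gt == "genome-wide"), 2L)
  expect_equal(lab$id[lab$sig_gt == "genome-wide"],
               c("rs75297609", "rs57205007"))
  expect_equal(sum(lab$sig_gt == "nominal"), 6L)
  t2 <- readr::read_tsv(system.file("extdata", "pv_imputed_hits_table.tsv",
                                    package = "pubgrowth"),
                        show_col_types = FALSE)
  lab2 <- classify_significance(t2)
  expect_equal(lab2$id[lab2$sig_gt == "genome-wide"], "rs7919344")
})

test_that("manhattan export drops the flat floor and adds genome coordinates", {
  res <- tibble::tibble(chrom = c("1", "1", "2"), pos = c(10L, 20L, 5L),
                        p_gt = c(0.05, 1e-3, 1e-9))
  out <- manhattan_export(res)
  expect_false(any(out$pos == 10))   # -log10(0.05) = 1.3 < 2
  expect_true(any(out$pos == 20))    # 1e-3 retained
  expect_equal(out$cum_pos[out$chrom == "2"], 20 + 5)
  empty <- manhattan_export(res[0, ])
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("chrom", "pos", "cum_pos", "test", "neglog10p") %in%
                    names(empty)))
})
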