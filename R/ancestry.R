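#' Native American proportion from local-ancestry dosages
#'
#' The genome-wide mean of the per-variant Native American allele dosage,
#' divided by 2 — the local-ancestry-derived counterpart of the global
#' admixture proportion.
#'
#' @param la A `local_ancestry` object (or a bare N x M dosage matrix).
#' @return Tibble: `id`, `native_prop`.
#' @export
global_from_local <- function(la) {
  dosage <- if (inherits(la, "local_ancestry")) la$dosage else la
  if (length(dosage) == 0) stop("empty dosage matrix")
  ids <- if (inherits(la, "local_ancestry") && !is.null(la$ids)) {
    la$ids
  } else {
    rownames(dosage) %||% sprintf("ind%05d", seq_len(nrow(dosage)))
  }
  tibble::tibble(id = ids, native_prop = rowMeans(dosage) / 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Matrix EM over all individuals at once: per iteration the update is
# q_ik <- q_ik/(2 M_i) * [(Galt/Fbar) F' + (Gref/(1-Fbar)) (1-F)']_ik
# with Fbar = Q F, Galt the alt-allele counts and Gref = 2 - Galt
# (missing loci contribute zero on both sides and to M_i).
supervised_admixture_em <- function(g, freqs, tol = 1e-7,
                                    max_iter = 2000) {
  f <- pmin(pmax(freqs, 1e-4), 1 - 1e-4)
  K <- nrow(f); N <- nrow(g)
  galt <- g; galt[is.na(g)] <- 0
  gref <- 2 - g; gref[is.na(g)] <- 0
  storage.mode(galt) <- "double"; storage.mode(gref) <- "double"
  m_i <- rowSums(galt + gref) / 2
  if (any(m_i == 0)) stop("individual has no non-missing genotypes")
  tf <- t(f); tf1 <- t(1 - f)

  em_step <- function(Q) {
    fbar <- Q %*% f
    Qn <- Q * ((galt / fbar) %*% tf + (gref / (1 - fbar)) %*% tf1) /
      (2 * m_i)
    Qn / rowSums(Qn)  # guard against rounding drift
  }
  loglik <- function(Q) {
    fbar <- Q %*% f
    rowSums(galt * log(fbar) + gref * log1p(-fbar))
  }

  # EM with per-individual SQUAREM-style extrapolation; any extrapolated
  # step that would lower an individual's log-likelihood falls back to
  # the plain double EM step, so the likelihood never decreases
  Q <- matrix(1 / K, N, K)
  ll_old <- loglik(Q)
  iters <- rep(NA_integer_, N)
  converged <- rep(FALSE, N)
  it <- 0L
  while (it < max_iter) {
    Q1 <- em_step(Q)
    Q2 <- em_step(Q1)
    it <- it + 2L
    r <- Q1 - Q
    v <- Q2 - 2 * Q1 + Q
    alpha <- -sqrt(rowSums(r^2) / pmax(rowSums(v^2), 1e-300))
    alpha <- pmin(alpha, -1)
    Qp <- Q - 2 * alpha * r + alpha^2 * v
    Qp <- pmax(Qp, 1e-9)
    Qp <- Qp / rowSums(Qp)
    Q3 <- em_step(Qp)
    it <- it + 1L
    ll3 <- loglik(Q3)
    ll2 <- loglik(Q2)
    worse <- ll3 < ll2
    if (any(worse)) {
      Q3[worse, ] <- Q2[worse, , drop = FALSE]
      ll3[worse] <- ll2[worse]
    }
    if (any(ll3 < ll_old - 1e-6)) {
      stop("EM log-likelihood decreased; numerical failure")
    }
    done <- (ll3 - ll_old < tol) & !converged
    iters[done] <- it
    converged <- converged | done
    Q <- Q3
    ll_old <- ll3
    if (all(converged)) break
  }
  iters[is.na(iters)] <- it
  list(Q = Q, loglik = ll_old, iterations = iters, converged = converged)
}

#' Supervised maximum-likelihood global ancestry estimation
#'
#' Estimates each individual's admixture proportions `q` across the `K`
#' reference populations of a panel with known allele frequencies, by
#' maximizing the binomial likelihood
#' `sum_m [g log(fbar_m) + (2 - g) log(1 - fbar_m)]`,
#' `fbar_m = sum_k q_k f_km`, with an EM algorithm on the simplex started
#' from uniform proportions. Panel frequencies are clipped to
#' `[1e-4, 1 - 1e-4]`; missing genotypes are skipped. The per-individual
#' log-likelihood is checked to be non-decreasing at every iteration.
#'
#' @param geno A `cohort_genotypes` (or a bare N x M genotype matrix).
#' @param panel A `reference_panel` with `freqs` (K x M) and `labels`.
#' @param tol Log-likelihood increase below which EM stops.
#' @param max_iter Maximum EM iterations per individual.
#' @return Tibble: `id`, one proportion column per ancestry label,
#'   `loglik`, `iterations`, `converged`.
#' @export
supervised_admixture <- function(geno, panel, tol = 1e-7, max_iter = 2000) {
  g <- if (inherits(geno, "cohort_genotypes")) geno$g else geno
  ids <- if (inherits(geno, "cohort_genotypes")) {
    geno$ids
  } else {
    rownames(g) %||% sprintf("ind%05d", seq_len(nrow(g)))
  }
  if (ncol(g) != ncol(panel$freqs)) {
    stop("genotypes and panel disagree on variant count")
  }
  fit <- supervised_admixture_em(g, panel$freqs, tol, max_iter)
  qhat <- fit$Q
  colnames(qhat) <- panel$labels
  dplyr::bind_cols(
    tibble::tibble(id = ids),
    tibble::as_tibble(qhat),
    tibble::tibble(loglik = fit$loglik,
                   iterations = as.integer(fit$iterations),
                   converged = fit$converged))
}
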