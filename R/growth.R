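#' @importFrom stats quantile splinefun optim var sd median coef
NULL

# Natural-cubic-spline mean curve, stored as values at its knot nodes.
# A natural cubic spline is uniquely determined by its values at the node
# set {lower boundary, interior knots, upper boundary} together with the
# natural boundary conditions, so the regression fit obtained through
# splines::ns() can be re-expressed exactly (to machine precision) as
# stats::splinefun(method = "natural") through those nodes. That gives an
# analytic first derivative and linear extrapolation identical to ns().
new_spline_curve <- function(interior, boundary, values) {
  nodes <- c(boundary[1], interior, boundary[2])
  structure(list(interior = interior, boundary = boundary,
                 nodes = nodes, values = as.numeric(values)),
            class = "spline_curve")
}

curve_fun <- function(curve) {
  splinefun(curve$nodes, curve$values, method = "natural")
}

#' Evaluate a fitted mean curve or its velocity
#'
#' @param curve A `spline_curve` from [fit_growth_model()].
#' @param x Ages (transformed scale) to evaluate at.
#' @param deriv 0 for height, 1 for velocity.
#' @return Numeric vector.
#' @export
eval_curve <- function(curve, x, deriv = 0) {
  curve_fun(curve)(x, deriv = deriv)
}

spline_basis <- function(x, interior, boundary) {
  cbind(1, splines::ns(x, knots = interior, Boundary.knots = boundary))
}

#' Fit the shape-invariant growth model to one sex
#'
#' Fits `y_it = alpha_i + h((t - beta_i) / exp(gamma_i))` where `h` is a
#' natural cubic spline shared by all individuals of one sex and
#' `(alpha_i, beta_i, gamma_i)` are per-individual size, tempo and
#' log-velocity-scale effects.
#'
#' Estimation alternates two penalized least-squares steps until the
#' relative change in residual sum of squares falls below `tol`:
#' 1. given the effects, the spline coefficients are the ordinary
#'    least-squares fit of height offsets on the transformed-age basis;
#' 2. given the spline, each individual's `(alpha, beta, gamma)` minimizes
#'    its residual sum of squares plus ridge penalties
#'    `sigma^2_resid / sigma^2_effect` per effect, the effect variances
#'    being re-estimated from the current spread of the effects.
#' After convergence the effects are recentred to mean zero and the
#' spline refitted once, so the shifts are absorbed into `h`.
#'
#' `gamma` is box-constrained to `[-1.5, 1.5]` to rule out degenerate
#' time scalings.
#'
#' @param data Long-format heights tibble (`id`, `sex`, `age_years`,
#'   `height_cm`).
#' @param sex Which sex to fit (0 male, 1 female); rows of the other sex
#'   are dropped.
#' @param spline_df Number of interior knots, placed at age quantiles.
#' @param tol Relative RSS change declaring convergence.
#' @param max_iter Maximum alternating sweeps.
#' @param min_records Individuals with fewer records are excluded (with a
#'   warning).
#' @return An object of class `growth_fit`: effects tibble, `curve`
#'   (`spline_curve`), `sigma_resid`, effect SDs, `rss_trace`,
#'   `iterations`, `converged`, `excluded`.
#' @export
fit_growth_model <- function(data, sex, spline_df = 10, tol = 1e-6,
                             max_iter = 30, min_records = 4) {
  stopifnot(spline_df >= 4)
  d <- dplyr::filter(data, .data$sex == !!sex)
  if (nrow(d) == 0) stop("no records for requested sex")
  counts <- dplyr::count(d, .data$id)
  excluded <- counts$id[counts$n < min_records]
  if (length(excluded) > 0) {
    warning(sprintf("excluding %d individual(s) with < %d records",
                    length(excluded), min_records))
    d <- dplyr::filter(d, !.data$id %in% excluded)
  }
  d <- dplyr::arrange(d, .data$id, .data$age_years)
  ids <- unique(d$id)
  n_ind <- length(ids)
  idx <- split(seq_len(nrow(d)), factor(d$id, levels = ids))
  t_all <- d$age_years
  y_all <- d$height_cm
  n_obs <- length(y_all)

  knot_probs <- seq_len(spline_df) / (spline_df + 1)
  interior <- unname(quantile(t_all, probs = knot_probs))
  boundary <- range(t_all) + c(-1, 1)

  alpha <- numeric(n_ind); beta <- numeric(n_ind); gamma <- numeric(n_ind)
  # effect-variance priors for the first sweep, before any spread exists
  s2 <- c(alpha = 25, beta = 0.49, gamma = 0.0144)
  var_floor <- c(alpha = 1e-8, beta = 1e-10, gamma = 1e-12)

  fit_spline <- function() {
    x <- (t_all - rep(beta, lengths(idx))) / exp(rep(gamma, lengths(idx)))
    z <- y_all - rep(alpha, lengths(idx))
    # knots track the quantiles of the *transformed* ages, where the
    # curve actually lives once tempo/velocity effects are estimated
    interior <<- unname(quantile(x, probs = knot_probs))
    boundary <<- range(c(boundary, min(x) - 0.5, max(x) + 0.5))
    X <- spline_basis(x, interior, boundary)
    cf <- qr.coef(qr(X), z)
    vals <- spline_basis(c(boundary[1], interior, boundary[2]),
                         interior, boundary) %*% cf
    curve <- new_spline_curve(interior, boundary, vals)
    rss <- sum((z - X %*% cf)^2)
    list(curve = curve, rss = rss)
  }

  sf <- NULL
  obj_i <- function(par, tt, yy, lam) {
    a <- par[1]; b <- par[2]; g <- par[3]
    r <- yy - a - sf((tt - b) / exp(g))
    sum(r^2) + lam[1] * a^2 + lam[2] * b^2 + lam[3] * g^2
  }
  grad_i <- function(par, tt, yy, lam) {
    a <- par[1]; b <- par[2]; g <- par[3]
    x <- (tt - b) / exp(g)
    pred <- sf(x)
    dv <- sf(x, deriv = 1)
    r <- yy - a - pred
    c(-2 * sum(r) + 2 * lam[1] * a,
      2 * sum(r * dv) * exp(-g) + 2 * lam[2] * b,
      2 * sum(r * dv * x) + 2 * lam[3] * g)
  }

  rss_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  curve <- NULL
  repeat {
    iter <- iter + 1L
    sp <- fit_spline()
    curve <- sp$curve
    rss_trace <- c(rss_trace, sp$rss)
    k <- length(rss_trace)
    if (k > 1) {
      rel <- (rss_trace[k - 1] - rss_trace[k]) /
        max(rss_trace[k - 1], 1e-12)
      if (abs(rel) < tol) { converged <- TRUE; break }
    }
    if (iter >= max_iter) break
    sigma2 <- max(sp$rss / n_obs, 1e-10)
    if (iter > 1L) {
      s2 <- pmax(c(mean(alpha^2), mean(beta^2), mean(gamma^2)), var_floor)
      names(s2) <- c("alpha", "beta", "gamma")
    }
    lam <- sigma2 / s2
    sf <- curve_fun(curve)
    for (j in seq_len(n_ind)) {
      ii <- idx[[j]]
      o <- optim(c(alpha[j], beta[j], gamma[j]), obj_i, grad_i,
                 tt = t_all[ii], yy = y_all[ii], lam = lam,
                 method = "L-BFGS-B",
                 lower = c(-Inf, -6, -1.5), upper = c(Inf, 6, 1.5))
      alpha[j] <- o$par[1]; beta[j] <- o$par[2]; gamma[j] <- o$par[3]
    }
    # recentre each sweep; the next spline refit absorbs the shifts,
    # keeping the mean-effect flat direction from wandering
    alpha <- alpha - mean(alpha)
    beta <- beta - mean(beta)
    gamma <- gamma - mean(gamma)
  }

  # identifiability centring: shifts absorbed into the refitted spline
  alpha <- alpha - mean(alpha)
  beta <- beta - mean(beta)
  gamma <- gamma - mean(gamma)
  sp <- fit_spline()
  curve <- sp$curve
  p_eff <- length(curve$nodes) + 1L
  sigma_resid <- sqrt(sp$rss / max(n_obs - p_eff, 1))

  structure(list(
    sex = sex,
    effects = tibble::tibble(id = ids, alpha = alpha, beta = beta,
                             gamma = gamma,
                             n_records = lengths(idx)),
    curve = curve,
    sigma_resid = sigma_resid,
    sd_effects = c(alpha = sd(alpha), beta = sd(beta), gamma = sd(gamma)),
    rss = sp$rss,
    rss_trace = rss_trace,
    n_obs = n_obs,
    iterations = iter,
    converged = converged,
    excluded = excluded
  ), class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    "<growth_fit> sex=%d: %d individuals, %d records; sigma=%.3f cm; %s after %d sweeps\n",
    x$sex, nrow(x$effects), x$n_obs, x$sigma_resid,
    if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

fit_effects_row <- function(fit, individual) {
  j <- match(individual, fit$effects$id)
  if (is.na(j)) stop("unknown individual: ", individual)
  fit$effects[j, ]
}

#' Predicted height for one individual
#'
#' @param fit A `growth_fit`.
#' @param individual Individual id.
#' @param ages Ages in years.
#' @return Heights in cm.
#' @export
predict_height <- function(fit, individual, ages) {
  e <- fit_effects_row(fit, individual)
  e$alpha + eval_curve(fit$curve, (ages - e$beta) / exp(e$gamma))
}

#' Height velocity for one individual
#'
#' Analytic derivative of the individual's predicted height:
#' `h'((t - beta_i) / exp(gamma_i)) * exp(-gamma_i)`.
#'
#' @param fit A `growth_fit`.
#' @param individual Individual id.
#' @param ages Ages in years.
#' @return Velocities in cm/year.
#' @export
velocity_curve <- function(fit, individual, ages) {
  e <- fit_effects_row(fit, individual)
  x <- (ages - e$beta) / exp(e$gamma)
  eval_curve(fit$curve, x, deriv = 1) * exp(-e$gamma)
}

default_search_range <- function(sex) if (sex == 0) c(9, 16) else c(8, 14)

#' Extract PV, APV and HAPV for fitted individuals
#'
#' The age at peak velocity is the argmax of the individual's velocity
#' curve on a fine grid over the pubertal search window (default 9-16
#' years for boys, 8-14 for girls), refined by quadratic interpolation
#' around the grid maximum; ties break to the earliest age. PV is the
#' velocity there and HAPV the predicted height. A landmark whose grid
#' maximum sits on the search boundary is flagged censored (and not
#' refined).
#'
#' @param fit A `growth_fit`.
#' @param individuals Ids to extract; default all fitted individuals.
#' @param search_range Length-2 ages delimiting the search; default by sex.
#' @param grid_step Grid resolution in years.
#' @return Tibble: `id`, `sex`, `pv`, `apv`, `hapv`, `censored`.
#' @export
extract_landmarks <- function(fit, individuals = NULL, search_range = NULL,
                              grid_step = 0.01) {
  if (is.null(individuals)) individuals <- fit$effects$id
  if (is.null(search_range)) search_range <- default_search_range(fit$sex)
  sf <- curve_fun(fit$curve)
  res <- purrr::map_dfr(individuals, function(ind) {
    e <- fit_effects_row(fit, ind)
    grid <- seq(search_range[1], search_range[2], by = grid_step)
    x <- (grid - e$beta) / exp(e$gamma)
    v <- sf(x, deriv = 1) * exp(-e$gamma)
    i <- which.max(v)
    censored <- i == 1L || i == length(grid)
    apv <- grid[i]
    if (!censored) {
      num <- v[i - 1L] - v[i + 1L]
      den <- v[i - 1L] - 2 * v[i] + v[i + 1L]
      if (is.finite(den) && abs(den) > 0) {
        apv <- grid[i] + grid_step * num / (2 * den)
      }
    }
    xa <- (apv - e$beta) / exp(e$gamma)
    tibble::tibble(id = ind, sex = fit$sex,
                   pv = sf(xa, deriv = 1) * exp(-e$gamma),
                   apv = apv,
                   hapv = e$alpha + sf(xa),
                   censored = censored)
  })
  res
}

#' Fit both sexes and derive pubertal phenotypes
#'
#' Convenience wrapper: fits the shape-invariant model separately to boys
#' and girls and extracts (PV, APV, HAPV) for every retained individual.
#'
#' @param data Long-format heights tibble.
#' @param ... Passed to [fit_growth_model()].
#' @return List with `phenotypes` (tibble: id, sex, pv, apv, hapv,
#'   censored) and `fits` (list of the two `growth_fit` objects, named
#'   "male", "female").
#' @export
derive_phenotypes <- function(data, ...) {
  sexes <- sort(unique(data$sex))
  fits <- list()
  phen <- list()
  for (s in sexes) {
    f <- fit_growth_model(data, sex = s, ...)
    key <- if (s == 0) "male" else "female"
    fits[[key]] <- f
    phen[[key]] <- extract_landmarks(f)
  }
  list(phenotypes = dplyr::bind_rows(phen), fits = fits)
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' Per-individual random effects of a growth fit
#'
#' @param x A `growth_fit`.
#' @param ... Unused.
#' @return Tibble with one row per individual: `id`, `alpha` (cm), `beta`
#'   (years), `gamma` (log velocity scale), `n_records`.
#' @export
tidy.growth_fit <- function(x, ...) x$effects

#' One-row summary of a growth fit
#'
#' @param x A `growth_fit`.
#' @param ... Unused.
#' @return One-row tibble with fit-level statistics.
#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(
    sex = x$sex, n_individuals = nrow(x$effects), n_obs = x$n_obs,
    sigma_resid = x$sigma_resid,
    sd_alpha = x$sd_effects[["alpha"]], sd_beta = x$sd_effects[["beta"]],
    sd_gamma = x$sd_effects[["gamma"]],
    rss = x$rss, iterations = x$iterations, converged = x$converged
  )
}

#' Plot the fitted mean curve and its velocity
#'
#' @param object A `growth_fit`.
#' @param ... Unused.
#' @return A ggplot with height and velocity panels over age.
#' @export
autoplot.growth_fit <- function(object, ...) {
  rng <- object$curve$boundary
  ages <- seq(rng[1] + 0.5, rng[2] - 0.5, by = 0.05)
  sf <- curve_fun(object$curve)
  df <- tibble::tibble(
    age = rep(ages, 2),
    value = c(sf(ages), sf(ages, deriv = 1)),
    panel = rep(c("height (cm)", "velocity (cm/year)"), each = length(ages))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~panel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "age (years)", y = NULL,
                  title = sprintf("Mean growth curve (%s)",
                                  if (object$sex == 0) "boys" else "girls"))
}

#' @export
#' @importFrom ggplot2 autoplot
ggplot2::autoplot
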