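#' Kernel density model of the log10-ED50 distribution
#'
#' Approximates the empirical distribution of the per-individual `a`
#' values (log10 ED50) with a Gaussian kernel density estimate computed by
#' [KernSmooth::bkde()], and precomputes the cumulative distribution (by
#' trapezoidal integration, renormalized to 1) so virtual individuals can
#' be drawn by inverse-transform sampling. The grid is truncated at
#' positive `a`: the dose-response model requires `a > 0`.
#'
#' @param raw A data frame of raw estimates with at least column `a`
#'   (see [generate_raw_estimates()] for the expected shape).
#' @param bandwidth Kernel standard deviation; default `NULL` uses
#'   Silverman's normal-reference rule ([stats::bw.nrd0()]).
#' @param gridsize Number of grid points (default 401).
#' @param range_a Optional length-2 grid range; default extends the data
#'   range by 3 bandwidths, floored at a small positive value.
#'
#' @return An object of class `mel_adist`: a list with elements `grid`,
#'   `density`, `cdf`, `a50` (the distribution median), `bandwidth`, `n`.
#' @examples
#' ad <- fit_a_distribution(generate_raw_estimates())
#' ad$a50
#' @export
fit_a_distribution <- function(raw, bandwidth = NULL, gridsize = 401L,
                               range_a = NULL) {
  stopifnot(is.data.frame(raw), "a" %in% names(raw))
  a <- raw$a
  if (length(a) < 5) {
    stop("At least 5 individuals are required to fit the a-distribution.",
         call. = FALSE)
  }
  if (any(!is.finite(a)) || any(a <= 0)) {
    stop("Column `a` must be finite and strictly positive.", call. = FALSE)
  }
  if (stats::sd(a) == 0) {
    stop("Column `a` is constant; a kernel density over `a` is degenerate.",
         call. = FALSE)
  }
  bw <- bandwidth %||% stats::bw.nrd0(a)
  rng <- range_a %||% c(max(min(a) - 3 * bw, 1e-8), max(a) + 3 * bw)
  kde <- KernSmooth::bkde(a, bandwidth = bw, gridsize = gridsize,
                          range.x = rng)
  dens <- pmax(kde$y, 0)
  cdf <- cumtrapz(kde$x, dens)
  total <- cdf[length(cdf)]
  if (total <= 0) stop("Kernel density integrated to zero.", call. = FALSE)
  dens <- dens / total
  cdf <- cdf / total
  out <- list(grid = kde$x, density = dens, cdf = cdf,
              a50 = inv_cdf(kde$x, cdf, 0.5),
              bandwidth = bw, n = length(a))
  class(out) <- "mel_adist"
  out
}

#' Draw log10-ED50 values from a fitted kernel density
#'
#' Inverse-transform sampling from the CDF of a [fit_a_distribution()]
#' object, by monotone linear interpolation of the gridded CDF.
#'
#' @param adist A `mel_adist` object.
#' @param n Number of draws (ignored when `u` is supplied).
#' @param u Optional uniform(0,1) variates to transform; useful for
#'   common-random-number schemes.
#' @return Numeric vector of sampled `a` values.
#' @export
sample_a <- function(adist, n, u = NULL) {
  stopifnot(inherits(adist, "mel_adist"))
  u <- u %||% stats::runif(n)
  inv_cdf(adist$grid, adist$cdf, u)
}

cumtrapz <- function(x, y) {
  c(0, cumsum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
}

# invert a gridded nondecreasing CDF by linear interpolation
inv_cdf <- function(grid, cdf, u) {
  keep <- c(TRUE, diff(cdf) > 0)
  stats::approx(cdf[keep], grid[keep], xout = u, rule = 2)$y
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- Bayesian fits (JAGS) ------------------------------------------------

# The statistical model is
#   log b_i ~ normal(alpha + beta * a_i, sigma0 + sigma1 * a_i)
# with priors alpha, beta ~ normal(0, 1) and sigma0, sigma1 ~ half-Cauchy(0, 1).
# It is sampled in a centered parameterization (intercept and residual SD
# evaluated at abar = mean(a)) because the raw (alpha, beta) and
# (sigma0, sigma1) pairs are almost perfectly negatively correlated in the
# posterior, which cripples single-site samplers. The change of variables is
# a pure location shift with unit Jacobian and the shifted priors are written
# out exactly (alpha_c ~ normal(beta * abar, 1); sc - sigma1 * abar
# half-Cauchy), so the posterior is identical to the uncentered model.
regression_model_string <- "
model {
  for (i in 1:n) {
    mu[i] <- alpha_c + beta * (a[i] - abar)
    sdv[i] <- sc + sigma1 * (a[i] - abar)
    logb[i] ~ dnorm(mu[i], 1 / (sdv[i] * sdv[i]))
  }
  beta ~ dnorm(0, 1)
  alpha_c ~ dnorm(beta * abar, 1)
  alpha <- alpha_c - beta * abar
  sigma1 ~ dt(0, 1, 1) T(0,)
  sc ~ dt(sigma1 * abar, 1, 1) T(sigma1 * abar,)
  sigma0 <- sc - sigma1 * abar
}"

prior_only_regression_string <- "
model {
  alpha ~ dnorm(0, 1)
  beta ~ dnorm(0, 1)
  sigma0 ~ dt(0, 1, 1) T(0,)
  sigma1 ~ dt(0, 1, 1) T(0,)
}"

# sigma_i ~ gamma(c, d) with c, d ~ half-Cauchy(0, 1). Sampled as
# (c, mc = c/d): shape and mean are nearly independent in the posterior,
# unlike (c, d) which are almost collinear. The half-Cauchy prior on
# d = c/mc plus the Jacobian c/mc^2 of the change of variables is imposed
# through the standard Poisson zeros trick, so the (c, d) posterior is
# exactly that of the plain parameterization.
gamma_model_string <- "
model {
  for (i in 1:n) {
    sigma[i] ~ dgamma(c, d)
  }
  c ~ dt(0, 1, 1) T(0,)
  mc ~ dunif(0, 1000)
  d <- c / mc
  phi <- 100 - (log(2 / 3.141592653589793) - log(1 + d * d)
                + log(c) - 2 * log(mc))
  zero ~ dpois(phi)
}"

# run a JAGS model and return draws as a tibble with .chain/.iteration
run_jags <- function(model_string, data, params, chains, iter, warmup,
                     thin, adapt, seed, inits_extra = list()) {
  chain_seeds <- derive_seeds(seed, chains)
  inits <- lapply(chain_seeds, function(s) {
    c(list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = s),
      inits_extra)
  })
  result <- tryCatch({
    jm <- rjags::jags.model(textConnection(model_string), data = data,
                            inits = inits, n.chains = chains,
                            n.adapt = adapt, quiet = TRUE)
    stats::update(jm, n.iter = warmup, progress.bar = "none")
    rjags::coda.samples(jm, variable.names = params,
                        n.iter = iter - warmup, thin = thin,
                        progress.bar = "none")
  }, error = function(e) {
    stop("MCMC sampler failure: ", conditionMessage(e),
         "\n  model parameters: ", paste(params, collapse = ", "),
         "\n  data sizes: ", paste(names(data), lengths(data),
                                   sep = "=", collapse = ", "),
         call. = FALSE)
  })
  purrr::imap_dfr(result, function(ch, i) {
    out <- tibble::as_tibble(as.matrix(ch))[, params]
    out$.chain <- as.integer(i)
    out$.iteration <- seq_len(nrow(out))
    out
  })
}

# reproducible 31-bit seeds for chains / cells derived from one master seed
derive_seeds <- function(seed, n, offset = 0L) {
  if (is.null(seed)) {
    return(sample.int(2147483646L, n))
  }
  vapply(seq_len(n) + offset, function(k) {
    as.integer((as.double(seed) %% 2147483647 * 48271 + 104729 * k) %%
                 2147483647) + 1L
  }, integer(1))
}

new_mel_fit <- function(draws, diagnostics, protocol, class) {
  converged <- converged_gate(diagnostics)
  if (!converged) {
    warning("MCMC did not pass the convergence gate (max R-hat < 1.01, ",
            "min bulk/tail ESS > 400); the fit is flagged non-converged. ",
            "Max R-hat = ", signif(max(diagnostics$rhat), 4),
            ", min ESS = ",
            signif(min(diagnostics$ess_bulk, diagnostics$ess_tail), 4), ".",
            call. = FALSE)
  }
  structure(list(draws = draws, diagnostics = diagnostics,
                 converged = converged, protocol = protocol),
            class = c(class, "mel_fit"))
}

#' Bayesian heteroscedastic regression of log b on a
#'
#' Fits the conditional model of the curve shape given sensitivity,
#' `log(b_i) ~ normal(alpha + beta * a_i, sigma0 + sigma1 * a_i)`, whose
#' residual standard deviation grows linearly with `a` (both `sigma0` and
#' `sigma1` positive). Priors are `normal(0, 1)` on `alpha` and `beta`
#' and half-Cauchy(0, 1) on `sigma0` and `sigma1`. Sampling uses JAGS with
#' 4 chains of 4000 iterations (2000 warm-up, post-warm-up draws thinned
#' by 2) by default; convergence is gated on rank-normalized split
#' R-hat < 1.01 and bulk/tail ESS > 400, and a fit failing the gate is
#' returned flagged with a warning, never silently.
#'
#' @param raw A raw-estimates data frame with positive columns `a`, `b`
#'   (and `rmse`); at least 5 rows.
#' @param chains,iter,warmup,thin,adapt MCMC protocol (iterations are per
#'   chain and include warm-up).
#' @param seed Integer seed; chain RNG seeds are derived from it.
#' @param prior_only If `TRUE`, sample the priors with the likelihood
#'   removed (for prior predictive checks).
#'
#' @return An object of class `mel_regression` with elements `draws`
#'   (tibble: `alpha`, `beta`, `sigma0`, `sigma1`, `.chain`,
#'   `.iteration`), `diagnostics`, `converged`, `protocol`.
#' @examples
#' \donttest{
#' fit <- fit_logb_regression(generate_raw_estimates(), seed = 1)
#' glance(fit)
#' }
#' @export
fit_logb_regression <- function(raw, chains = 4, iter = 4000, warmup = 2000,
                                thin = 2, adapt = 1000, seed = NULL,
                                prior_only = FALSE) {
  params <- c("alpha", "beta", "sigma0", "sigma1")
  if (prior_only) {
    draws <- run_jags(prior_only_regression_string, data = list(), params,
                      chains, iter, warmup, thin, adapt, seed)
  } else {
    validate_raw_estimates(raw)
    draws <- run_jags(regression_model_string,
                      data = list(n = nrow(raw), a = raw$a,
                                  logb = log(raw$b), abar = mean(raw$a)),
                      params, chains, iter, warmup, thin, adapt, seed)
  }
  diagnostics <- compute_diagnostics(draws)
  new_mel_fit(draws, diagnostics,
              protocol = list(chains = chains, iter = iter, warmup = warmup,
                              thin = thin, seed = seed,
                              prior_only = prior_only),
              class = "mel_regression")
}

#' Gamma population model of measurement-noise levels
#'
#' Fits `sigma_i ~ gamma(c, d)` (shape-rate parameterization) to the
#' calibrated per-individual logit-scale noise levels, with half-Cauchy(0, 1)
#' priors on both parameters. Default protocol: 4 chains of 2000
#' iterations, 1000 warm-up, no thinning. Convergence gating as in
#' [fit_logb_regression()]; degenerate inputs (for example a single
#' repeated value) surface as a flagged non-converged fit rather than a
#' crash.
#'
#' @param sigmas Positive numeric vector of noise levels, or a data frame
#'   with a `sigma` column (as written by [calibrate_sigmas()]); at least
#'   5 values.
#' @inheritParams fit_logb_regression
#'
#' @return An object of class `mel_noise` with posterior draws of `c` and
#'   `d` plus diagnostics.
#' @export
fit_sigma_population <- function(sigmas, chains = 4, iter = 2000,
                                 warmup = 1000, thin = 1, adapt = 1000,
                                 seed = NULL) {
  if (is.data.frame(sigmas)) {
    stopifnot("sigma" %in% names(sigmas))
    sigmas <- sigmas$sigma
  }
  if (length(sigmas) < 5) {
    stop("At least 5 noise levels are required.", call. = FALSE)
  }
  if (any(!is.finite(sigmas)) || any(sigmas <= 0)) {
    stop("All noise levels must be finite and strictly positive.",
         call. = FALSE)
  }
  draws <- run_jags(gamma_model_string,
                    data = list(n = length(sigmas), sigma = sigmas,
                                zero = 0),
                    params = c("c", "d"), chains, iter, warmup, thin,
                    adapt, seed,
                    inits_extra = list(c = 1, mc = mean(sigmas)))
  diagnostics <- compute_diagnostics(draws)
  new_mel_fit(draws, diagnostics,
              protocol = list(chains = chains, iter = iter, warmup = warmup,
                              thin = thin, seed = seed),
              class = "mel_noise")
}

#' Posterior predictive ribbon for the log-b regression
#'
#' For a grid of `a` values, simulates one predictive `b` per posterior
#' draw and grid point and returns the 2.5/50/97.5 percent predictive
#' quantiles (back-transformed from log b). On well-specified data about
#' 95 percent of the raw `(a_i, b_i)` points should fall inside the outer
#' ribbon.
#'
#' @param fit A `mel_regression` object.
#' @param raw The raw-estimates data frame the model was fitted to (used
#'   for the default grid).
#' @param a_grid Optional evaluation grid; default 50 points spanning the
#'   raw `a` range.
#' @param probs Predictive quantiles to report.
#' @param seed Integer seed for the predictive simulation.
#'
#' @return A tibble with columns `a` and one column per quantile
#'   (`lower`, `median`, `upper` for the default `probs`).
#' @export
ppc_regression <- function(fit, raw, a_grid = NULL,
                           probs = c(0.025, 0.5, 0.975), seed = NULL) {
  stopifnot(inherits(fit, "mel_regression"))
  a_grid <- a_grid %||% seq(min(raw$a), max(raw$a), length.out = 50)
  d <- fit$draws
  m <- nrow(d)
  qs <- withr::with_seed(seed %||% sample.int(2147483646L, 1), {
    vapply(a_grid, function(a) {
      mu <- d$alpha + d$beta * a
      sdv <- d$sigma0 + d$sigma1 * a
      if (any(sdv <= 0)) {
        stop("Nonpositive residual SD evaluated at a = ", a, call. = FALSE)
      }
      b_pred <- exp(stats::rnorm(m, mu, sdv))
      stats::quantile(b_pred, probs = probs, names = FALSE)
    }, numeric(length(probs)))
  })
  qm <- t(qs)
  colnames(qm) <- if (identical(probs, c(0.025, 0.5, 0.975))) {
    c("lower", "median", "upper")
  } else {
    paste0("q", probs * 100)
  }
  out <- tibble::as_tibble(qm)
  dplyr::bind_cols(tibble::tibble(a = a_grid), out)
}

#' @param ribbon A ribbon table from [ppc_regression()].
#' @return `ppc_coverage()`: the fraction of raw points inside the outer
#'   ribbon (interpolated at each raw `a`).
#' @rdname ppc_regression
#' @export
ppc_coverage <- function(ribbon, raw) {
  lo <- stats::approx(ribbon$a, ribbon$lower, xout = raw$a, rule = 2)$y
  hi <- stats::approx(ribbon$a, ribbon$upper, xout = raw$a, rule = 2)$y
  mean(raw$b >= lo & raw$b <= hi)
}

# ---- broom-style methods -------------------------------------------------

#' Tidy posterior summaries of a fitted model component
#'
#' @param x A `mel_regression` or `mel_noise` fit.
#' @param conf_level Width of the central credible interval.
#' @param ... Unused.
#' @return A tibble with one row per parameter: posterior mean, sd,
#'   credible bounds, R-hat and ESS diagnostics.
#' @method tidy mel_fit
#' @export
tidy.mel_fit <- function(x, conf_level = 0.95, ...) {
  lo <- (1 - conf_level) / 2
  params <- setdiff(names(x$draws), c(".chain", ".iteration"))
  est <- purrr::map_dfr(params, function(p) {
    v <- x$draws[[p]]
    tibble::tibble(
      parameter = p,
      estimate = mean(v),
      std.error = stats::sd(v),
      conf.low = stats::quantile(v, lo, names = FALSE),
      conf.high = stats::quantile(v, 1 - lo, names = FALSE)
    )
  })
  dplyr::left_join(est, x$diagnostics, by = "parameter")
}

#' @method tidy mel_regression
#' @export
tidy.mel_regression <- tidy.mel_fit

#' @method tidy mel_noise
#' @export
tidy.mel_noise <- tidy.mel_fit

#' One-row summary of a fitted model component
#'
#' @param x A `mel_regression` or `mel_noise` fit.
#' @param ... Unused.
#' @return A tibble with draw counts, worst-case diagnostics and the
#'   convergence flag.
#' @method glance mel_fit
#' @export
glance.mel_fit <- function(x, ...) {
  tibble::tibble(
    n_draws = nrow(x$draws),
    n_chains = length(unique(x$draws$.chain)),
    max_rhat = max(x$diagnostics$rhat),
    min_ess = min(x$diagnostics$ess_bulk, x$diagnostics$ess_tail),
    converged = x$converged
  )
}

#' @method glance mel_regression
#' @export
glance.mel_regression <- glance.mel_fit

#' @method glance mel_noise
#' @export
glance.mel_noise <- glance.mel_fit

#' @export
print.mel_fit <- function(x, ...) {
  cat("<", class(x)[1], "> ", nrow(x$draws), " posterior draws, ",
      length(unique(x$draws$.chain)), " chains, ",
      if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  print(tidy.mel_fit(x))
  invisible(x)
}
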