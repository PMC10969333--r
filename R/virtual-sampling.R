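#' Assemble a sampleable population model
#'
#' Combines the three fitted components — the kernel density over `a`
#' (log10 ED50), the heteroscedastic log-b regression posterior and the
#' gamma measurement-noise posterior — with plausibility bounds derived
#' from the raw estimates: a virtual individual's ED25 may not fall below
#' half the minimum raw ED25 and its ED75 may not exceed 1.5 times the
#' maximum raw ED75. Candidates outside these bounds are rejected during
#' sampling, keeping virtual curves no more extreme than those observed.
#'
#' @param adist A `mel_adist` from [fit_a_distribution()].
#' @param regression A `mel_regression` from [fit_logb_regression()].
#' @param noise A `mel_noise` from [fit_sigma_population()].
#' @param raw The raw-estimates table the components were fitted to
#'   (columns `a`, `b`), used to compute the rejection bounds.
#'
#' @return An object of class `mel_popmodel`.
#' @seealso [fit_population_model()] for the one-call pipeline.
#' @export
population_model <- function(adist, regression, noise, raw) {
  stopifnot(inherits(adist, "mel_adist"),
            inherits(regression, "mel_regression"),
            inherits(noise, "mel_noise"))
  validate_raw_estimates(raw, min_n = 1)
  if (!regression$converged || !noise$converged) {
    warning("Building a population model from a fit flagged non-converged.",
            call. = FALSE)
  }
  ed25_floor <- 0.5 * min(effective_dose(0.25, raw$a, raw$b))
  ed75_ceiling <- 1.5 * max(effective_dose(0.75, raw$a, raw$b))
  stopifnot(ed25_floor > 0, ed25_floor < ed75_ceiling)
  structure(list(adist = adist, regression = regression, noise = noise,
                 ed25_floor = ed25_floor, ed75_ceiling = ed75_ceiling),
            class = "mel_popmodel")
}

#' Fit the full population model in one call
#'
#' Convenience pipeline: kernel density over `a`, Bayesian log-b
#' regression, per-individual noise calibration against the observed
#' RMSEs, gamma noise-population fit, and assembly into a
#' [population_model()].
#'
#' @param raw Raw-estimates table with columns `a`, `b`, `rmse`.
#' @param grid Measurement grid used for noise calibration.
#' @param seed Master seed; component seeds are derived from it.
#' @param regression_args,noise_args,calibration_args Named lists of
#'   extra arguments for the component fits.
#' @return A `mel_popmodel`.
#' @export
fit_population_model <- function(raw, grid = default_measurement_grid(),
                                 seed = NULL, regression_args = list(),
                                 noise_args = list(),
                                 calibration_args = list()) {
  validate_raw_estimates(raw)
  seeds <- derive_seeds(seed, 3)
  adist <- fit_a_distribution(raw)
  regression <- do.call(fit_logb_regression,
                        c(list(raw = raw, seed = seeds[1]), regression_args))
  calibrated <- do.call(calibrate_sigmas,
                        c(list(raw = raw, grid = grid, seed = seeds[2]),
                          calibration_args))
  noise <- do.call(fit_sigma_population,
                   c(list(sigmas = calibrated, seed = seeds[3]), noise_args))
  population_model(adist, regression, noise, raw)
}

#' @export
print.mel_popmodel <- function(x, ...) {
  cat("<mel_popmodel>\n",
      "  a-distribution: n = ", x$adist$n, ", a50 = ",
      signif(x$adist$a50, 4), "\n",
      "  regression: ", nrow(x$regression$draws), " draws, ",
      if (x$regression$converged) "converged" else "NOT converged", "\n",
      "  noise model: ", nrow(x$noise$draws), " draws, ",
      if (x$noise$converged) "converged" else "NOT converged", "\n",
      "  rejection bounds: ED25 >= ", signif(x$ed25_floor, 4),
      " lux, ED75 <= ", signif(x$ed75_ceiling, 4), " lux\n", sep = "")
  invisible(x)
}

# draw per-individual measurement-noise levels: for each individual a
# (c, d) pair is sampled uniformly from the noise posterior, then
# sigma ~ gamma(c, d)
draw_sigmas <- function(model, n) {
  nd <- model$noise$draws
  idx <- sample.int(nrow(nd), n, replace = TRUE)
  stats::rgamma(n, shape = nd$c[idx], rate = nd$d[idx])
}

# vectorized rejection sampler shared by the unrestricted (eta = 1,
# joint posterior draw per individual) and variance-reduced processes
sample_curves <- function(model, n, eta, max_attempts) {
  rd <- model$regression$draws
  m <- nrow(rd)
  if (eta < 1) {
    # shrink every stored (alpha, beta) draw towards its posterior mean
    alpha <- rd$alpha + (mean(rd$alpha) - rd$alpha) * (1 - eta)
    beta <- rd$beta + (mean(rd$beta) - rd$beta) * (1 - eta)
  } else {
    alpha <- rd$alpha
    beta <- rd$beta
  }
  a_out <- b_out <- numeric(n)
  pending <- seq_len(n)
  attempts <- integer(n)
  while (length(pending)) {
    k <- length(pending)
    attempts[pending] <- attempts[pending] + 1L
    if (any(attempts > max_attempts)) {
      stop("Rejection sampling exceeded ", max_attempts, " attempts for ",
           "an individual; the population model appears inconsistent with ",
           "its own ED25/ED75 bounds.", call. = FALSE)
    }
    idx <- sample.int(m, k, replace = TRUE)
    a_cand <- sample_a(model$adist, k)
    if (eta < 1) {
      # independent draw index for the (unshrunk) noise-scale parameters
      idx_s <- sample.int(m, k, replace = TRUE)
      a_cand <- a_cand + (model$adist$a50 - a_cand) * (1 - eta)
      sdv <- eta * (rd$sigma0[idx_s] + rd$sigma1[idx_s] * a_cand)
    } else {
      sdv <- rd$sigma0[idx] + rd$sigma1[idx] * a_cand
    }
    b_cand <- exp(stats::rnorm(k, alpha[idx] + beta[idx] * a_cand, sdv))
    ok <- a_cand > 0 & b_cand > 0 &
      effective_dose(0.25, pmax(a_cand, 1e-12), b_cand) >=
        model$ed25_floor &
      effective_dose(0.75, pmax(a_cand, 1e-12), b_cand) <=
        model$ed75_ceiling
    take <- pending[ok]
    a_out[take] <- a_cand[ok]
    b_out[take] <- b_cand[ok]
    pending <- pending[!ok]
  }
  tibble::tibble(a = a_out, b = b_out)
}

#' Sample virtual individuals from the population model
#'
#' `sample_individuals()` draws `n` virtual individuals by the
#' unrestricted process: `a` by inverse-transform sampling from the
#' kernel density, one posterior draw of `(alpha, beta, sigma0, sigma1)`
#' sampled uniformly per individual (so fitting uncertainty contributes
#' to between-individual variation), `log b` from the conditional normal,
#' and rejection of candidates violating the ED25/ED75 plausibility
#' bounds. Each individual also receives a measurement-noise level
#' `sigma` drawn from the gamma noise model under a uniformly sampled
#' posterior draw of `(c, d)`.
#'
#' `sample_individuals_reduced()` modulates individual heterogeneity with
#' `eta` in `[0, 1]`: all stored posterior draws of `alpha` and `beta`
#' are first shrunk towards their posterior means by the factor `eta`,
#' the sampled `a` is shrunk towards the distribution median `a50`, and
#' the conditional standard deviation is scaled by `eta` (the `sigma0`,
#' `sigma1` draws themselves are used unshrunk). `eta = 1` reproduces the
#' unrestricted process; `eta = 0` yields deterministic copies of the
#' median individual (`a = a50`, `log b` at the posterior-mean regression
#' line, zero conditional spread).
#'
#' @param model A `mel_popmodel`.
#' @param n Number of individuals.
#' @param eta Heterogeneity level in `[0, 1]`.
#' @param seed Optional integer seed.
#' @param max_attempts Rejection-loop cap per individual before erroring.
#'
#' @return A tibble with columns `individual_id`, `a`, `b`, `sigma`.
#' @export
sample_individuals <- function(model, n, seed = NULL, max_attempts = 10000) {
  stopifnot(inherits(model, "mel_popmodel"), n >= 1)
  run <- function() {
    curves <- sample_curves(model, n, eta = 1, max_attempts = max_attempts)
    dplyr::bind_cols(tibble::tibble(individual_id = seq_len(n)), curves,
                     tibble::tibble(sigma = draw_sigmas(model, n)))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @rdname sample_individuals
#' @export
sample_individuals_reduced <- function(model, n, eta, seed = NULL,
                                       max_attempts = 10000) {
  stopifnot(inherits(model, "mel_popmodel"), n >= 1)
  if (length(eta) != 1 || !is.finite(eta) || eta < 0 || eta > 1) {
    stop("`eta` must be a single value in [0, 1].", call. = FALSE)
  }
  run <- function() {
    curves <- sample_curves(model, n, eta = eta,
                            max_attempts = max_attempts)
    dplyr::bind_cols(tibble::tibble(individual_id = seq_len(n)), curves,
                     tibble::tibble(sigma = draw_sigmas(model, n)))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Noisy measurement of melatonin suppression
#'
#' Applies the logit-normal measurement model: the observed suppression
#' is `inv_logit(normal(logit(s_true), sigma))`, which is guaranteed to
#' stay strictly inside (0, 1). The noiseless `sigma = 0` limit returns
#' the true suppression. Vectorized over individuals and illuminances
#' (recycled).
#'
#' @param x Illuminance(s) in lux, each > 1 (at exactly 1 lux the true
#'   suppression is 0 and its logit is undefined; keep measurement grids
#'   above 1 lux).
#' @param a,b Dose-response parameters.
#' @param sigma Logit-scale noise standard deviation(s), >= 0.
#' @param seed Optional integer seed.
#'
#' @return Numeric vector of measured suppressions in (0, 1).
#' @export
measure <- function(x, a, b, sigma, seed = NULL) {
  if (any(sigma < 0)) stop("`sigma` must be nonnegative.", call. = FALSE)
  s_true <- suppression(x, a, b)
  if (any(s_true <= 0) || any(s_true >= 1)) {
    stop("True suppression hits {0, 1} (illuminance at the domain edge); ",
         "keep the measurement grid strictly above 1 lux.", call. = FALSE)
  }
  z <- logit(s_true)
  run <- function() inv_logit(stats::rnorm(length(z), z, sigma))
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate a complete virtual experiment
#'
#' Samples `n` virtual individuals at heterogeneity `eta` and measures
#' each once at every illuminance of the grid through the logit-normal
#' measurement model. The result is a tidy table, one row per individual
#' and grid point.
#'
#' @inheritParams sample_individuals
#' @param grid Measurement illuminances (lux), strictly increasing and
#'   (for measurement) above 1 lux.
#' @param sigma Optional override of the per-individual noise level: a
#'   single value applied to all individuals (use 0 for noiseless
#'   measurements). Default `NULL` draws each individual's level from the
#'   fitted gamma noise model.
#' @param experiment_id Identifier stored in the output (default 1).
#'
#' @return A tibble of class `mel_experiment` with columns
#'   `experiment_id`, `individual_id`, `a`, `b`, `sigma`, `lux`,
#'   `true_suppression`, `measured_suppression`, and attributes `grid`
#'   and `eta`.
#' @examples
#' \donttest{
#' model <- fit_population_model(generate_raw_estimates(), seed = 1)
#' ve <- virtual_experiment(model, n = 41, seed = 1)
#' }
#' @export
virtual_experiment <- function(model, n = 41,
                               grid = default_measurement_grid(),
                               eta = 1, seed = NULL, sigma = NULL,
                               experiment_id = 1L) {
  stopifnot(n >= 1)
  validate_grid(grid)
  run <- function() {
    ind <- if (eta == 1) {
      sample_individuals(model, n)
    } else {
      sample_individuals_reduced(model, n, eta)
    }
    if (!is.null(sigma)) ind$sigma <- sigma
    out <- tidyr::expand_grid(ind, lux = grid)
    out$true_suppression <- suppression(out$lux, out$a, out$b)
    out$measured_suppression <- measure(out$lux, out$a, out$b, out$sigma)
    out
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  out <- dplyr::bind_cols(
    tibble::tibble(experiment_id = rep(as.integer(experiment_id),
                                       nrow(out))), out)
  structure(out, grid = grid, eta = eta,
            class = c("mel_experiment", class(out)))
}

#' Extrema and saturation checks over replicate virtual experiments
#'
#' For each experiment and illuminance level, computes the minimum and
#' maximum measured suppression (the "extrema") and the fractions of
#' measurements below 5 percent and above 95 percent suppression (the
#' lower and upper "saturation values"). Comparing these summaries
#' between replicate virtual experiments and real data is the model
#' adequacy check for the virtual-experiment framework.
#'
#' @param experiments A single `mel_experiment` or a list of them; all
#'   must share the same measurement grid.
#'
#' @return A tibble with one row per experiment and lux:
#'   `experiment_id`, `lux`, `min`, `max`, `frac_below_5`,
#'   `frac_above_95`.
#' @export
experiment_checks <- function(experiments) {
  if (inherits(experiments, "mel_experiment")) {
    experiments <- list(experiments)
  }
  stopifnot(length(experiments) >= 1)
  grids <- lapply(experiments, attr, "grid")
  if (!all(vapply(grids, identical, logical(1), y = grids[[1]]))) {
    stop("All experiments must share the same measurement grid.",
         call. = FALSE)
  }
  purrr::map_dfr(seq_along(experiments), function(i) {
    experiments[[i]] |>
      dplyr::group_by(.data$experiment_id, .data$lux) |>
      dplyr::summarise(
        min = min(.data$measured_suppression),
        max = max(.data$measured_suppression),
        frac_below_5 = mean(.data$measured_suppression < 0.05),
        frac_above_95 = mean(.data$measured_suppression > 0.95),
        .groups = "drop"
      )
  })
}
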