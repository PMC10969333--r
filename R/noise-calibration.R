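#' Default measurement grid of experimental illuminance levels
#'
#' The discrete photopic illuminances (lux) at which virtual measurements
#' are simulated, matching the experimental light levels of the study
#' underlying the population model. Configurable everywhere it is used;
#' all values must be strictly increasing and at least 1 lux (the dim
#' control below 1 lux lies outside the curve's domain and is excluded).
#'
#' @return Numeric vector of illuminances.
#' @export
default_measurement_grid <- function() {
  c(10, 30, 50, 100, 200, 400, 2000)
}

validate_grid <- function(grid) {
  if (length(grid) < 1 || any(!is.finite(grid)) || any(grid < 1) ||
      any(diff(grid) <= 0)) {
    stop("The measurement grid must be strictly increasing illuminances ",
         ">= 1 lux.", call. = FALSE)
  }
  invisible(grid)
}

#' Root-mean-square error between measured and predicted suppressions
#'
#' Computed on the raw suppression scale (not the logit scale), matching
#' how per-individual fit quality is summarized upstream.
#'
#' @param measured,predicted Equal-length numeric vectors.
#' @return A single nonnegative number.
#' @examples
#' rmse(c(0.2, 0.6), c(0.4, 0.6))  # 0.1414...
#' @export
rmse <- function(measured, predicted) {
  if (length(measured) != length(predicted)) {
    stop("`measured` and `predicted` must have equal length.", call. = FALSE)
  }
  if (length(measured) < 1) {
    stop("At least one observation is required.", call. = FALSE)
  }
  sqrt(mean((measured - predicted)^2))
}

#' Average simulated RMSE for a given noise level
#'
#' Simulates repeated virtual measurement experiments for one individual:
#' true suppressions at the grid are perturbed by logit-normal noise of
#' standard deviation `sigma`, the RMSE of each replicate experiment is
#' computed against the true curve, and the mean RMSE across replicates is
#' returned. Given a pre-generated block of standard-normal deviates the
#' result is deterministic, which is what makes the calibration
#' root-finding well-posed.
#'
#' @param params A one-row data frame with columns `a`, `b`
#'   (see [dose_params()]).
#' @param sigma Positive logit-scale noise standard deviation.
#' @param grid Measurement illuminances (lux), each >= 1; default
#'   [default_measurement_grid()].
#' @param replicates Number of replicate experiments (default 100).
#' @param noise_draws Optional `replicates x length(grid)` matrix of
#'   standard-normal deviates; generated from `seed` if omitted.
#' @param seed Integer seed used when `noise_draws` is not supplied.
#'
#' @return Mean RMSE across replicates (nonnegative scalar).
#' @export
simulated_mean_rmse <- function(params, sigma,
                                grid = default_measurement_grid(),
                                replicates = 100, noise_draws = NULL,
                                seed = NULL) {
  stopifnot(is.data.frame(params), nrow(params) == 1, replicates >= 1)
  if (!is.finite(sigma) || sigma <= 0) {
    stop("`sigma` must be a single positive number.", call. = FALSE)
  }
  validate_grid(grid)
  noise_draws <- noise_draws %||% withr::with_seed(
    seed %||% sample.int(2147483646L, 1),
    matrix(stats::rnorm(replicates * length(grid)), nrow = replicates)
  )
  stopifnot(nrow(noise_draws) == replicates,
            ncol(noise_draws) == length(grid))
  s_true <- suppression(grid, params$a, params$b)
  z_true <- logit(s_true)
  # replicates x grid matrix of logit-normal measurements
  meas <- inv_logit(sweep(sigma * noise_draws, 2, z_true, `+`))
  err <- sweep(meas, 2, s_true, `-`)
  mean(sqrt(rowMeans(err^2)))
}

#' Calibrate an individual's measurement-noise level
#'
#' Finds the logit-scale noise standard deviation `sigma` whose average
#' simulated RMSE (over `replicates` virtual experiments at the
#' measurement grid) matches the individual's observed fit RMSE, by
#' one-dimensional root finding ([stats::uniroot()]) on a bracket.
#' One fixed block of standard-normal deviates is reused for every
#' `sigma` evaluation (common random numbers), so the objective is
#' deterministic and monotone and the root is reproducible bit-for-bit
#' given the seed.
#'
#' @inheritParams simulated_mean_rmse
#' @param target_rmse The individual's observed RMSE (positive).
#' @param bracket Initial search interval for `sigma`; the upper end is
#'   doubled once if the target lies above the bracket's range.
#' @param tol Tolerance on the RMSE scale (default 1e-4).
#'
#' @return The calibrated `sigma` (positive scalar).
#' @export
calibrate_sigma <- function(params, target_rmse,
                            grid = default_measurement_grid(),
                            replicates = 100, seed = NULL,
                            bracket = c(1e-3, 10), tol = 1e-4) {
  if (!is.finite(target_rmse) || target_rmse <= 0) {
    stop("`target_rmse` must be strictly positive: a zero RMSE is ",
         "unattainable for any positive noise level.", call. = FALSE)
  }
  validate_grid(grid)
  noise_draws <- withr::with_seed(
    seed %||% sample.int(2147483646L, 1),
    matrix(stats::rnorm(replicates * length(grid)), nrow = replicates)
  )
  objective <- function(sigma) {
    simulated_mean_rmse(params, sigma, grid, replicates, noise_draws) -
      target_rmse
  }
  lo <- bracket[1]
  hi <- bracket[2]
  f_lo <- objective(lo)
  f_hi <- objective(hi)
  if (f_hi < 0) {  # one bracket-doubling pass
    hi <- hi * 2
    f_hi <- objective(hi)
  }
  if (f_lo * f_hi > 0) {
    stop("target_rmse = ", signif(target_rmse, 4), " is outside the ",
         "achievable mean-RMSE range [", signif(f_lo + target_rmse, 4),
         ", ", signif(f_hi + target_rmse, 4), "] for sigma in [",
         lo, ", ", hi, "].", call. = FALSE)
  }
  root <- stats::uniroot(objective, lower = lo, upper = hi,
                         f.lower = f_lo, f.upper = f_hi,
                         tol = .Machine$double.eps^0.5)
  if (abs(root$f.root) > tol) {
    warning("Calibration residual ", signif(abs(root$f.root), 3),
            " exceeds tolerance ", tol, ".", call. = FALSE)
  }
  root$root
}

#' Calibrate noise levels for a whole raw-estimates table
#'
#' Runs [calibrate_sigma()] for each individual, targeting that
#' individual's observed `rmse`, and returns the table with a `sigma`
#' column appended. Per-individual seeds are derived from `seed` and the
#' row position, so the result is reproducible.
#'
#' @param raw Raw-estimates data frame with columns `a`, `b`, `rmse`.
#' @inheritParams calibrate_sigma
#' @return The input tibble plus a `sigma` column.
#' @export
calibrate_sigmas <- function(raw, grid = default_measurement_grid(),
                             replicates = 100, seed = NULL, ...) {
  validate_raw_estimates(raw)
  seeds <- derive_seeds(seed, nrow(raw))
  raw$sigma <- purrr::map_dbl(seq_len(nrow(raw)), function(i) {
    calibrate_sigma(raw[i, c("a", "b")], target_rmse = raw$rmse[i],
                    grid = grid, replicates = replicates, seed = seeds[i],
                    ...)
  })
  tibble::as_tibble(raw)
}
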