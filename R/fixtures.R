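#' Generate synthetic raw dose-response estimates
#'
#' Produces a reproducible synthetic stand-in for a table of per-individual
#' raw dose-response estimates `(a_i, b_i, rmse_i)`, the input every
#' fitting step consumes. The generator emulates a study population in
#' which light sensitivity spans roughly 1.5-2 orders of magnitude of
#' ED50: `a_i` (log10 ED50) is drawn from a normal distribution truncated
#' to `a_range`, `log(b_i)` follows the heteroscedastic regression
#' `normal(alpha + beta * a_i, sigma0 + sigma1 * a_i)`, and per-individual
#' fit RMSEs come from a right-skewed gamma distribution. The generating
#' ("ground truth") parameters are attached as the `"ground_truth"`
#' attribute so that recovery tests can compare fitted posteriors against
#' them. These are synthetic data, not any study's measurements.
#'
#' @param n Number of individuals (default 41).
#' @param alpha,beta Intercept and slope of the log-b regression truth.
#' @param sigma0,sigma1 Intercept and slope of the residual standard
#'   deviation `sigma0 + sigma1 * a`; both must keep the SD positive over
#'   `a_range`.
#' @param a_mean,a_sd,a_range Location, scale and truncation interval of
#'   the `a` distribution (defaults: normal(2, 0.45) truncated to [1, 3]).
#' @param rmse_shape,rmse_rate Gamma parameters for the RMSE column
#'   (defaults give mean 0.1).
#' @param seed Integer seed (default 41) making the fixture deterministic.
#'
#' @return A tibble with columns `id`, `a`, `b`, `rmse` and attribute
#'   `"ground_truth"` (retrievable with [fixture_truth()]).
#' @examples
#' raw <- generate_raw_estimates()
#' fixture_truth(raw)$beta
#' @export
generate_raw_estimates <- function(n = 41,
                                   alpha = -1.0, beta = 0.6,
                                   sigma0 = 0.05, sigma1 = 0.1,
                                   a_mean = 2, a_sd = 0.45,
                                   a_range = c(1, 3),
                                   rmse_shape = 4, rmse_rate = 40,
                                   seed = 41L) {
  stopifnot(n >= 1, a_sd > 0, length(a_range) == 2, a_range[1] > 0,
            a_range[1] < a_range[2], rmse_shape > 0, rmse_rate > 0)
  withr::with_seed(seed, {
    # truncated normal via inverse transform
    lo <- stats::pnorm(a_range[1], a_mean, a_sd)
    hi <- stats::pnorm(a_range[2], a_mean, a_sd)
    a <- stats::qnorm(stats::runif(n, lo, hi), a_mean, a_sd)
    sd_a <- sigma0 + sigma1 * a
    if (any(sd_a < 0)) {
      stop("sigma0 + sigma1 * a is negative for some generated a; choose ",
           "parameters giving a positive residual SD over `a_range`.",
           call. = FALSE)
    }
    b <- exp(alpha + beta * a + stats::rnorm(n, 0, sd_a))
    rmse <- stats::rgamma(n, shape = rmse_shape, rate = rmse_rate)
  })
  out <- tibble::tibble(id = seq_len(n), a = a, b = b, rmse = rmse)
  attr(out, "ground_truth") <- list(
    alpha = alpha, beta = beta, sigma0 = sigma0, sigma1 = sigma1,
    a_mean = a_mean, a_sd = a_sd, a_range = a_range,
    rmse_shape = rmse_shape, rmse_rate = rmse_rate, seed = seed
  )
  out
}

#' @param raw A fixture returned by [generate_raw_estimates()].
#' @rdname generate_raw_estimates
#' @export
fixture_truth <- function(raw) {
  attr(raw, "ground_truth")
}

# validate a raw-estimates table (shared precondition of the fitting steps)
validate_raw_estimates <- function(raw, min_n = 5) {
  stopifnot(is.data.frame(raw))
  missing <- setdiff(c("a", "b", "rmse"), names(raw))
  if (length(missing)) {
    stop("Raw estimates must have columns a, b, rmse; missing: ",
         paste(missing, collapse = ", "), ".", call. = FALSE)
  }
  if (nrow(raw) < min_n) {
    stop("At least ", min_n, " individuals are required; got ", nrow(raw),
         ".", call. = FALSE)
  }
  for (col in c("a", "b", "rmse")) {
    v <- raw[[col]]
    if (any(!is.finite(v)) || any(v <= 0)) {
      stop("Column `", col, "` must be finite and strictly positive.",
           call. = FALSE)
    }
  }
  invisible(raw)
}

# photopic-lux -> melanopic-EDI pairs for the fluorescent source of the
# underlying study. The 1106.21 value is printed against "nominal 200 lx"
# in the source, an apparent typo for the 2000 lx condition (200 lx already
# has its own entry); it is stored under 2000.
medi_pairs <- c(`10` = 1.58, `100` = 48.24, `200` = 99.76,
                `400` = 206.33, `2000` = 1106.21)

#' Melanopic equivalent daylight illuminance conversion
#'
#' `melanopic_edi()` rescales photopic illuminance by a single
#' user-supplied factor, valid when the light source's spectrum does not
#' change with intensity. `medi_lookup()` returns the tabulated
#' melanopic-EDI values for the five nominal photopic levels of the
#' fluorescent source underlying the population model; the per-level
#' ratios are not constant (about 0.16 at 10 lx up to about 0.55 at
#' 2000 lx), so no interpolation between the two interfaces is offered.
#'
#' @param photopic_lux Nonnegative photopic illuminance(s), lux.
#' @param scale Positive scalar melanopic-EDI-per-photopic-lux factor.
#' @param nominal_lux Nominal photopic level(s); must be among 10, 100,
#'   200, 400, 2000.
#'
#' @return Numeric vector of melanopic EDI values in lux.
#' @examples
#' melanopic_edi(100, scale = 0.48)
#' medi_lookup(c(100, 400))
#' @export
melanopic_edi <- function(photopic_lux, scale) {
  if (length(scale) != 1 || !is.finite(scale) || scale <= 0) {
    stop("`scale` must be a single positive number.", call. = FALSE)
  }
  if (any(photopic_lux < 0)) {
    stop("`photopic_lux` must be nonnegative.", call. = FALSE)
  }
  photopic_lux * scale
}

#' @rdname melanopic_edi
#' @export
medi_lookup <- function(nominal_lux) {
  key <- as.character(nominal_lux)
  unknown <- setdiff(key, names(medi_pairs))
  if (length(unknown)) {
    stop("No tabulated melanopic EDI for nominal level(s) ",
         paste(unknown, collapse = ", "), "; available levels: ",
         paste(names(medi_pairs), collapse = ", "), " lux.", call. = FALSE)
  }
  unname(medi_pairs[key])
}
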