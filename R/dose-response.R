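#' Individual dose-response curve parameters
#'
#' Constructs a validated tibble of per-individual dose-response parameters.
#' Each individual's melatonin suppression curve is the two-parameter
#' logistic-type function
#' \deqn{s(x) = 1 - \frac{1}{1 + (\log_{10}(x)/a)^b},}
#' where `a` is the base-10 logarithm of the ED50 (the photopic illuminance,
#' in lux, producing 50\% suppression) and `b > 0` controls the curve shape.
#' Both parameters must be positive: `a > 0` means the ED50 exceeds 1 lux,
#' which keeps suppression monotone over the operational domain `x >= 1`.
#'
#' @param a Numeric vector, log10 of ED50 in photopic lux; all > 0.
#' @param b Numeric vector, curve shape; all > 0. Recycled against `a`.
#'
#' @return A tibble with columns `a` and `b`.
#' @examples
#' dose_params(a = 2, b = 1.5)
#' @export
dose_params <- function(a, b) {
  check_positive(a, "a")
  check_positive(b, "b")
  tibble::tibble(a = as.numeric(a), b = as.numeric(b))
}

#' Melatonin suppression at a given illuminance
#'
#' Forward evaluation of the individual dose-response curve
#' \eqn{s(x) = 1 - 1/(1 + (\log_{10}(x)/a)^b)}. Suppression is 0 at 1 lux,
#' strictly increasing in `x`, and tends to 1 (100\%) as illuminance grows
#' without bound. The curve is undefined below 1 lux (the log-illuminance
#' ratio would be negative, and non-integer powers of negative numbers are
#' undefined); by convention the dim control condition (< 1 lux) is treated
#' as zero suppression by callers, never silently inside this function.
#'
#' @param x Illuminance in photopic lux (or its base-10 logarithm when
#'   `x_log10 = TRUE`); all values must be >= 1 (log10 >= 0).
#' @param a,b Curve parameters (see [dose_params()]); vectors are recycled.
#' @param x_log10 Interpret `x` as log10 illuminance. Extreme shallow
#'   curves (small `b`) place high-quantile effective doses beyond the
#'   largest representable double in lux; the log10 scale keeps the
#'   forward/inverse pair exact there.
#'
#' @return Numeric vector of suppression values in `[0, 1)`.
#' @examples
#' suppression(100, a = 2, b = 1.5)  # x = ED50 -> 0.5
#' suppression(1000, a = 2, b = 2)   # 1 - 1/(1 + 1.5^2)
#' @seealso [effective_dose()] for the inverse.
#' @export
suppression <- function(x, a, b, x_log10 = FALSE) {
  check_positive(a, "a")
  check_positive(b, "b")
  lx <- if (x_log10) x else log10(x)
  if (any(is.na(lx)) || any(lx < 0) || (!x_log10 && any(!is.finite(x)))) {
    stop("`x` must be finite illuminance >= 1 lux: the dose-response curve ",
         "is undefined below 1 lux.", call. = FALSE)
  }
  1 - 1 / (1 + (lx / a)^b)
}

#' Effective dose for a target suppression quantile
#'
#' Inverts the dose-response curve: returns the illuminance at which an
#' individual's suppression equals `q`. Algebraically,
#' \eqn{ed(q) = 10^{a(-1 + 1/(1-q))^{1/b}}}; `effective_dose(0.5) = 10^a`
#' is the ED50, and ED25/ED75 are the quarter and three-quarter doses used
#' as plausibility bounds when generating virtual individuals.
#'
#' @param q Suppression quantile(s), strictly between 0 and 1.
#' @param log10_out Return the base-10 logarithm of the effective dose
#'   instead of lux (see `x_log10` in [suppression()]).
#' @inheritParams suppression
#'
#' @return Numeric vector of illuminances in photopic lux (or log10 lux).
#' @examples
#' effective_dose(0.5, a = 2, b = 1.5)  # 100 lux
#' suppression(effective_dose(0.75, 2, 1.5), 2, 1.5)  # 0.75
#' @export
effective_dose <- function(q, a, b, log10_out = FALSE) {
  check_positive(a, "a")
  check_positive(b, "b")
  if (any(!is.finite(q)) || any(q <= 0) || any(q >= 1)) {
    stop("`q` must lie strictly inside (0, 1).", call. = FALSE)
  }
  lx <- a * (-1 + 1 / (1 - q))^(1 / b)
  if (log10_out) lx else 10^lx
}

#' Logit and inverse-logit transforms
#'
#' `logit(p) = log(p / (1 - p))` maps the open unit interval to the real
#' line; `inv_logit()` is its inverse. Measurement noise in the virtual
#' experiment model is additive on the logit scale, which guarantees noisy
#' suppression measurements stay inside (0, 1).
#'
#' @param p Probabilities strictly inside (0, 1).
#' @param z Real numbers.
#'
#' @return Numeric vector.
#' @examples
#' logit(0.75)     # log(3)
#' inv_logit(0)    # 0.5
#' @export
logit <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("`p` must lie strictly inside (0, 1); logit is undefined at 0 and 1.",
         call. = FALSE)
  }
  log(p / (1 - p))
}

#' @rdname logit
#' @export
inv_logit <- function(z) {
  stats::plogis(z)
}

#' Shift dose-response curves by an intervention multiplier
#'
#' Applies a light-sensitivity intervention that multiplies each
#' individual's natural ED50 by `chi`, leaving the curve shape `b`
#' unchanged: on the log scale, `a' = a + log10(chi)`. For example
#' `chi = 0.2` divides the ED50 by 5 (individuals become five times more
#' sensitive); `chi = 1` is the identity.
#'
#' @param params A data frame with columns `a` and `b` (see
#'   [dose_params()]), one row per individual.
#' @param chi Positive scalar ED50 multiplier. The shifted `a` values must
#'   remain positive (shifted ED50 above 1 lux).
#'
#' @return The input data frame with its `a` column shifted.
#' @examples
#' apply_intervention(dose_params(2, 1.5), chi = 0.2)  # ED50 100 -> 20 lux
#' @export
apply_intervention <- function(params, chi) {
  stopifnot(is.data.frame(params), all(c("a", "b") %in% names(params)))
  if (length(chi) != 1 || !is.finite(chi) || chi <= 0) {
    stop("`chi` must be a single positive number.", call. = FALSE)
  }
  a_new <- params$a + log10(chi)
  if (any(a_new <= 0)) {
    stop("Intervention chi = ", chi, " pushes some ED50 values to 1 lux or ",
         "below (shifted a <= 0); the dose-response model requires a > 0.",
         call. = FALSE)
  }
  params$a <- a_new
  params
}

# shared positivity check for curve parameters
check_positive <- function(v, name) {
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("`", name, "` must be finite and strictly positive.", call. = FALSE)
  }
  invisible(v)
}
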