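#' Specify a virtual experiment design
#'
#' Describes one design point of a power analysis. Two experiment
#' classes are supported: `"comparison"` (population suppression compared
#' between two illuminance levels `x1`, `x2`) and `"intervention"`
#' (suppression at one level `x` compared between natural curves and
#' curves whose ED50 is multiplied by `chi`). Each class can be run as a
#' within-subjects design (the same `N` individuals measured under both
#' conditions; paired t-test) or a between-subjects design (two
#' independent groups of `N`; independent t-test, Welch by default).
#'
#' @param class `"comparison"` or `"intervention"`.
#' @param design `"within"` or `"between"`.
#' @param x1,x2 Comparison illuminances (lux, > 1); must differ.
#' @param x Intervention measurement illuminance (lux, > 1).
#' @param chi Intervention ED50 multiplier (> 0); `chi < 1` increases
#'   sensitivity (higher suppression at fixed `x`).
#' @param N Per-group sample size, at least 2.
#' @param eta Individual-heterogeneity level in `[0, 1]`.
#' @param alpha Test size in (0, 1).
#'
#' @return A list of class `mel_design`.
#' @examples
#' design_spec("comparison", "within", x1 = 250, x2 = 750, N = 20)
#' @export
design_spec <- function(class = c("comparison", "intervention"),
                        design = c("within", "between"),
                        x1 = NULL, x2 = NULL, x = NULL, chi = NULL,
                        N = 10, eta = 1, alpha = 0.05) {
  class <- match.arg(class)
  design <- match.arg(design)
  if (N < 2) stop("`N` must be at least 2.", call. = FALSE)
  if (!is.finite(eta) || eta < 0 || eta > 1) {
    stop("`eta` must lie in [0, 1].", call. = FALSE)
  }
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie strictly inside (0, 1).", call. = FALSE)
  }
  if (class == "comparison") {
    if (is.null(x1) || is.null(x2)) {
      stop("Comparison designs need `x1` and `x2`.", call. = FALSE)
    }
    if (x1 == x2) stop("`x1` and `x2` must differ.", call. = FALSE)
    if (min(x1, x2) <= 1) {
      stop("Comparison illuminances must exceed 1 lux.", call. = FALSE)
    }
  } else {
    if (is.null(x) || is.null(chi)) {
      stop("Intervention designs need `x` and `chi`.", call. = FALSE)
    }
    if (x <= 1) stop("`x` must exceed 1 lux.", call. = FALSE)
    if (chi <= 0) stop("`chi` must be positive.", call. = FALSE)
  }
  structure(list(class = class, design = design, x1 = x1, x2 = x2, x = x,
                 chi = chi, N = N, eta = eta, alpha = alpha),
            class = "mel_design")
}

sample_for_design <- function(model, n, eta) {
  if (eta == 1) {
    sample_individuals(model, n)
  } else {
    sample_individuals_reduced(model, n, eta)
  }
}

# two-sided t-test rejection plus sign of the mean difference; handles the
# zero-variance degenerate limit (eta = 0, sigma ~ 0) as t -> infinity
test_difference <- function(d1, d2, paired, alpha, var_equal = FALSE) {
  diffs <- if (paired) d1 - d2 else NULL
  degenerate <- if (paired) {
    stats::sd(diffs) < .Machine$double.eps^0.75
  } else {
    stats::sd(d1) < .Machine$double.eps^0.75 &&
      stats::sd(d2) < .Machine$double.eps^0.75
  }
  delta <- mean(d1) - mean(d2)
  if (degenerate) {
    return(list(reject = delta != 0, delta = delta))
  }
  tt <- stats::t.test(d1, d2, paired = paired, var.equal = var_equal)
  list(reject = tt$p.value < alpha, delta = delta)
}

#' Run a single virtual comparison trial
#'
#' Simulates one illuminance-comparison experiment from the population
#' model and tests it. Within-subjects: `N` individuals are each measured
#' at `x1` and at `x2` (same curve and noise level, independent
#' measurement noise) and a paired two-sided t-test is applied.
#' Between-subjects: two independent groups of `N` individuals, one
#' measured per level, compared by an independent two-sided t-test
#' (Welch by default). The trial succeeds when the test rejects at level
#' `alpha` *and* the observed mean difference has the correct sign
#' (higher illuminance implies higher expected suppression).
#'
#' @param model A `mel_popmodel`.
#' @param spec A `mel_design` with `class = "comparison"`.
#' @param seed Optional integer seed.
#' @param var_equal Use the pooled-variance t-test for between-subjects
#'   designs instead of Welch's.
#'
#' @return Logical: significant difference of the correct sign.
#' @export
comparison_trial <- function(model, spec, seed = NULL, var_equal = FALSE) {
  stopifnot(inherits(spec, "mel_design"), spec$class == "comparison")
  run <- function() {
    if (spec$design == "within") {
      ind <- sample_for_design(model, spec$N, spec$eta)
      s1 <- measure(spec$x1, ind$a, ind$b, ind$sigma)
      s2 <- measure(spec$x2, ind$a, ind$b, ind$sigma)
      res <- test_difference(s1, s2, paired = TRUE, alpha = spec$alpha)
    } else {
      g1 <- sample_for_design(model, spec$N, spec$eta)
      g2 <- sample_for_design(model, spec$N, spec$eta)
      s1 <- measure(spec$x1, g1$a, g1$b, g1$sigma)
      s2 <- measure(spec$x2, g2$a, g2$b, g2$sigma)
      res <- test_difference(s1, s2, paired = FALSE, alpha = spec$alpha,
                             var_equal = var_equal)
    }
    # suppression is increasing in illuminance, so the x1 - x2 difference
    # must share the sign of x1 - x2
    res$reject && sign(res$delta) == sign(spec$x1 - spec$x2)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Run a single virtual intervention trial
#'
#' Simulates one light-sensitivity-intervention experiment.
#' Within-subjects: `N` individuals are measured at `x` with their
#' natural curves and again after the intervention multiplies their ED50
#' by `chi` (same noise level, independent noise); paired two-sided
#' t-test. Between-subjects: an independent baseline group and an
#' intervention group whose curves are shifted; independent t-test. The
#' trial succeeds when the test rejects at `alpha` and the observed sign
#' matches the truth: `chi < 1` (lower ED50, more sensitive) implies
#' higher suppression under intervention, `chi > 1` lower. At `chi = 1`
#' there is no true direction, so the plain rejection indicator is
#' returned (used for type-I calibration).
#'
#' @inheritParams comparison_trial
#' @param spec A `mel_design` with `class = "intervention"`.
#' @return Logical.
#' @export
intervention_trial <- function(model, spec, seed = NULL,
                               var_equal = FALSE) {
  stopifnot(inherits(spec, "mel_design"), spec$class == "intervention")
  run <- function() {
    if (spec$design == "within") {
      ind <- sample_for_design(model, spec$N, spec$eta)
      shifted <- apply_intervention(ind[, c("a", "b")], spec$chi)
      s_nat <- measure(spec$x, ind$a, ind$b, ind$sigma)
      s_int <- measure(spec$x, shifted$a, shifted$b, ind$sigma)
      res <- test_difference(s_int, s_nat, paired = TRUE,
                             alpha = spec$alpha)
    } else {
      g_nat <- sample_for_design(model, spec$N, spec$eta)
      g_int <- sample_for_design(model, spec$N, spec$eta)
      shifted <- apply_intervention(g_int[, c("a", "b")], spec$chi)
      s_nat <- measure(spec$x, g_nat$a, g_nat$b, g_nat$sigma)
      s_int <- measure(spec$x, shifted$a, shifted$b, g_int$sigma)
      res <- test_difference(s_int, s_nat, paired = FALSE,
                             alpha = spec$alpha, var_equal = var_equal)
    }
    if (spec$chi == 1) {
      res$reject
    } else {
      res$reject && sign(res$delta) == sign(1 - spec$chi)
    }
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Monte-Carlo power estimate for one design point
#'
#' Repeats the appropriate trial simulation and reports the fraction of
#' trials yielding a significant difference of the correct sign, together
#' with its binomial Monte-Carlo standard error
#' `sqrt(power * (1 - power) / replicates)`. Deterministic given `seed`.
#'
#' @inheritParams comparison_trial
#' @param spec A `mel_design`.
#' @param replicates Number of simulated trials (>= 1).
#' @param seed Integer seed.
#'
#' @return A one-row tibble: design fields, `replicates`, `power`,
#'   `mc_se`, `seed`.
#' @export
estimate_power <- function(model, spec, replicates = 1000, seed = NULL,
                           var_equal = FALSE) {
  stopifnot(inherits(spec, "mel_design"), replicates >= 1)
  trial <- switch(spec$class,
                  comparison = comparison_trial,
                  intervention = intervention_trial)
  run <- function() {
    mean(vapply(seq_len(replicates),
                function(i) trial(model, spec, var_equal = var_equal),
                logical(1)))
  }
  power <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  tibble::tibble(
    class = spec$class, design = spec$design,
    x1 = spec$x1 %||% NA_real_, x2 = spec$x2 %||% NA_real_,
    x = spec$x %||% NA_real_, chi = spec$chi %||% NA_real_,
    N = spec$N, eta = spec$eta, alpha = spec$alpha,
    replicates = as.integer(replicates), power = power,
    mc_se = sqrt(power * (1 - power) / replicates),
    seed = seed %||% NA_integer_
  )
}

#' All unordered pairs of comparison illuminances
#'
#' Expands a vector of illuminance levels into the set of all possible
#' pairs of different levels (`x1 < x2`), the standard comparison-design
#' grid axis. The conventional full set `seq(10, 1990, by = 20)` yields
#' `choose(100, 2)` pairs.
#'
#' @param levels Numeric vector of illuminance levels (lux, > 1).
#' @return A tibble with columns `x1`, `x2`.
#' @examples
#' nrow(comparison_pairs(seq(10, 1990, by = 20)))  # 4950
#' @export
comparison_pairs <- function(levels) {
  levels <- sort(unique(levels))
  if (length(levels) < 2) {
    stop("At least two distinct levels are required.", call. = FALSE)
  }
  idx <- utils::combn(length(levels), 2)
  tibble::tibble(x1 = levels[idx[1, ]], x2 = levels[idx[2, ]])
}

#' Monte-Carlo power over a grid of design points
#'
#' Expands the supplied axes into design cells (for comparisons, all
#' `x1`-`x2` combinations with `x1 != x2`) and estimates power for each.
#' Per-cell seeds are derived deterministically from the master seed and
#' the cell's position in the canonical expansion, so any cell can be
#' reproduced in isolation and the full table is bit-identical across
#' reruns with the same master seed. Default axes follow the standard
#' design sets (sample sizes 10-100, heterogeneity 0-1 in steps of 0.2,
#' test sizes 1/5/10 percent, ED50 multipliers 0.2-2); every axis can be
#' reduced for desk-scale runs.
#'
#' @inheritParams estimate_power
#' @param class,design Experiment class and design (single values).
#' @param x1,x2,x,chi,N,eta,alpha Grid axes (numeric vectors).
#' @param pairs Optional tibble of comparison pairs (columns `x1`, `x2`),
#'   e.g. from [comparison_pairs()]; overrides `x1`/`x2`.
#' @param replicates Trials per cell.
#' @param seed Master seed.
#'
#' @return A tibble of class `mel_power_grid`, one row per cell.
#' @export
power_grid <- function(model, class = c("comparison", "intervention"),
                       design = c("within", "between"),
                       x1 = NULL, x2 = NULL, x = NULL, chi = NULL,
                       N = seq(10, 100, by = 10),
                       eta = seq(0, 1, by = 0.2),
                       alpha = c(0.01, 0.05, 0.10),
                       pairs = NULL,
                       replicates = 1000, seed = NULL,
                       var_equal = FALSE) {
  class <- match.arg(class)
  design <- match.arg(design)
  if (class == "comparison") {
    if (is.null(pairs) && (is.null(x1) || is.null(x2))) {
      stop("Comparison grids need `pairs` or `x1` and `x2` axes.",
           call. = FALSE)
    }
    pairs <- pairs %||% (tidyr::expand_grid(x1 = x1, x2 = x2) |>
                           dplyr::filter(.data$x1 != .data$x2))
    cells <- tidyr::expand_grid(pairs, N = N, eta = eta, alpha = alpha)
  } else {
    if (is.null(x) || is.null(chi)) {
      stop("Intervention grids need `x` and `chi` axes.", call. = FALSE)
    }
    cells <- tidyr::expand_grid(x = x, chi = chi, N = N, eta = eta,
                                alpha = alpha)
  }
  if (!nrow(cells)) stop("Empty design grid.", call. = FALSE)
  seeds <- derive_seeds(seed, nrow(cells))
  out <- purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    row <- cells[i, ]
    spec <- if (class == "comparison") {
      design_spec(class, design, x1 = row$x1, x2 = row$x2,
                  N = row$N, eta = row$eta, alpha = row$alpha)
    } else {
      design_spec(class, design, x = row$x, chi = row$chi,
                  N = row$N, eta = row$eta, alpha = row$alpha)
    }
    estimate_power(model, spec, replicates = replicates, seed = seeds[i],
                   var_equal = var_equal)
  })
  class(out) <- c("mel_power_grid", class(out))
  out
}
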