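#' MCMC convergence diagnostics
#'
#' Computes rank-normalized split R-hat and bulk/tail effective sample
#' sizes per parameter, following the diagnostics of Vehtari, Gelman,
#' Simpson, Carpenter and Buerkner (2021). Bulk ESS is the effective
#' sample size of the rank-normalized split draws; tail ESS is the
#' smaller of the effective sample sizes of the 5\% and 95\% quantile
#' indicator sequences. The package-wide convergence gate is
#' `max R-hat < 1.01` and `min(bulk ESS, tail ESS) > 400`.
#'
#' @param draws A data frame of posterior draws with one row per draw, a
#'   `.chain` integer column, and one numeric column per parameter
#'   (any `.iteration` column is ignored).
#'
#' @return A tibble with columns `parameter`, `rhat`, `ess_bulk`,
#'   `ess_tail`.
#' @examples
#' draws <- data.frame(.chain = rep(1:4, each = 250), theta = rnorm(1000))
#' compute_diagnostics(draws)
#' @references Vehtari A, Gelman A, Simpson D, Carpenter B, Buerkner P-C
#'   (2021). Rank-normalization, folding, and localization: an improved
#'   R-hat for assessing convergence of MCMC. Bayesian Analysis 16(2).
#' @export
compute_diagnostics <- function(draws) {
  stopifnot(is.data.frame(draws), ".chain" %in% names(draws))
  params <- setdiff(names(draws), c(".chain", ".iteration"))
  chains <- sort(unique(draws$.chain))
  if (length(chains) < 2) {
    stop("Split R-hat requires at least 2 chains; got ", length(chains), ".",
         call. = FALSE)
  }
  n_per <- table(draws$.chain)
  if (length(unique(n_per)) != 1) {
    stop("All chains must have the same number of draws.", call. = FALSE)
  }
  if (min(n_per) < 100) {
    stop("Diagnostics require at least 100 draws per chain; got ",
         min(n_per), ".", call. = FALSE)
  }
  purrr::map_dfr(params, function(p) {
    m <- matrix(draws[[p]][order(draws$.chain)], ncol = length(chains))
    tibble::tibble(
      parameter = p,
      rhat = rhat_rank(m),
      ess_bulk = ess_bulk(m),
      ess_tail = ess_tail(m)
    )
  })
}

#' @param diagnostics A tibble as returned by [compute_diagnostics()].
#' @param rhat_max,ess_min Gate thresholds.
#' @return `converged_gate()`: a single logical.
#' @rdname compute_diagnostics
#' @export
converged_gate <- function(diagnostics, rhat_max = 1.01, ess_min = 400) {
  all(is.finite(diagnostics$rhat)) &&
    max(diagnostics$rhat) < rhat_max &&
    all(is.finite(c(diagnostics$ess_bulk, diagnostics$ess_tail))) &&
    min(diagnostics$ess_bulk, diagnostics$ess_tail) > ess_min
}

# ---- internals: draws as iterations x chains matrices --------------------

split_chains <- function(m) {
  n <- nrow(m)
  half <- floor(n / 2)
  cbind(m[seq_len(half), , drop = FALSE],
        m[seq.int(n - half + 1, n), , drop = FALSE])
}

# rank-normalize jointly across all chains (Blom offset 3/8)
z_scale <- function(m) {
  r <- rank(as.vector(m), ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, nrow = nrow(m))
}

# classic potential-scale-reduction on an iterations x chains matrix
rhat_basic <- function(m) {
  n <- nrow(m)
  chain_means <- colMeans(m)
  chain_vars <- apply(m, 2, stats::var)
  var_between <- n * stats::var(chain_means)
  var_within <- mean(chain_vars)
  if (var_within == 0) return(NaN)
  sqrt((var_between / var_within + n - 1) / n)
}

rhat_rank <- function(m) {
  sm <- split_chains(m)
  bulk <- rhat_basic(z_scale(sm))
  folded <- abs(sm - stats::median(sm))
  tail <- rhat_basic(z_scale(folded))
  max(bulk, tail)
}

# biased autocovariance via FFT with zero padding
autocovariance <- function(y) {
  n <- length(y)
  yc <- c(y - mean(y), rep(0, n))
  f <- stats::fft(yc)
  acov <- Re(stats::fft(Conj(f) * f, inverse = TRUE))[seq_len(n)]
  acov / (2 * n * n)
}

# effective sample size via Geyer's initial monotone positive pair sequence
ess_basic <- function(m) {
  n <- nrow(m)
  n_chain <- ncol(m)
  if (n < 6 || any(!is.finite(m))) return(NaN)
  if (stats::sd(as.vector(m)) == 0) return(NaN)
  acov <- apply(m, 2, autocovariance)
  mean_var <- mean(acov[1, ]) * n / (n - 1)
  var_plus <- mean_var * (n - 1) / n
  if (n_chain > 1) var_plus <- var_plus + stats::var(colMeans(m))
  if (var_plus == 0) return(NaN)

  rho <- rep(0, n)
  t <- 0
  even <- 1
  rho[1] <- even
  odd <- 1 - (mean_var - mean(acov[2, ])) / var_plus
  rho[2] <- odd
  while (t < n - 5 && !is.nan(even + odd) && even + odd > 0) {
    t <- t + 2
    even <- 1 - (mean_var - mean(acov[t + 1, ])) / var_plus
    odd <- 1 - (mean_var - mean(acov[t + 2, ])) / var_plus
    if (even + odd >= 0) {
      rho[t + 1] <- even
      rho[t + 2] <- odd
    }
  }
  max_t <- t
  if (even > 0) rho[max_t + 1] <- even
  # enforce monotone nonincreasing pair sums
  t <- 0
  while (t <= max_t - 4) {
    t <- t + 2
    if (rho[t + 1] + rho[t + 2] > rho[t - 1] + rho[t]) {
      rho[t + 1] <- (rho[t - 1] + rho[t]) / 2
      rho[t + 2] <- rho[t + 1]
    }
  }
  total <- n * n_chain
  tau <- -1 + 2 * sum(rho[seq_len(max_t)]) + rho[max_t + 1]
  tau <- max(tau, 1 / log10(total))
  total / tau
}

ess_bulk <- function(m) {
  ess_basic(z_scale(split_chains(m)))
}

ess_quantile <- function(m, prob) {
  q <- stats::quantile(as.vector(m), probs = prob, names = FALSE)
  ind <- (m <= q) + 0
  ess_basic(split_chains(ind))
}

ess_tail <- function(m) {
  min(ess_quantile(m, 0.05), ess_quantile(m, 0.95))
}
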