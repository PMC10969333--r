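# Shared test-scale population model, fitted once per test run from the
# default synthetic fixture. Chain lengths are reduced relative to the
# package defaults but still pass the convergence gate.
.melpower_test_cache <- new.env(parent = emptyenv())

test_raw <- function() {
  if (is.null(.melpower_test_cache$raw)) {
    .melpower_test_cache$raw <- generate_raw_estimates()
  }
  .melpower_test_cache$raw
}

test_popmodel <- function() {
  if (is.null(.melpower_test_cache$model)) {
    .melpower_test_cache$model <- fit_population_model(
      test_raw(), seed = 4242,
      regression_args = list(iter = 2000, warmup = 1000, thin = 1),
      calibration_args = list(replicates = 100)
    )
  }
  .melpower_test_cache$model
}

# AR(1) chains used by the diagnostics tests
make_ar1_chains <- function(n, m, rho, mu = 0) {
  vapply(seq_len(m), function(k) {
    x <- numeric(n)
    x[1] <- stats::rnorm(1)
    for (i in 2:n) {
      x[i] <- rho * x[i - 1] + stats::rnorm(1, 0, sqrt(1 - rho^2))
    }
    x + mu
  }, numeric(n))
}

chains_to_draws <- function(m) {
  data.frame(.chain = rep(seq_len(ncol(m)), each = nrow(m)),
             theta = as.vector(m))
}
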