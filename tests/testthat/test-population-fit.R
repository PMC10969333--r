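test_that("the kernel density model normalizes and locates the sample", {
  set.seed(21)
  raw <- tibble::tibble(a = rnorm(500, 2, 0.5), b = 1, rmse = 0.1)
  raw$a <- pmax(raw$a, 0.05)
  ad <- fit_a_distribution(raw)
  expect_s3_class(ad, "mel_adist")
  expect_true(all(ad$density >= 0))
  expect_true(all(diff(ad$cdf) >= -1e-12))
  expect_equal(ad$cdf[length(ad$cdf)], 1, tolerance = 1e-6)
  # KDE mean close to the generating mean
  kde_mean <- sum(diff(ad$grid) *
                    (head(ad$grid * ad$density, -1) +
                       tail(ad$grid * ad$density, -1)) / 2)
  expect_equal(kde_mean, 2, tolerance = 0.1)
  # inverse-transform samples reproduce the empirical quartiles
  set.seed(22)
  draws <- sample_a(ad, 20000)
  expect_equal(unname(quantile(draws, c(0.25, 0.5, 0.75))),
               unname(quantile(raw$a, c(0.25, 0.5, 0.75))),
               tolerance = 0.1)
})

test_that("a near-degenerate sample concentrates the density at its value", {
  set.seed(23)
  raw <- tibble::tibble(a = 2 + rnorm(50, 0, 1e-3), b = 1, rmse = 0.1)
  ad <- fit_a_distribution(raw)
  expect_equal(ad$a50, 2, tolerance = 0.01)
  expect_error(
    fit_a_distribution(tibble::tibble(a = rep(2, 10), b = 1, rmse = 0.1)),
    "`a`")
})

test_that("the heteroscedastic regression recovers known parameters", {
  truth <- list(alpha = -1.0, beta = 0.6, sigma0 = 0.05, sigma1 = 0.1)
  raw <- generate_raw_estimates(n = 200, alpha = truth$alpha,
                                beta = truth$beta, sigma0 = truth$sigma0,
                                sigma1 = truth$sigma1, seed = 24L)
  fit <- fit_logb_regression(raw, seed = 25)
  expect_true(fit$converged)
  expect_lt(max(fit$diagnostics$rhat), 1.01)
  expect_gt(min(fit$diagnostics$ess_bulk, fit$diagnostics$ess_tail), 400)
  td <- tidy(fit)
  for (p in names(truth)) {
    row <- td[td$parameter == p, ]
    expect_lte(row$conf.low, truth[[p]])
    expect_gte(row$conf.high, truth[[p]])
  }
  expect_identical(nrow(fit$draws), 4000L)
})

test_that("homoscedastic truth drives the sigma1 posterior towards zero", {
  raw <- generate_raw_estimates(n = 500, sigma0 = 0.15, sigma1 = 0,
                                seed = 26L)
  fit <- fit_logb_regression(raw, seed = 27)
  q975 <- quantile(fit$draws$sigma1, 0.975)
  expect_lt(q975, 0.2)
})

test_that("prior-only sampling reproduces the stated priors", {
  fit <- fit_logb_regression(raw = NULL, prior_only = TRUE, seed = 28)
  for (p in c("alpha", "beta")) {
    v <- fit$draws[[p]]
    expect_equal(mean(v), 0, tolerance = 0.08)
    expect_equal(sd(v), 1, tolerance = 0.08)
  }
  # half-Cauchy draws are all positive with heavy tails
  expect_true(all(fit$draws$sigma0 > 0))
  expect_true(all(fit$draws$sigma1 > 0))
  expect_gt(quantile(fit$draws$sigma0, 0.99), 2)
})

test_that("the gamma noise model recovers its parameters and converges", {
  set.seed(29)
  sig <- rgamma(300, shape = 3, rate = 10)
  fit <- fit_sigma_population(sig, seed = 30)
  expect_true(fit$converged)
  expect_gt(min(fit$diagnostics$ess_bulk, fit$diagnostics$ess_tail), 400)
  expect_equal(mean(fit$draws$c), 3, tolerance = 0.2)
  expect_equal(mean(fit$draws$d), 10, tolerance = 0.2)
})

test_that("degenerate noise input is flagged, not crashed", {
  expect_warning(
    fit <- fit_sigma_population(rep(0.3, 20), seed = 31, iter = 600,
                                warmup = 300),
    "non-converged")
  expect_false(fit$converged)
  expect_error(fit_sigma_population(c(0.1, 0.2, -0.1, 0.3, 0.2)),
               "positive")
  expect_error(fit_sigma_population(rep(0.2, 4)), "At least 5")
})

test_that("posterior predictive ribbon covers well-specified data", {
  raw <- generate_raw_estimates(n = 200, seed = 32L)
  fit <- fit_logb_regression(raw, seed = 33)
  ribbon <- ppc_regression(fit, raw, seed = 34)
  expect_named(ribbon, c("a", "lower", "median", "upper"))
  cov <- ppc_coverage(ribbon, raw)
  expect_gte(cov, 0.90)
  expect_lte(cov, 0.99)
  # median curve tracks the conditional mean of b at the center
  abar <- mean(raw$a)
  med <- approx(ribbon$a, ribbon$median, xout = abar)$y
  expect_equal(med,
               exp(mean(fit$draws$alpha) + mean(fit$draws$beta) * abar),
               tolerance = 0.1)
  # heteroscedastic truth widens the ribbon with a
  width <- ribbon$upper - ribbon$lower
  expect_gt(mean(width[ribbon$a > quantile(raw$a, 0.8)]),
            mean(width[ribbon$a < quantile(raw$a, 0.2)]))
})

test_that("regression parameters are recovered across seeded replicates", {
  # 20 fixtures at n = 500; the generating values of all four parameters
  # must fall inside their central 95% credible intervals in >= 18 runs
  truth <- c(alpha = -1.0, beta = 0.6, sigma0 = 0.05, sigma1 = 0.1)
  hits <- vapply(1:20, function(s) {
    raw <- generate_raw_estimates(n = 500, seed = s)
    fit <- fit_logb_regression(raw, iter = 1500, warmup = 500,
                               seed = 1000 + s)
    td <- tidy(fit)
    all(vapply(names(truth), function(p) {
      row <- td[td$parameter == p, ]
      row$conf.low <= truth[[p]] && row$conf.high >= truth[[p]]
    }, logical(1)))
  }, logical(1))
  expect_gte(sum(hits), 18)
})
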