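test_that("design specification validates its fields", {
  expect_error(design_spec("comparison", "within", x1 = 250, x2 = 250),
               "differ")
  expect_error(design_spec("comparison", "within", x1 = 250),
               "x1")
  expect_error(design_spec("comparison", "within", x1 = 250, x2 = 500,
                           N = 1), "at least 2")
  expect_error(design_spec("intervention", "within", x = 200, chi = -1),
               "positive")
  expect_error(design_spec("comparison", "within", x1 = 10, x2 = 100,
                           eta = 2), "0, 1")
  expect_error(design_spec("comparison", "within", x1 = 10, x2 = 100,
                           alpha = 0), "inside")
  spec <- design_spec("intervention", "between", x = 200, chi = 0.5,
                      N = 30, eta = 0.4, alpha = 0.01)
  expect_s3_class(spec, "mel_design")
  expect_equal(spec$chi, 0.5)
})

test_that("trials are reproducible and respect their contracts", {
  model <- test_popmodel()
  spec <- design_spec("comparison", "within", x1 = 100, x2 = 1000, N = 15)
  expect_identical(comparison_trial(model, spec, seed = 71),
                   comparison_trial(model, spec, seed = 71))
  ispec <- design_spec("intervention", "between", x = 200, chi = 0.3,
                       N = 15)
  expect_identical(intervention_trial(model, ispec, seed = 72),
                   intervention_trial(model, ispec, seed = 72))
  expect_error(comparison_trial(model, ispec), "comparison")
  expect_error(intervention_trial(model, spec), "intervention")
})

test_that("near-null comparisons reject with the correct sign at ~alpha/2", {
  model <- test_popmodel()
  spec <- design_spec("comparison", "within", x1 = 250, x2 = 252, N = 10)
  pc <- estimate_power(model, spec, replicates = 2000, seed = 73)
  se <- sqrt(0.025 * 0.975 / 2000)
  expect_lt(abs(pc$power - 0.025), 3 * se)
})

test_that("extreme separation at eta = 0 gives essentially full power", {
  model <- test_popmodel()
  spec <- design_spec("comparison", "within", x1 = 10, x2 = 1990,
                      N = 100, eta = 0)
  pc <- estimate_power(model, spec, replicates = 500, seed = 74)
  expect_gte(pc$power, 0.99)
})

test_that("null interventions (chi = 1) reject at the test size", {
  model <- test_popmodel()
  for (design in c("within", "between")) {
    spec <- design_spec("intervention", design, x = 200, chi = 1, N = 20)
    pc <- estimate_power(model, spec, replicates = 2000, seed = 75)
    se <- sqrt(0.05 * 0.95 / 2000)
    expect_lt(abs(pc$power - 0.05), 3 * se)
  }
})

test_that("strong interventions at the median ED50 are reliably detected", {
  model <- test_popmodel()
  spec <- design_spec("intervention", "within",
                      x = round(10^model$adist$a50), chi = 0.2,
                      N = 50, eta = 0)
  pc <- estimate_power(model, spec, replicates = 500, seed = 76)
  expect_gt(pc$power, 0.9)
})

test_that("power estimates carry their Monte-Carlo error and determinism", {
  model <- test_popmodel()
  spec <- design_spec("comparison", "within", x1 = 100, x2 = 400, N = 10)
  p1 <- estimate_power(model, spec, replicates = 1, seed = 77)
  expect_true(p1$power %in% c(0, 1))
  p2 <- estimate_power(model, spec, replicates = 300, seed = 78)
  expect_identical(p2, estimate_power(model, spec, replicates = 300,
                                      seed = 78))
  expect_equal(p2$mc_se, sqrt(p2$power * (1 - p2$power) / 300))
  # more participants cannot reduce power beyond Monte-Carlo error
  spec_big <- design_spec("comparison", "within", x1 = 100, x2 = 400,
                          N = 100)
  p3 <- estimate_power(model, spec_big, replicates = 300, seed = 79)
  expect_gte(p3$power, p2$power - 3 * sqrt(p2$mc_se^2 + p3$mc_se^2))
})

test_that("power grids enumerate cells and reproduce bit-identically", {
  model <- test_popmodel()
  g <- power_grid(model, "comparison", "within",
                  x1 = 10, x2 = c(100, 400), N = c(10, 20), eta = 1,
                  alpha = 0.05, replicates = 20, seed = 80)
  expect_identical(nrow(g), 4L)
  expect_s3_class(g, "mel_power_grid")
  g2 <- power_grid(model, "comparison", "within",
                   x1 = 10, x2 = c(100, 400), N = c(10, 20), eta = 1,
                   alpha = 0.05, replicates = 20, seed = 80)
  expect_identical(tibble::as_tibble(g), tibble::as_tibble(g2))
  expect_error(power_grid(model, "comparison", "within"), "pairs")
  expect_error(power_grid(model, "intervention", "within", x = 100),
               "chi")
})

test_that("the full comparison design set has the documented cardinality", {
  levels <- seq(10, 1990, by = 20)
  expect_identical(nrow(comparison_pairs(levels)), choose(100, 2) |>
                     as.integer())
  # cells = pairs x 10 sample sizes x 6 heterogeneity levels x 3 test sizes
  expect_identical(choose(100, 2) * 10 * 6 * 3, 891000)
})

test_that("within-subjects designs dominate between-subjects designs", {
  model <- test_popmodel()
  set.seed(81)
  cells <- tibble::tibble(
    x1 = sample(c(10, 50, 100, 250), 4, replace = TRUE),
    x2 = sample(c(400, 750, 1200, 1990), 4),
    N = sample(c(20, 40, 60), 4, replace = TRUE)
  )
  for (i in seq_len(nrow(cells))) {
    sw <- design_spec("comparison", "within", x1 = cells$x1[i],
                      x2 = cells$x2[i], N = cells$N[i])
    sb <- design_spec("comparison", "between", x1 = cells$x1[i],
                      x2 = cells$x2[i], N = cells$N[i])
    pw <- estimate_power(model, sw, replicates = 400, seed = 82 + i)
    pb <- estimate_power(model, sb, replicates = 400, seed = 182 + i)
    expect_gte(pw$power,
               pb$power - 3 * sqrt(pw$mc_se^2 + pb$mc_se^2))
  }
})
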