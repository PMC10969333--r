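test_that("sampled individuals honor the ED25/ED75 rejection bounds", {
  model <- test_popmodel()
  ind <- sample_individuals(model, 10000, seed = 51)
  expect_identical(nrow(ind), 10000L)
  expect_true(all(ind$a > 0 & ind$b > 0 & ind$sigma > 0))
  ed25 <- effective_dose(0.25, ind$a, ind$b)
  ed75 <- effective_dose(0.75, ind$a, ind$b)
  expect_true(all(ed25 >= model$ed25_floor))
  expect_true(all(ed75 <= model$ed75_ceiling))
  # sampled parameters overlay the raw-estimate scatter
  raw <- test_raw()
  expect_lte(min(ind$a), min(raw$a) + 0.2)
  expect_gte(max(ind$a), max(raw$a) - 0.2)
  expect_true(min(ind$b) < min(raw$b) && max(ind$b) > max(raw$b) * 0.5)
  # inverse-transform sampling reproduces the KDE quartiles
  kde_q <- sapply(c(0.25, 0.5, 0.75), function(p) {
    approx(model$adist$cdf, model$adist$grid, xout = p, ties = "ordered")$y
  })
  expect_equal(unname(quantile(ind$a, c(0.25, 0.5, 0.75))), kde_q,
               tolerance = 0.1)
})

test_that("eta = 0 collapses the population onto the median individual", {
  model <- test_popmodel()
  i1 <- sample_individuals_reduced(model, 5, eta = 0, seed = 52)
  i2 <- sample_individuals_reduced(model, 5, eta = 0, seed = 53)
  # all curves identical within and across calls
  expect_equal(var(c(i1$a, i2$a)), 0)
  expect_equal(var(c(i1$b, i2$b)), 0)
  expect_equal(i1$a[1], model$adist$a50)
  rd <- model$regression$draws
  expect_equal(log(i1$b[1]),
               mean(rd$alpha) + mean(rd$beta) * model$adist$a50)
})

test_that("eta = 1 matches the unrestricted sampling process", {
  model <- test_popmodel()
  a1 <- sample_individuals(model, 2000, seed = 54)$a
  a2 <- sample_individuals_reduced(model, 2000, eta = 1, seed = 55)$a
  ks <- suppressWarnings(ks.test(a1, a2))
  expect_gt(ks$p.value, 0.01)
})

test_that("heterogeneity shrinks smoothly with eta", {
  model <- test_popmodel()
  sds <- vapply(seq(0, 1, by = 0.2), function(eta) {
    sd(sample_individuals_reduced(model, 5000, eta = eta,
                                  seed = 56)$a)
  }, numeric(1))
  expect_lt(sds[2], sds[6])  # eta = 0.2 vs eta = 1
  expect_equal(sds[1], 0)
  # spread grows with eta up to Monte-Carlo error
  expect_true(all(diff(sds) > -0.02))
  expect_error(sample_individuals_reduced(model, 5, eta = 1.5), "0, 1")
})

test_that("the logit-normal measurement model stays inside (0, 1)", {
  s_true <- suppression(200, 2, 1.5)
  expect_equal(measure(200, 2, 1.5, sigma = 0), s_true)
  set.seed(57)
  m <- measure(rep(200, 1e6), 2, 1.5, sigma = 1.5)
  expect_true(all(m > 0 & m < 1))
  # logit-normal median equals the point value
  m2 <- measure(rep(200, 10000), 2, 1.5, sigma = 0.5, seed = 58)
  expect_equal(median(m2), s_true, tolerance = 0.01)
  expect_error(measure(1, 2, 1.5, sigma = 0.5), "above 1 lux")
  expect_error(measure(10, 2, 1.5, sigma = -1), "nonnegative")
})

test_that("virtual experiments assemble and reproduce deterministically", {
  model <- test_popmodel()
  ve <- virtual_experiment(model, n = 41, seed = 59)
  expect_s3_class(ve, "mel_experiment")
  expect_identical(nrow(ve), 41L * 7L)
  expect_identical(dplyr::n_distinct(ve$individual_id), 41L)
  expect_true(all(ve$measured_suppression > 0 &
                    ve$measured_suppression < 1))
  expect_equal(tibble::as_tibble(ve),
               tibble::as_tibble(virtual_experiment(model, n = 41,
                                                    seed = 59)))
  # noiseless median individual reproduces its true curve exactly
  ve0 <- virtual_experiment(model, n = 1, eta = 0, sigma = 0, seed = 60)
  expect_equal(ve0$measured_suppression, ve0$true_suppression)
  expect_equal(ve0$true_suppression,
               suppression(ve0$lux, ve0$a, ve0$b))
})

test_that("experiment checks summarize extrema and saturations", {
  model <- test_popmodel()
  # constructed experiment with every measurement at 0.5
  fake <- virtual_experiment(model, n = 10, seed = 61)
  fake$measured_suppression <- 0.5
  chk <- experiment_checks(fake)
  expect_equal(chk$min, rep(0.5, 7))
  expect_equal(chk$max, rep(0.5, 7))
  expect_equal(chk$frac_below_5, rep(0, 7))
  expect_equal(chk$frac_above_95, rep(0, 7))

  ves <- lapply(1:20, function(i) {
    virtual_experiment(model, n = 41, seed = 600 + i, experiment_id = i)
  })
  chk2 <- experiment_checks(ves)
  expect_identical(nrow(chk2), 20L * 7L)
  expect_true(all(chk2$frac_below_5 >= 0 & chk2$frac_below_5 <= 1))
  expect_true(all(chk2$frac_below_5 + chk2$frac_above_95 <= 1))
  # at the top illuminance the upper saturation dominates the lower
  top <- chk2[chk2$lux == 2000, ]
  expect_gt(mean(top$frac_above_95), mean(top$frac_below_5))

  short <- virtual_experiment(model, n = 5, grid = c(10, 100), seed = 62)
  expect_error(experiment_checks(list(fake, short)), "same measurement")
})
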