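test_that("Matheron estimator matches hand and brute-force computation", {
  # two points: gamma = (0 - 2)^2 / 2 = 2 in the single bin
  two <- grid_counts(data.frame(x = c(0, 10), y = c(0, 0), count = c(0, 2)))
  sv2 <- empirical_semivariogram(two, n_bins = 1, max_lag = 15)
  expect_equal(sv2$gamma, 2)
  expect_equal(sv2$n_pairs, 1L)

  # constant field: flat zero semivariogram
  const <- grid_counts(data.frame(x = rep(1:4, 4), y = rep(1:4, each = 4),
                                  count = 7L))
  expect_true(all(empirical_semivariogram(const, n_bins = 4)$gamma == 0))

  # 5x5 grid with arbitrary integers vs all-pairs brute force
  set.seed(41)
  gc <- random_grid_counts(5, 5, lambda = 8)
  for (nb in c(4, 7)) {
    ml <- max(dist(gc[, c("x", "y")])) / 2
    sv <- empirical_semivariogram(gc, n_bins = nb, max_lag = ml)
    oracle <- brute_semivariogram(gc, nb, ml)
    expect_equal(sv$gamma, oracle$gamma)
    expect_equal(sv$n_pairs, oracle$n_pairs)
  }

  expect_error(empirical_semivariogram(grid_counts(
    data.frame(x = c(1, 1), y = c(2, 2), count = c(1, 2)))), "coincident")
})

test_that("noiseless model curves are recovered to below 1% relative error", {
  h <- seq(20, 400, by = 20)
  cases <- list(
    list(model = "exponential", C0 = 50, C = 450, a = 150),
    list(model = "spherical", C0 = 100, C = 900, a = 200),
    list(model = "gaussian", C0 = 30, C = 270, a = 120))
  for (cs in cases) {
    u <- h / cs$a
    g <- cs$C0 + cs$C * switch(cs$model,
      exponential = 1 - exp(-3 * u),
      spherical = ifelse(u >= 1, 1, 1.5 * u - 0.5 * u^3),
      gaussian = 1 - exp(-3 * u^2))
    fit <- fit_variogram(data.frame(lag = h, gamma = g, n_pairs = 30), cs$model)
    expect_true(fit$converged)
    expect_lt(abs(fit$nugget - cs$C0) / cs$C0, 0.01)
    expect_lt(abs(fit$psill - cs$C) / cs$C, 0.01)
    expect_lt(abs(fit$range_eff - cs$a) / cs$a, 0.01)
    # and the generating model wins selection
    expect_equal(select_best_model(fit_variogram_models(
      data.frame(lag = h, gamma = g, n_pairs = 30)))$model, cs$model)
  }

  # pure nugget: flat curve gives ~zero structural variance and DD ~ 0
  flat <- data.frame(lag = h, gamma = 100 + 0 * h, n_pairs = 30)
  fn <- fit_variogram(flat, "exponential")
  expect_lt(fn$psill, 1)
  expect_lt(fn$dd, 1)
})

test_that("model selection breaks ties by r2 then fixed model order", {
  h <- seq(20, 400, by = 20)
  g <- 50 + 450 * (1 - exp(-3 * h / 150))
  sv <- data.frame(lag = h, gamma = g, n_pairs = 30)
  f1 <- fit_variogram(sv, "exponential")
  expect_equal(select_best_model(list(f1))$model, "exponential")
  # exact duplicates: documented order returns the exponential entry
  f2 <- f1
  f2$model <- "gaussian"
  expect_equal(select_best_model(list(gaussian = f2, exponential = f1))$model,
               "exponential")
  f1$converged <- FALSE
  f2$converged <- FALSE
  expect_error(select_best_model(list(f1, f2)), "converged")
})

test_that("degree of spatial dependence follows the nugget-to-sill formula", {
  b1 <- spatial_dependence(14400, 212600)
  expect_equal(b1$dd, 93.2, tolerance = 0.0005)
  expect_equal(b1$dd_class, "strong")
  b13 <- spatial_dependence(15930, 38320)
  expect_equal(b13$dd, 58.4, tolerance = 0.0005)
  expect_equal(b13$dd_class, "moderate")

  expect_equal(spatial_dependence(0, 100)$dd, 100)
  expect_equal(spatial_dependence(100, 100)$dd, 0)
  expect_equal(spatial_dependence(100, 100)$dd_class, "weak")
  # boundary rules: <=25 weak, >=76 strong, in between moderate
  expect_equal(spatial_dependence(75, 100)$dd_class, "weak")
  expect_equal(spatial_dependence(24.5, 100)$dd_class, "moderate")
  expect_equal(spatial_dependence(24, 100)$dd_class, "strong")
  expect_error(spatial_dependence(10, 0), "positive")
})

test_that("DD is invariant under count rescaling", {
  set.seed(43)
  gc <- random_grid_counts(7, 7, lambda = 6)
  sv1 <- empirical_semivariogram(gc, n_bins = 6)
  gck <- gc
  gck$count <- gck$count * 3
  svk <- empirical_semivariogram(gck, n_bins = 6)
  expect_equal(svk$gamma, 9 * sv1$gamma)
  f1 <- fit_variogram(sv1, "exponential")
  fk <- fit_variogram(svk, "exponential")
  expect_equal(fk$dd, f1$dd, tolerance = 1e-4)
  expect_equal(fk$sill_total, 9 * f1$sill_total, tolerance = 1e-3)
})

test_that("variogram_fit methods expose coefficients, predictions, plot", {
  h <- seq(20, 400, by = 20)
  g <- 80 + 320 * (1 - exp(-3 * h / 180))
  fit <- fit_variogram(data.frame(lag = h, gamma = g, n_pairs = 25),
                       "exponential")
  expect_named(coef(fit), c("nugget", "psill", "sill_total", "range_eff"))
  expect_equal(predict(fit, 0), 0)
  expect_equal(predict(fit, 1e6), fit$sill_total, tolerance = 1e-6)
  expect_lt(max(abs(residuals(fit))), 1e-3)
  expect_s3_class(summary(fit), "data.frame")
  expect_output(print(fit), "degree of spatial dependence")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
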