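test_that("relative RMSE normalises by the observed maximum", {
  expect_equal(rmse_rel(c(1, 2, 3), c(1, 2, 3)), 0)
  # hand arithmetic: 100 x sqrt((0^2 + 60^2)/2) / 600 = 7.071
  expect_equal(rmse_rel(c(600, 300), c(600, 360)),
               100 * sqrt(1800) / 600, tolerance = 1e-12)
  # scale invariance
  obs <- c(10, 40, 25)
  sim <- c(12, 35, 27)
  for (c_ in c(0.1, 3, 1e4))
    expect_equal(rmse_rel(c_ * obs, c_ * sim), rmse_rel(obs, sim),
                 tolerance = 1e-12)
  expect_error(rmse_rel(c(0, 0), c(1, 1)), "positive")
})

test_that("fixtures are reproducible and exact at zero noise", {
  tmpl <- list(experiment_series(
    "feed_volume", time_h = c(1, 2, 4, 6), values = numeric(4),
    scenario = list(draw_molarity_M = 0.8, dt_s = 240,
                    policy = pressure_policy("constant", P_const = 1))))
  clean <- make_fixture("pro", c(A = 1.2e-7), tmpl, noise_pct = 0, seed = 7,
                        fixed = list(B = 1.35e-7, S_struct = 6.78e-4))
  again <- make_fixture("pro", c(A = 1.2e-7), tmpl, noise_pct = 0, seed = 99,
                        fixed = list(B = 1.35e-7, S_struct = 6.78e-4))
  expect_identical(clean[[1]]$values, again[[1]]$values)  # noise-free
  noisy1 <- make_fixture("pro", c(A = 1.2e-7), tmpl, noise_pct = 2, seed = 7,
                         fixed = list(B = 1.35e-7, S_struct = 6.78e-4))
  noisy2 <- make_fixture("pro", c(A = 1.2e-7), tmpl, noise_pct = 2, seed = 7,
                         fixed = list(B = 1.35e-7, S_struct = 6.78e-4))
  expect_identical(noisy1[[1]]$values, noisy2[[1]]$values)  # same seed
  expect_false(identical(clean[[1]]$values, noisy1[[1]]$values))
  # the fixture sits on the forward simulation when noise-free
  expect_true(all(is.finite(clean[[1]]$values)))
  expect_true(all(clean[[1]]$values < 600 & clean[[1]]$values > 0))
})

test_that("the fitted point never scores worse than the start point", {
  tmpl <- list(experiment_series(
    "feed_volume", time_h = c(2, 4, 6), values = numeric(3),
    scenario = list(draw_molarity_M = 0.8, dt_s = 240,
                    policy = pressure_policy("constant", P_const = 1))))
  fixed <- list(B = 1.35e-7, S_struct = 6.78e-4)
  series <- make_fixture("pro", c(A = 1.2e-7), tmpl, noise_pct = 2,
                         seed = 3, fixed = fixed)
  prob <- calibration_problem("pro", series,
                              start = c(A = 3e-7),
                              lower = c(A = 2e-8), upper = c(A = 8e-7),
                              fixed = fixed)
  res <- fit(prob, n_starts = 1)
  start_obj <- sum(((series[[1]]$values -
    promec:::simulate_series("pro", c(A = 3e-7), series[[1]], fixed)) /
      max(series[[1]]$values))^2)
  expect_lte(res$objective, start_obj + 1e-12)
  expect_true(res$par["A"] >= 2e-8 && res$par["A"] <= 8e-7)
})

test_that("the water permeability is recovered from 2%-noise fixtures", {
  tmpl <- list(experiment_series(
    "feed_volume", time_h = c(1, 2, 3, 4, 5, 6), values = numeric(6),
    scenario = list(draw_molarity_M = 0.8, dt_s = 240,
                    policy = pressure_policy("constant", P_const = 1))))
  fixed <- list(B = 1.35e-7, S_struct = 6.78e-4)
  A_true <- 1.19e-7
  for (seed in 1:3) {
    series <- make_fixture("pro", c(A = A_true), tmpl, noise_pct = 2,
                           seed = seed, fixed = fixed)
    prob <- calibration_problem("pro", series, start = c(A = 3e-7),
                                lower = c(A = 2e-8), upper = c(A = 8e-7),
                                fixed = fixed)
    res <- fit(prob, n_starts = 1)
    expect_lt(abs(res$par[["A"]] - A_true) / A_true, 0.10)
  }
})

test_that("membrane calibration pins the 0.8 M validation endpoint", {
  mem <- calibrate_membrane()
  info <- attr(mem, "fit")
  expect_equal(info$endpoints_predicted[1], 138, tolerance = 1e-4)
  # shipped defaults are this calibration, frozen
  def <- default_membrane()
  expect_equal(mem$A, def$A, tolerance = 1e-4)
  expect_equal(mem$B, def$B)
  expect_equal(mem$S_struct, def$S_struct)
})
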