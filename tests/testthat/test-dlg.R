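# aOSG plan construction, DLG tuning, sweeping-gap and transmission
# estimators.

test_that("the default aOSG plan set is the 3 x 5 cross product", {
  plans <- build_aosg_plans()
  expect_equal(nrow(plans), 15L)
  expect_equal(plans$shift_mm, plans$gap_mm * plans$tg_fraction)
  expect_equal(plans$shift_mm[plans$gap_mm == 30 & plans$tg_fraction == 1], 30)
  expect_error(build_aosg_plans(tg_fractions = numeric(0)), "non-empty")
  expect_error(build_aosg_plans(gaps = c(-10, 20)), "> 0")
})

test_that("DLG tuning recovers the truth when both sides share the TG coefficient", {
  truth <- noise_free_truth(dlg = 0.55, tg_meas = 0.1, tg_calc = 0.1)
  curve <- tune_dlg(engine_aosg_set(truth))
  expect_lt(abs(curve$optimum - 0.55), 0.05 + 1e-9)
  # on a grid containing the exact truth the cost reaches 0 there
  curve2 <- tune_dlg(engine_aosg_set(truth), dlg_grid = seq(0, 3.4, by = 0.05))
  expect_lt(abs(curve2$optimum - 0.55), 1e-12)
  expect_equal(curve2$value_at_optimum, 0, tolerance = 1e-12)
  expect_equal(curve2$per_plan_sd[which.min(abs(curve2$dlg_grid - 0.55))], 0,
               tolerance = 1e-12)
})

test_that("a TPS overestimating tongue-and-groove drags the aOSG DLG upwards", {
  truth <- noise_free_truth(dlg = 0.55, tg_meas = 0.05, tg_calc = 0.20)
  curve <- tune_dlg(engine_aosg_set(truth))
  expect_gt(curve$optimum, 0.55)
  # the spread over the plans at the optimum stays below the worse endpoint
  n <- length(curve$dlg_grid)
  j0 <- which(curve$dlg_grid == curve$optimum)
  expect_lte(curve$per_plan_sd[j0],
             max(curve$per_plan_sd[1], curve$per_plan_sd[n]))
})

test_that("the tuning curve equals a brute-force grid evaluation and is unimodal", {
  truth <- noise_free_truth(dlg = 1.2, tg_meas = 0.02, tg_calc = 0.12)
  rs <- engine_aosg_set(truth)
  grid <- seq(0, 3.4, by = 0.2)
  curve <- tune_dlg(rs, dlg_grid = grid)
  brute <- vapply(grid, function(d) {
    calc <- vapply(seq_len(nrow(rs$plans)), function(i) {
      rs$calculated_provider(rs$plans[i, ], d)
    }, numeric(1))
    mean(abs((calc - rs$measured) / rs$measured))
  }, numeric(1))
  expect_equal(curve$mean_abs_diff, brute, tolerance = 1e-14)
  j0 <- which.min(brute)
  expect_true(all(diff(brute[seq_len(j0)]) <= 1e-14))
  expect_true(all(diff(brute[j0:length(brute)]) >= -1e-14))
})

test_that("parabolic refinement stays inside the bracketing grid cell", {
  truth <- noise_free_truth(dlg = 0.55, tg_meas = 0.1, tg_calc = 0.1)
  curve <- tune_dlg(engine_aosg_set(truth), refine = TRUE)
  expect_gte(curve$optimum, 0.5)
  expect_lte(curve$optimum, 0.6)
  expect_lt(abs(curve$optimum - 0.55), 0.03)
})

test_that("transmission is the closed-to-open ratio with guarded inputs", {
  expect_equal(estimate_transmission(100, 1.49), 0.0149)
  expect_equal(estimate_transmission(100, 0), 0)
  expect_error(estimate_transmission(100, 100), "smaller")
  expect_error(estimate_transmission(0, 0), "> 0")
})

test_that("the sweeping-gap extrapolation is exact on the affine engine", {
  for (dlg in c(0, 0.55, 2.0)) {
    truth <- noise_free_truth(dlg = dlg)
    gaps <- c(5, 10, 20, 30, 40)
    readings <- vapply(gaps, sweeping_gap_reading, numeric(1),
                       truth = truth, role = "measured", tg_fraction = 0)
    series <- sweeping_series(gaps, readings,
                              open_reading = static_reading(truth, "open"),
                              closed_reading = static_reading(truth, "closed"))
    est <- estimate_dlg_sweeping(series, truth$params$transmission)
    expect_equal(est, dlg, tolerance = 1e-10)
  }
})

test_that("the sweeping-gap estimator is unbiased under measurement noise", {
  est <- vapply(1:100, function(s) {
    truth <- synthetic_truth(beam_params(0.7, 0.35, 0.55, 0.0126),
                             detector_sigma = 0, noise_cv = 0.003, seed = s)
    gaps <- c(5, 10, 20, 30, 40)
    readings <- vapply(gaps, sweeping_gap_reading, numeric(1),
                       truth = truth, role = "measured", tg_fraction = 0)
    series <- sweeping_series(gaps, readings,
                              open_reading = static_reading(truth, "open"),
                              closed_reading = static_reading(truth, "closed"))
    estimate_dlg_sweeping(series, 0.0126)
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.55), 0.03)
})

test_that("degenerate sweeping series are rejected", {
  truth <- noise_free_truth()
  expect_error(sweeping_series(c(10, 5), c(0.1, 0.2), 1, 0.01), "increasing")
  expect_error(sweeping_series(c(10, 20), c(0.1, 0.2), 1, 2), "closed_reading")
  s <- sweeping_series(c(10, 20), c(0.3, 0.2), 1, 0.01)  # negative slope
  expect_error(estimate_dlg_sweeping(s, 0.01), "slope")
})
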