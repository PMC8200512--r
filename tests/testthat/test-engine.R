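# Closed-form dose engine: profiles, sweeping-gap law, output factors,
# dose planes.

test_that("profile edge width matches the Gaussian closed form", {
  # brute-force oracle: dense evaluation of the edge law, crossings by
  # nearest sample on a 1e-4 mm grid
  sigma <- 1.0; a <- 20
  xs <- seq(15, 25, by = 1e-4)
  edge <- 0.5 * (pracma::erf((a - xs) / (sqrt(2) * sigma)) + 1)  # right edge
  w_brute <- abs(xs[which.min(abs(edge - 0.2))] - xs[which.min(abs(edge - 0.8))])
  expect_equal(w_brute, expected_erf_width(sigma), tolerance = 1e-3)

  truth <- noise_free_truth(sigma_x = 1.0, sigma_y = 1.0, dlg = 0,
                            transmission = 0)
  p <- simulate_profile(field_geometry(40), truth, "calculated")
  pen <- extract_penumbra(p)
  expect_equal(pen$left, w_brute, tolerance = 0.01)
  expect_equal(pen$right, w_brute, tolerance = 0.01)
})

test_that("zero spot size degenerates to a step edge", {
  truth <- noise_free_truth(sigma_x = 0, sigma_y = 0, dlg = 0, transmission = 0)
  for (spacing in c(0.1, 0.01)) {
    pos <- seq(-35, 35, by = spacing)
    p <- simulate_profile(field_geometry(40), truth, "calculated", pos)
    pen <- extract_penumbra(p)
    # both crossings interpolate within one sample of the edge
    expect_lte(pen$left, 2 * spacing)
    expect_lte(pen$right, 2 * spacing)
  }
})

test_that("measured and calculated profiles coincide without detector blur or noise", {
  truth <- noise_free_truth(sigma_x = 0.8, dlg = 1.2, transmission = 0.015)
  geom <- field_geometry(20)
  pm <- simulate_profile(geom, truth, "measured")
  pc <- simulate_profile(geom, truth, "calculated")
  expect_identical(pm$readings, pc$readings)
})

test_that("noise-free profiles are symmetric and floor at the transmission level", {
  truth <- noise_free_truth(sigma_x = 1.1, dlg = 0, transmission = 0.02)
  pos <- seq(-40, 40, by = 0.1)
  p <- simulate_profile(field_geometry(20), truth, "measured", pos)
  expect_equal(p$readings, rev(p$readings))
  # far outside the field the normalized reading tends to T * 100 / central
  far <- abs(pos) > 35
  central_raw <- (1 - 0.02) * 1 + 0.02  # closed form at x = 0, sigma small
  expect_true(all(abs(p$readings[far] - 100 * 0.02 / central_raw) < 1e-9))
})

test_that("profiles not spanning the penumbra levels are refused", {
  truth <- noise_free_truth()
  expect_error(
    simulate_profile(field_geometry(40), truth, "measured",
                     positions = seq(-5, 5, by = 0.1)),
    "20-80%")
})

test_that("sweeping-gap law is affine in the gap with DLG-independent slope", {
  truth1 <- noise_free_truth(dlg = 0.3)
  truth2 <- noise_free_truth(dlg = 2.7)
  g <- c(10, 30, 60)
  d1 <- sweeping_gap_reading(g, truth1, "measured")
  d2 <- sweeping_gap_reading(g, truth2, "measured")
  slope1 <- diff(d1) / diff(g)
  slope2 <- diff(d2) / diff(g)
  expect_equal(slope1[1], slope1[2], tolerance = 1e-12)  # affine
  expect_equal(slope1, slope2, tolerance = 1e-12)        # slope free of DLG
})

test_that("tongue-and-groove asymmetry enters the sweeping dose as lambda * s / L", {
  # lambda_meas = 0.05, lambda_calc = 0, g = 20, tau = 0.5 -> diff = 0.005
  truth <- synthetic_truth(beam_params(0, 0, 1.0, 0),
                           tg_loss_measured = 0.05, tg_loss_calculated = 0,
                           detector_sigma = 0, noise_cv = 0)
  dm <- sweeping_gap_reading(20, truth, "measured", tg_fraction = 0.5)
  dc <- sweeping_gap_reading(20, truth, "calculated", tg_fraction = 0.5)
  expect_equal(dc - dm, 0.005, tolerance = 1e-12)
  # identical coefficients and DLG -> exact agreement on every plan
  truth_eq <- noise_free_truth(tg_meas = 0.1, tg_calc = 0.1)
  plans <- build_aosg_plans()
  for (i in seq_len(nrow(plans))) {
    expect_equal(
      sweeping_gap_reading(plans$gap_mm[i], truth_eq, "measured",
                           tg_fraction = plans$tg_fraction[i]),
      sweeping_gap_reading(plans$gap_mm[i], truth_eq, "calculated",
                           tg_fraction = plans$tg_fraction[i]),
      tolerance = 1e-15)
  }
})

test_that("sweeping gap rejects non-physical gaps", {
  truth <- noise_free_truth()
  expect_error(sweeping_gap_reading(0, truth, "measured"), "gap")
  expect_error(sweeping_gap_reading(100, truth, "measured"), "gap")
  expect_error(sweeping_gap_reading(20, truth, "measured", tg_fraction = 1.5),
               "tg_fraction")
})

test_that("output factor has the expected monotonicities and limits", {
  # no occlusion: point source, no transmission
  expect_equal(output_factor(c(5, 10, 40), beam_params(0, 0, 0, 0)),
               c(1, 1, 1))
  # finite-difference oracle at 5 mm
  p0 <- beam_params(1.0, 0.6, 1.2, 0.015)
  h <- 1e-4
  d_dlg <- (output_factor(5, beam_params(1.0, 0.6, 1.2 + h, 0.015)) -
            output_factor(5, beam_params(1.0, 0.6, 1.2 - h, 0.015))) / (2 * h)
  d_sx <- (output_factor(5, beam_params(1.0 + h, 0.6, 1.2, 0.015)) -
           output_factor(5, beam_params(1.0 - h, 0.6, 1.2, 0.015))) / (2 * h)
  d_t <- (output_factor(5, beam_params(1.0, 0.6, 1.2, 0.015 + h)) -
          output_factor(5, beam_params(1.0, 0.6, 1.2, 0.015 - h))) / (2 * h)
  expect_gt(d_dlg, 0)
  expect_lt(d_sx, 0)
  expect_gt(d_t, 0)
  # large-field limit
  expect_equal(output_factor(300, p0), 1, tolerance = 1e-9)
})

test_that("dose planes are deterministic, linear and refinement-consistent", {
  pars <- beam_params(1, 1, 0.5, 0.01)
  pat <- modulation_pattern(seed = 11)
  a <- simulate_dose_plane(pars, pat, spacing = 2, extent = 30)
  b <- simulate_dose_plane(pars, pat, spacing = 2, extent = 30)
  expect_identical(a$dose, b$dose)
  # uniform scaling of the pattern weights scales every pixel (T = 0)
  pars0 <- beam_params(1, 1, 0.5, 0)
  pat2 <- pat; pat2$weight <- 2 * pat2$weight
  a0 <- simulate_dose_plane(pars0, pat, spacing = 2, extent = 30)
  a2 <- simulate_dose_plane(pars0, pat2, spacing = 2, extent = 30)
  expect_equal(a2$dose, 2 * a0$dose, tolerance = 1e-12)
  # halving the spacing: closed form at shared points is identical
  fine <- simulate_dose_plane(pars, pat, spacing = 1, extent = 30)
  expect_equal(fine$dose[seq(1, 61, by = 2), seq(1, 61, by = 2)], a$dose,
               tolerance = 1e-12)
})

test_that("two seeds differ only through noise", {
  tr1 <- synthetic_truth(beam_params(0.7, 0.35, 0.55, 0.0126),
                         detector_sigma = 0, noise_cv = 0.003, seed = 1)
  tr2 <- synthetic_truth(beam_params(0.7, 0.35, 0.55, 0.0126),
                         detector_sigma = 0, noise_cv = 0.003, seed = 2)
  g <- field_geometry(20)
  expect_false(identical(simulate_profile(g, tr1, "measured")$readings,
                         simulate_profile(g, tr2, "measured")$readings))
  # noise off: seeds are irrelevant
  tr1$noise_cv <- 0; tr2$noise_cv <- 0
  expect_identical(simulate_profile(g, tr1, "measured")$readings,
                   simulate_profile(g, tr2, "measured")$readings)
})
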