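# Shared fixture builders for the synthetic engine.

noise_free_truth <- function(sigma_x = 0.7, sigma_y = 0.35, dlg = 0.55,
                             transmission = 0.0126,
                             tg_meas = 0.05, tg_calc = 0.05, seed = 1L) {
  synthetic_truth(beam_params(sigma_x, sigma_y, dlg, transmission),
                  tg_loss_measured = tg_meas, tg_loss_calculated = tg_calc,
                  detector_sigma = 0, noise_cv = 0, seed = seed)
}

profile_set <- function(truth, role = "measured", axis = "crossline",
                        field_sizes = c(5, 10, 20, 30, 40)) {
  lapply(field_sizes, function(fs) {
    simulate_profile(field_geometry(fs, axis = axis), truth, role)
  })
}

# Calculated-profile provider for spot tuning, matching measured positions.
spot_provider <- function(meas, axis = "crossline") {
  function(sig) {
    lapply(meas, function(mp) {
      pars <- if (axis == "crossline") beam_params(sigma_x = sig) else
        beam_params(sigma_y = sig)
      simulate_profile(field_geometry(mp$field_size, axis = axis),
                       synthetic_truth(pars, detector_sigma = 0, noise_cv = 0),
                       role = "calculated", positions = mp$positions)
    })
  }
}

# aOSG reading set drawn from the engine: measured side uses the truth,
# calculated side re-evaluates with a candidate DLG and the truth's
# calculated TG coefficient.
engine_aosg_set <- function(truth, plans = build_aosg_plans()) {
  meas <- vapply(seq_len(nrow(plans)), function(i) {
    sweeping_gap_reading(plans$gap_mm[i], truth, "measured",
                         tg_fraction = plans$tg_fraction[i])
  }, numeric(1))
  provider <- function(plan, d) {
    p <- truth$params
    calc_truth <- synthetic_truth(
      beam_params(p$sigma_x, p$sigma_y, dlg = d, transmission = p$transmission),
      tg_loss_measured = truth$tg_loss_measured,
      tg_loss_calculated = truth$tg_loss_calculated,
      detector_sigma = 0, noise_cv = 0)
    sweeping_gap_reading(plan$gap_mm, calc_truth, "calculated",
                         tg_fraction = plan$tg_fraction)
  }
  aosg_reading_set(plans, meas, provider)
}

expected_erf_width <- function(sigma) 2 * sqrt(2) * pracma::erfinv(0.6) * sigma
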