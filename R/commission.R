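#' Generate a complete synthetic commissioning data set
#'
#' Writes every input family consumed by [run_commission()] from the
#' synthetic dose engine: ten measured profiles (five field sizes, two
#' axes), the fifteen aOSG plans with measured point doses, a sweeping-gap
#' series with open and closed readings, a two-detector output-factor table,
#' a measured and a calculated dose plane, and a YAML run configuration
#' pointing at all of them. Everything is deterministic given the truth's
#' seed.
#'
#' @param truth A [synthetic_truth()]: the ground truth the pipeline should
#'   recover.
#' @param dir Output directory (created if missing).
#' @param field_sizes Profile field sizes, mm.
#' @param sweep_gaps Gap widths of the sweeping-gap series, mm.
#' @param of_field_sizes Output-factor field sizes, mm.
#' @param doe_levels A [factor_levels()] used for the DOE stage.
#' @param plane_params Parameters of the calculated (evaluated) dose plane;
#'   defaults to the truth parameters so the QA stage compares a perfectly
#'   commissioned model.
#' @return Invisibly, a list with the config path and all file paths.
#' @export
generate_fixtures <- function(truth, dir,
                              field_sizes = c(5, 10, 20, 30, 40),
                              sweep_gaps = c(5, 10, 20, 30, 40),
                              of_field_sizes = c(5, 10, 15, 20, 30, 40),
                              doe_levels = levels_hd_x6(),
                              plane_params = truth$params) {
  stopifnot(inherits(truth, "synthetic_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "profiles"), showWarnings = FALSE)

  prof_files <- character(0)
  for (axis in c("crossline", "inline")) {
    for (fs in field_sizes) {
      p <- simulate_profile(field_geometry(fs, axis = axis), truth, "measured")
      f <- file.path(dir, "profiles", sprintf("meas_%s_%gmm.csv", axis, fs))
      write_profile_csv(p, f)
      prof_files <- c(prof_files, f)
    }
  }

  plans <- build_aosg_plans()
  meas_dose <- vapply(seq_len(nrow(plans)), function(i) {
    sweeping_gap_reading(plans$gap_mm[i], truth, "measured",
                         tg_fraction = plans$tg_fraction[i])
  }, numeric(1))
  plans_file <- file.path(dir, "aosg_plans.csv")
  readings_file <- file.path(dir, "aosg_readings.csv")
  write_aosg_plans_csv(plans, plans_file)
  write_readings_csv(data.frame(label = plans$label, measured_dose = meas_dose),
                     readings_file)

  sweep_read <- vapply(sweep_gaps, sweeping_gap_reading, numeric(1),
                       truth = truth, role = "measured", tg_fraction = 0)
  series <- sweeping_series(sweep_gaps, sweep_read,
                            open_reading = static_reading(truth, "open"),
                            closed_reading = static_reading(truth, "closed"))
  sweeping_file <- file.path(dir, "sweeping.csv")
  write_sweeping_csv(series, sweeping_file)

  # Two small-field detectors with synthetic correction factors near unity;
  # raw ratios are defined so the corrected reading reproduces the engine.
  of_true <- output_factor(of_field_sizes, truth$params, "measured")
  corr <- list(diamond = 1 - 0.02 * exp(-of_field_sizes / 10),
               razor = 1 + 0.015 * exp(-of_field_sizes / 10))
  of_tab <- do.call(rbind, lapply(names(corr), function(det) {
    raw <- of_true / corr[[det]]
    if (truth$noise_cv > 0) {
      raw <- mult_noise(raw, truth$noise_cv,
                        sub_seed(truth$seed, match(det, names(corr)), 31))
    }
    data.frame(field_size_mm = of_field_sizes, detector = det,
               raw_ratio = raw, correction_factor = corr[[det]])
  }))
  of_file <- file.path(dir, "output_factors.csv")
  write_of_csv(of_tab, of_file)

  pattern <- modulation_pattern(seed = truth$seed)
  ref_plane <- simulate_dose_plane(truth$params, pattern)
  eval_plane <- simulate_dose_plane(plane_params, pattern)
  ref_file <- file.path(dir, "plane_measured.txt")
  eval_file <- file.path(dir, "plane_calculated.txt")
  write_dose_plane(ref_plane, ref_file)
  write_dose_plane(eval_plane, eval_file)

  cfg <- list(
    beam = "synthetic",
    seed = truth$seed,
    paths = list(
      profiles_dir = "profiles",
      aosg_plans = "aosg_plans.csv",
      aosg_readings = "aosg_readings.csv",
      sweeping = "sweeping.csv",
      output_factors = "output_factors.csv",
      dose_plane_reference = "plane_measured.txt",
      dose_plane_evaluated = "plane_calculated.txt"
    ),
    engine = list(tg_loss_calculated = truth$tg_loss_calculated,
                  sweep_length = 100, calibration = 1),
    sigma_grid = list(from = 0, to = 2, by = 0.2),
    dlg_grid = list(from = 0, to = 3.4, by = 0.1),
    doe = list(alpha = 0.01,
               levels = lapply(unclass(doe_levels), as.numeric)),
    gamma = list(dose_pct = 3, dta_mm = 2, threshold_pct = 10)
  )
  config_file <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, config_file)

  invisible(list(config = config_file, profiles = prof_files,
                 aosg_plans = plans_file, aosg_readings = readings_file,
                 sweeping = sweeping_file, output_factors = of_file,
                 dose_plane_reference = ref_file,
                 dose_plane_evaluated = eval_file))
}

resolve_path <- function(base, p) {
  if (is.null(p)) return(NULL)
  if (file.exists(p)) p else file.path(base, p)
}

#' Run the full commissioning pipeline
#'
#' Executes the stages in the recommended order — spot-size tuning on
#' penumbras (both axes), transmission measurement, DLG tuning (aOSG plus
#' the classic sweeping-gap estimate), the L27 sensitivity analysis of
#' small-field output factors, and the gamma-index plan QA. The calculated
#' side of every stage is provided by the synthetic dose engine configured
#' by the `engine` section of the config; measured inputs are read from the
#' files the config names. A stage whose inputs are missing is skipped with
#' a warning and reported as `NULL`.
#'
#' @param config A [read_run_config()] object or the path to a YAML config.
#' @return An object of class `commission_report`.
#' @export
run_commission <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  base <- dirname(config$config_path)
  warn_skip <- function(stage) {
    warning("inputs for stage '", stage, "' missing; stage skipped",
            call. = FALSE)
    NULL
  }
  eng <- config$engine

  # --- stage 1: spot sizes on penumbras -----------------------------------
  spot <- list(crossline = NULL, inline = NULL)
  prof_dir <- resolve_path(base, config$paths$profiles_dir)
  if (!is.null(prof_dir) && dir.exists(prof_dir)) {
    profs <- lapply(list.files(prof_dir, pattern = "\\.csv$", full.names = TRUE),
                    read_profile_csv)
    for (axis in c("crossline", "inline")) {
      meas <- Filter(function(p) p$axis == axis, profs)
      if (length(meas) == 0) next
      provider <- function(sig) {
        lapply(meas, function(mp) {
          pars <- if (axis == "crossline") {
            beam_params(sigma_x = sig)
          } else {
            beam_params(sigma_y = sig)
          }
          simulate_profile(
            field_geometry(mp$field_size, axis = axis),
            synthetic_truth(pars, detector_sigma = 0, noise_cv = 0),
            role = "calculated", positions = mp$positions)
        })
      }
      spot[[axis]] <- tune_spot_size(meas, provider, grid = config$sigma_grid)
    }
  } else {
    spot$crossline <- warn_skip("penumbra")
  }
  sx <- if (!is.null(spot$crossline)) spot$crossline$optimum else NA_real_
  sy <- if (!is.null(spot$inline)) spot$inline$optimum else NA_real_

  # --- stage 2: transmission ----------------------------------------------
  sweeping_path <- resolve_path(base, config$paths$sweeping)
  series <- NULL
  transmission <- NA_real_
  if (!is.null(sweeping_path) && file.exists(sweeping_path)) {
    series <- read_sweeping_csv(sweeping_path)
    transmission <- estimate_transmission(series$open_reading,
                                          series$closed_reading)
  } else {
    warn_skip("transmission")
  }

  # --- stage 3: DLG (aOSG + sweeping gap) ---------------------------------
  dlg_curve <- NULL
  plans_path <- resolve_path(base, config$paths$aosg_plans)
  readings_path <- resolve_path(base, config$paths$aosg_readings)
  if (!is.null(plans_path) && file.exists(plans_path) &&
      !is.null(readings_path) && file.exists(readings_path) &&
      is.finite(transmission)) {
    plans <- read_aosg_plans_csv(plans_path)
    readings <- read_readings_csv(readings_path)
    meas <- readings$measured_dose[match(plans$label, readings$label)]
    provider <- function(plan, d) {
      sweeping_gap_reading(
        plan$gap_mm,
        synthetic_truth(
          beam_params(sigma_x = ifelse(is.finite(sx), sx, 0),
                      sigma_y = ifelse(is.finite(sy), sy, 0),
                      dlg = d, transmission = transmission),
          tg_loss_measured = 0,
          tg_loss_calculated = eng$tg_loss_calculated,
          detector_sigma = 0, noise_cv = 0),
        role = "calculated", tg_fraction = plan$tg_fraction,
        sweep_length = eng$sweep_length, calibration = eng$calibration)
    }
    dlg_curve <- tune_dlg(aosg_reading_set(plans, meas, provider),
                          dlg_grid = config$dlg_grid)
  } else {
    warn_skip("dlg")
  }
  dlg_sweeping <- if (!is.null(series) && is.finite(transmission)) {
    estimate_dlg_sweeping(series, transmission)
  } else NA_real_

  # --- stage 4: DOE sensitivity -------------------------------------------
  doe <- NULL
  of_path <- resolve_path(base, config$paths$output_factors)
  if (!is.null(of_path) && file.exists(of_path) &&
      !is.null(config$doe$levels)) {
    of_tab <- read_of_csv(of_path)
    lv <- config$doe$levels
    levels <- factor_levels(sigma_x = lv$sigma_x, sigma_y = lv$sigma_y,
                            dlg = lv$dlg, transmission = lv$transmission)
    design <- build_l27()
    settings <- design_to_settings(design, levels)
    responses <- compute_responses(
      settings, of_tab,
      calc_provider = function(p, fs) output_factor(fs, p, "calculated"),
      field_sizes = sort(unique(of_tab$field_size_mm)))
    doe <- effects_and_anova(design, responses, alpha = config$doe$alpha)
    doe$design <- design
    doe$responses <- responses
  } else {
    warn_skip("doe")
  }

  # --- stage 5: gamma QA ---------------------------------------------------
  gam <- NULL
  ref_path <- resolve_path(base, config$paths$dose_plane_reference)
  eval_path <- resolve_path(base, config$paths$dose_plane_evaluated)
  if (!is.null(ref_path) && file.exists(ref_path) &&
      !is.null(eval_path) && file.exists(eval_path)) {
    gam <- gamma_map(read_dose_plane(ref_path), read_dose_plane(eval_path),
                     dose_pct = config$gamma$dose_pct,
                     dta_mm = config$gamma$dta_mm,
                     threshold_pct = config$gamma$threshold_pct)
  } else {
    warn_skip("gamma")
  }

  structure(
    list(
      beam = config$beam %||% "unnamed",
      params = list(sigma_x = sx, sigma_y = sy,
                    dlg_aosg = if (!is.null(dlg_curve)) dlg_curve$optimum else NA_real_,
                    dlg_sweeping = dlg_sweeping,
                    transmission = transmission),
      spot = spot,
      dlg_curve = dlg_curve,
      doe = doe,
      gamma = gam,
      provenance = list(config_md5 = config$config_md5,
                        seed = config$seed,
                        package_version = as.character(utils::packageVersion("beamtune")))
    ),
    class = "commission_report"
  )
}

#' @export
print.commission_report <- function(x, ...) {
  cat(sprintf("<commission_report> beam '%s'\n", x$beam))
  p <- x$params
  cat(sprintf("  sigma_x %.2f mm | sigma_y %.2f mm | DLG %.2f mm (aOSG) / %.2f mm (sweeping) | T %.2f %%\n",
              p$sigma_x, p$sigma_y, p$dlg_aosg, p$dlg_sweeping,
              100 * p$transmission))
  if (!is.null(x$gamma)) {
    cat(sprintf("  gamma pass rate %.1f%% -> %s\n", x$gamma$pass_rate,
                qa_verdict(x$gamma$pass_rate)))
  }
  invisible(x)
}

#' Serialize a commission report to machine-readable JSON
#'
#' The JSON contains the tuned parameter table, the full tuning curves (so
#' the deviation-vs-spot-size and cost-vs-DLG figures can be replotted from
#' the report alone), the per-field-size DOE verdicts and amplitudes, the
#' gamma result, and provenance (config hash, seed, package version). Output
#' is deterministic: the same config and seed produce byte-identical files.
#'
#' @param report A [run_commission()] report.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_commission_report <- function(report, path) {
  stopifnot(inherits(report, "commission_report"))
  spot_out <- lapply(report$spot, function(s) {
    if (is.null(s)) return(NULL)
    list(optimum_mm = s$optimum, method = s$method, ambiguous = s$ambiguous,
         grid_mm = s$grid, mean_deviation_mm = s$mean_deviation)
  })
  dlg_out <- if (!is.null(report$dlg_curve)) {
    dc <- report$dlg_curve
    list(optimum_mm = dc$optimum, mean_abs_diff_at_optimum = dc$value_at_optimum,
         grid_mm = dc$dlg_grid, mean_abs_diff = dc$mean_abs_diff,
         per_plan_sd = dc$per_plan_sd)
  } else NULL
  doe_out <- if (!is.null(report$doe)) {
    an <- report$doe$anova
    sig <- an[!is.na(an$significant) & an$significant, ]
    list(alpha = report$doe$alpha,
         zero_error = report$doe$zero_error,
         significant = lapply(split(sig$source, sig$field_size_mm), as.list),
         amplitudes_pct = report$doe$effects)
  } else NULL
  gamma_out <- if (!is.null(report$gamma)) {
    list(pass_rate_pct = report$gamma$pass_rate,
         verdict = qa_verdict(report$gamma$pass_rate),
         criteria = report$gamma$criteria)
  } else NULL
  out <- list(beam = report$beam, params = report$params, spot = spot_out,
              dlg = dlg_out, doe = doe_out, gamma = gamma_out,
              provenance = report$provenance)
  json <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null", dataframe = "columns")
  writeLines(json, path)
  invisible(path)
}
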