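#' Beam model parameters
#'
#' Bundle of the four tunable parameters of the photon beam model: the
#' effective target spot sizes in the crossline (X, along leaf travel) and
#' inline (Y) directions, the dosimetric leaf gap (DLG) and the MLC
#' transmission.
#'
#' The spot sizes are the widths (in mm, at the isocenter plane) of the
#' Gaussian smoothing applied to the primary-photon fluence; they broaden the
#' calculated penumbra in their respective direction. The DLG is the
#' effective widening of every MLC-defined gap that accounts for transmission
#' through the rounded leaf ends. The transmission is the fraction of the
#' open-field dose measured under fully closed leaves.
#'
#' @param sigma_x Crossline effective spot size, mm, in `[0, 5]`.
#' @param sigma_y Inline effective spot size, mm, in `[0, 5]`.
#' @param dlg Dosimetric leaf gap, mm, in `[-1, 5]`.
#' @param transmission MLC transmission as a fraction, in `[0, 0.1]`.
#' @return An object of class `beam_params`.
#' @examples
#' beam_params(sigma_x = 1.25, sigma_y = 0, dlg = 0.55, transmission = 0.0149)
#' @export
beam_params <- function(sigma_x = 0, sigma_y = 0, dlg = 0, transmission = 0) {
  stopifnot(
    is.numeric(sigma_x), length(sigma_x) == 1L, is.finite(sigma_x),
    is.numeric(sigma_y), length(sigma_y) == 1L, is.finite(sigma_y),
    is.numeric(dlg), length(dlg) == 1L, is.finite(dlg),
    is.numeric(transmission), length(transmission) == 1L, is.finite(transmission)
  )
  if (sigma_x < 0 || sigma_x > 5) stop("sigma_x must lie in [0, 5] mm")
  if (sigma_y < 0 || sigma_y > 5) stop("sigma_y must lie in [0, 5] mm")
  if (dlg < -1 || dlg > 5) stop("dlg must lie in [-1, 5] mm")
  if (transmission < 0 || transmission > 0.1) {
    stop("transmission must be a fraction in [0, 0.1]")
  }
  structure(
    list(sigma_x = sigma_x, sigma_y = sigma_y, dlg = dlg,
         transmission = transmission),
    class = "beam_params"
  )
}

#' @export
print.beam_params <- function(x, ...) {
  cat("<beam_params>\n")
  cat(sprintf("  sigma_x:      %.3f mm\n", x$sigma_x))
  cat(sprintf("  sigma_y:      %.3f mm\n", x$sigma_y))
  cat(sprintf("  DLG:          %.3f mm\n", x$dlg))
  cat(sprintf("  transmission: %.2f %%\n", 100 * x$transmission))
  invisible(x)
}

#' Ground truth for the synthetic dose engine
#'
#' Describes the synthetic "linac + planning system" pair used by the dose
#' engine: the physical beam parameters, the tongue-and-groove fluence-loss
#' coefficients of the measured (linac) and calculated (TPS stand-in) sides,
#' the detector blurring added in quadrature to measured profiles, and the
#' multiplicative noise applied to measured readings.
#'
#' Making `tg_loss_calculated` differ from `tg_loss_measured` emulates a
#' planning system whose tongue-and-groove modelling does not match the
#' machine, which is precisely the mismatch the asynchronous oscillating
#' sweeping gap (aOSG) tests are designed to expose: when the calculated
#' coefficient exceeds the measured one, the aOSG-optimal DLG exceeds the
#' sweeping-gap DLG.
#'
#' @param params A [beam_params()] object: the physical ground truth.
#' @param tg_loss_measured Tongue-and-groove loss coefficient of the linac
#'   stand-in, dimensionless in `[0, 1]`.
#' @param tg_loss_calculated Tongue-and-groove loss coefficient of the TPS
#'   stand-in, dimensionless in `[0, 1]`.
#' @param detector_sigma Detector blurring (mm) added in quadrature to the
#'   spot size for measured profiles only.
#' @param noise_cv Coefficient of variation of multiplicative Gaussian noise
#'   applied to measured readings; in `[0, 0.02]`, 0 disables noise.
#' @param seed Integer seed used whenever noise is drawn.
#' @return An object of class `synthetic_truth`.
#' @examples
#' synthetic_truth(beam_params(0.7, 0.35, 0.55, 0.0126))
#' @export
synthetic_truth <- function(params,
                            tg_loss_measured = 0.05,
                            tg_loss_calculated = 0.20,
                            detector_sigma = 0.3,
                            noise_cv = 0,
                            seed = 1L) {
  if (!inherits(params, "beam_params")) {
    stop("params must be a beam_params object")
  }
  stopifnot(
    is.numeric(tg_loss_measured), length(tg_loss_measured) == 1L,
    is.numeric(tg_loss_calculated), length(tg_loss_calculated) == 1L,
    is.numeric(detector_sigma), length(detector_sigma) == 1L,
    is.numeric(noise_cv), length(noise_cv) == 1L,
    is.numeric(seed), length(seed) == 1L
  )
  if (tg_loss_measured < 0 || tg_loss_measured > 1) {
    stop("tg_loss_measured must lie in [0, 1]")
  }
  if (tg_loss_calculated < 0 || tg_loss_calculated > 1) {
    stop("tg_loss_calculated must lie in [0, 1]")
  }
  if (detector_sigma < 0) stop("detector_sigma must be >= 0")
  if (noise_cv < 0 || noise_cv > 0.02) stop("noise_cv must lie in [0, 0.02]")
  structure(
    list(params = params,
         tg_loss_measured = tg_loss_measured,
         tg_loss_calculated = tg_loss_calculated,
         detector_sigma = detector_sigma,
         noise_cv = noise_cv,
         seed = as.integer(seed)),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth>\n")
  print(x$params)
  cat(sprintf("  TG loss (measured / calculated): %.3f / %.3f\n",
              x$tg_loss_measured, x$tg_loss_calculated))
  cat(sprintf("  detector_sigma: %.2f mm, noise_cv: %.4f, seed: %d\n",
              x$detector_sigma, x$noise_cv, x$seed))
  invisible(x)
}

#' Field geometry for a synthetic delivery
#'
#' @param field_size Side (mm) of the square MLC-defined field at isocenter.
#' @param sweep_length Total leaf travel (mm) of a sweeping delivery.
#' @param axis Scan axis: `"crossline"` (along leaf travel) or `"inline"`.
#' @return An object of class `field_geometry`.
#' @export
field_geometry <- function(field_size, sweep_length = 100,
                           axis = c("crossline", "inline")) {
  axis <- match.arg(axis)
  stopifnot(is.numeric(field_size), length(field_size) == 1L,
            is.numeric(sweep_length), length(sweep_length) == 1L)
  if (field_size <= 0) stop("field_size must be > 0")
  if (sweep_length <= 0) stop("sweep_length must be > 0")
  structure(
    list(field_size = field_size, sweep_length = sweep_length, axis = axis),
    class = "field_geometry"
  )
}
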