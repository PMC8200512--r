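#' @importFrom pracma erf erfinv
NULL

# Evaluate the Gaussian-smeared edge response erf(w / (sqrt(2) sigma)),
# degenerating to a unit step (sign) when sigma = 0.
edge_erf <- function(w, sigma) {
  if (sigma <= 0) return(sign(w))
  pracma::erf(w / (sqrt(2) * sigma))
}

# Run expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a reproducible sub-seed from a base seed and small integers.
sub_seed <- function(seed, ...) {
  extra <- c(...)
  s <- as.double(seed)
  for (e in extra) s <- (s * 7919 + as.double(e) * 104729 + 1) %% 2147483629
  as.integer(s)
}

mult_noise <- function(values, cv, seed) {
  if (cv <= 0) return(values)
  with_seed(seed, values * (1 + stats::rnorm(length(values), sd = cv)))
}

#' Simulate a scanned dose profile
#'
#' Closed-form profile of a square MLC-defined field: each field edge is an
#' error-function edge broadened by the effective spot size of the scanned
#' axis, the MLC-defined edges along leaf travel (crossline) are widened by
#' half the dosimetric leaf gap on each side, and the transmission lifts the
#' out-of-field floor. Profiles are normalized to 100% at the beam central
#' axis. For `role = "measured"` the detector blurring is added in quadrature
#' to the spot size and multiplicative noise (if enabled) is applied.
#'
#' @param geom A [field_geometry()]; its `axis` selects which spot size is
#'   used (crossline uses `sigma_x`, inline `sigma_y`).
#' @param truth A [synthetic_truth()].
#' @param role `"measured"` (linac stand-in) or `"calculated"` (TPS
#'   stand-in).
#' @param positions Sorted scan positions in mm; must span both field edges
#'   far enough that the profile covers the 20% and 80% levels on each side.
#' @return A [profile()] object with readings normalized to 100 on axis.
#' @export
simulate_profile <- function(geom, truth, role = c("measured", "calculated"),
                             positions = NULL) {
  role <- match.arg(role)
  stopifnot(inherits(geom, "field_geometry"), inherits(truth, "synthetic_truth"))
  if (is.null(positions)) {
    half <- geom$field_size / 2
    positions <- seq(-(half + 15), half + 15, by = 0.1)
  }
  if (is.unsorted(positions, strictly = TRUE)) {
    stop("positions must be strictly increasing")
  }
  p <- truth$params
  a <- geom$field_size / 2
  if (geom$axis == "crossline") {
    sigma <- p$sigma_x
    delta <- p$dlg / 2
  } else {
    sigma <- p$sigma_y
    delta <- 0
  }
  sigma_eff <- if (role == "measured") {
    sqrt(sigma^2 + truth$detector_sigma^2)
  } else {
    sigma
  }
  tr <- p$transmission
  field_term <- function(x) {
    if (sigma_eff <= 0) {
      0.5 * (sign(a + delta - x) + sign(a + delta + x))
    } else {
      0.5 * (edge_erf(a + delta - x, sigma_eff) +
             edge_erf(a + delta + x, sigma_eff))
    }
  }
  raw <- (1 - tr) * field_term(positions) + tr
  if (role == "measured" && truth$noise_cv > 0) {
    seed <- sub_seed(truth$seed, round(geom$field_size * 10),
                     as.integer(geom$axis == "inline"))
    raw <- mult_noise(raw, truth$noise_cv, seed)
  }
  central <- stats::approx(positions, raw, xout = 0, rule = 1)$y
  if (is.na(central) || central <= 0) {
    stop("central axis (x = 0) not covered by positions, or zero dose there")
  }
  readings <- 100 * raw / central
  half_cov <- function(side) {
    idx <- if (side == "left") positions < 0 else positions > 0
    r <- readings[idx]
    length(r) > 0 && min(r) < 20 && max(r) > 80
  }
  if (!half_cov("left") || !half_cov("right")) {
    stop("positions do not cover the 20-80% dose levels on both sides; ",
         "extend the scan range")
  }
  profile(axis = geom$axis, field_size = geom$field_size,
          positions = positions, readings = readings,
          depth = 100, ssd = 900,
          label = sprintf("%s_%gmm_%s", role, geom$field_size, geom$axis))
}

#' Point dose of a (possibly asynchronous) sweeping gap delivery
#'
#' Dose at the center of a phantom for a delivery in which a uniform MLC gap
#' `g` sweeps across a field of length `L` at constant speed, with adjacent
#' leaf pairs shifted by `s = tg_fraction * g` to expose the tongue-and-groove
#' effect. The dose law is affine in the gap:
#' `D = C (g + DLG - lambda s) / L + T (1 - g / L)`,
#' where `lambda` is the tongue-and-groove loss coefficient of the requested
#' role and `C` a calibration constant (`C = 1` makes the open 10-cm reading
#' 1.000).
#'
#' @param gap Gap width(s), mm, in `(0, sweep_length)`.
#' @param truth A [synthetic_truth()]; for `role = "calculated"` the model
#'   DLG carried in `truth$params` is the one applied, so a DLG sweep is
#'   performed by re-evaluating with modified params.
#' @param role `"measured"` or `"calculated"`.
#' @param tg_fraction Tongue-and-groove fraction(s) `s / g` in `[0, 1]`.
#' @param sweep_length Total leaf travel `L`, mm.
#' @param calibration Calibration constant `C`.
#' @return Dose reading(s), arbitrary units.
#' @export
sweeping_gap_reading <- function(gap, truth,
                                 role = c("measured", "calculated"),
                                 tg_fraction = 0, sweep_length = 100,
                                 calibration = 1) {
  role <- match.arg(role)
  stopifnot(inherits(truth, "synthetic_truth"), is.numeric(gap),
            is.numeric(tg_fraction))
  if (any(gap <= 0) || any(gap >= sweep_length)) {
    stop("gap must lie strictly between 0 and sweep_length")
  }
  if (any(tg_fraction < 0) || any(tg_fraction > 1)) {
    stop("tg_fraction must lie in [0, 1]")
  }
  n <- max(length(gap), length(tg_fraction))
  gap <- rep_len(gap, n)
  tg_fraction <- rep_len(tg_fraction, n)
  p <- truth$params
  lambda <- if (role == "measured") truth$tg_loss_measured else truth$tg_loss_calculated
  s <- tg_fraction * gap
  d <- calibration * (gap + p$dlg - lambda * s) / sweep_length +
    p$transmission * (1 - gap / sweep_length)
  if (role == "measured" && truth$noise_cv > 0) {
    seed <- sub_seed(truth$seed, round(gap[1] * 10), round(tg_fraction[1] * 100), 11)
    d <- mult_noise(d, truth$noise_cv, seed)
  }
  d
}

#' Static open / closed-MLC reading of the synthetic linac
#'
#' The open-field reading equals the calibration constant; the closed-MLC
#' reading is the transmission times the open reading. Used for the
#' transmission measurement and to transmission-correct sweeping-gap series.
#'
#' @inheritParams sweeping_gap_reading
#' @param type `"open"` or `"closed"`.
#' @return Dose reading, arbitrary units.
#' @export
static_reading <- function(truth, type = c("open", "closed"),
                           role = c("measured", "calculated"),
                           calibration = 1) {
  type <- match.arg(type)
  role <- match.arg(role)
  stopifnot(inherits(truth, "synthetic_truth"))
  d <- if (type == "open") calibration else calibration * truth$params$transmission
  if (role == "measured" && truth$noise_cv > 0) {
    d <- mult_noise(d, truth$noise_cv,
                    sub_seed(truth$seed, as.integer(type == "closed"), 23))
  }
  d
}

#' Small-field output factor of the synthetic beam model
#'
#' Product-of-edges response surface: with half-side `a = field_size / 2`,
#' `OF = (1 - T) erf((a + DLG/2) / (sqrt(2) sigma_x)) erf(a / (sqrt(2) sigma_y)) + T`
#' (each erf factor is 1 when its sigma is 0). The output factor is strictly
#' increasing in DLG and transmission and strictly decreasing in the spot
#' sizes for small fields, and tends to 1 for large fields.
#'
#' @param field_size Field side(s), mm.
#' @param params A [beam_params()]: for `role = "calculated"` these are the
#'   model parameters under test; for `role = "measured"` supply the physical
#'   truth parameters.
#' @param role `"measured"` or `"calculated"`; the law is identical, the role
#'   only documents which side of the comparison is being emulated.
#' @return Output factor(s), dimensionless.
#' @export
output_factor <- function(field_size, params,
                          role = c("calculated", "measured")) {
  role <- match.arg(role)
  stopifnot(inherits(params, "beam_params"), is.numeric(field_size))
  if (any(field_size <= 0)) stop("field_size must be > 0")
  a <- field_size / 2
  ex <- vapply(a + params$dlg / 2, edge_erf, numeric(1), sigma = params$sigma_x)
  ey <- vapply(a, edge_erf, numeric(1), sigma = params$sigma_y)
  tr <- params$transmission
  (1 - tr) * ex * ey + tr
}

#' Deterministic modulation pattern for synthetic dose planes
#'
#' Draws a set of rectangular apertures (position, size, weight) from a
#' seeded RNG, emulating the segment pattern of a modulated delivery.
#'
#' @param seed Integer seed.
#' @param n_apertures Number of apertures.
#' @param extent Half-size (mm) of the region the apertures occupy.
#' @return Data frame with columns `xlo, xhi, ylo, yhi, weight`.
#' @export
modulation_pattern <- function(seed = 1L, n_apertures = 4, extent = 40) {
  with_seed(seed, {
    cx <- stats::runif(n_apertures, -extent / 2, extent / 2)
    cy <- stats::runif(n_apertures, -extent / 2, extent / 2)
    wx <- stats::runif(n_apertures, extent / 4, extent)
    wy <- stats::runif(n_apertures, extent / 4, extent)
    w <- stats::runif(n_apertures, 0.4, 1)
    data.frame(xlo = cx - wx / 2, xhi = cx + wx / 2,
               ylo = cy - wy / 2, yhi = cy + wy / 2, weight = w)
  })
}

#' Simulate a 2D dose plane
#'
#' Sum of erf-edged rectangular apertures evaluated on a regular grid. Edges
#' along the leaf-travel (x) axis are widened by half the DLG and blurred by
#' `sigma_x`; edges along y are blurred by `sigma_y`. Each aperture leaks a
#' transmission floor proportional to its weight. The plane is smooth and
#' deterministic given the pattern, so a perturbed variant is obtained simply
#' by re-evaluating with different parameters.
#'
#' @param params A [beam_params()].
#' @param pattern Aperture table as returned by [modulation_pattern()].
#' @param spacing Grid spacing, mm (isotropic).
#' @param extent Half-size of the grid, mm; the grid spans `[-extent, extent]`
#'   in both axes.
#' @return A [dose_grid()] object.
#' @export
simulate_dose_plane <- function(params, pattern = modulation_pattern(),
                                spacing = 2, extent = 40) {
  stopifnot(inherits(params, "beam_params"), is.data.frame(pattern),
            all(c("xlo", "xhi", "ylo", "yhi", "weight") %in% names(pattern)))
  xs <- seq(-extent, extent, by = spacing)
  ys <- seq(-extent, extent, by = spacing)
  sx <- max(params$sigma_x, 1e-6)  # keep the plane smooth for gamma DTA
  sy <- max(params$sigma_y, 1e-6)
  tr <- params$transmission
  half_dlg <- params$dlg / 2
  dose <- matrix(0, nrow = length(xs), ncol = length(ys))
  for (k in seq_len(nrow(pattern))) {
    ap <- pattern[k, ]
    ex <- 0.5 * (pracma::erf((ap$xhi + half_dlg - xs) / (sqrt(2) * sx)) -
                 pracma::erf((ap$xlo - half_dlg - xs) / (sqrt(2) * sx)))
    ey <- 0.5 * (pracma::erf((ap$yhi - ys) / (sqrt(2) * sy)) -
                 pracma::erf((ap$ylo - ys) / (sqrt(2) * sy)))
    dose <- dose + ap$weight * ((1 - tr) * outer(ex, ey) + tr)
  }
  dose_grid(dose, spacing = c(spacing, spacing),
            origin = c(xs[1], ys[1]), units = "normalized")
}
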