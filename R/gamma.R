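#' A 2D dose plane on a regular grid
#'
#' @param dose Numeric matrix of doses (>= 0); rows index x, columns y.
#' @param spacing Grid spacing `c(dx, dy)`, mm (a scalar is recycled).
#' @param origin Position `c(x0, y0)` of `dose[1, 1]`, mm.
#' @param units `"Gy"` or `"normalized"`.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(dose, spacing, origin = c(0, 0),
                      units = c("normalized", "Gy")) {
  units <- match.arg(units)
  stopifnot(is.matrix(dose), is.numeric(dose))
  spacing <- rep_len(as.numeric(spacing), 2L)
  origin <- rep_len(as.numeric(origin), 2L)
  if (any(spacing <= 0)) stop("spacing must be > 0")
  if (any(dose < 0)) stop("doses must be >= 0")
  structure(
    list(dose = dose, spacing = spacing, origin = origin, units = units),
    class = "dose_grid"
  )
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %d x %d, spacing %g x %g mm, origin (%g, %g), max %.4g %s\n",
              nrow(x$dose), ncol(x$dose), x$spacing[1], x$spacing[2],
              x$origin[1], x$origin[2], max(x$dose), x$units))
  invisible(x)
}

grid_axis <- function(g, which) {
  g$origin[which] + (seq_len(dim(g$dose)[which]) - 1L) * g$spacing[which]
}

# Bilinear interpolation of a dose_grid at the outer product of xq and yq.
# Points outside the grid return NA.
bilinear_sample <- function(g, xq, yq) {
  xs <- grid_axis(g, 1L); ys <- grid_axis(g, 2L)
  fx <- (xq - xs[1]) / g$spacing[1]
  fy <- (yq - ys[1]) / g$spacing[2]
  ix <- floor(fx); iy <- floor(fy)
  okx <- fx >= 0 & fx <= length(xs) - 1
  oky <- fy >= 0 & fy <= length(ys) - 1
  ix <- pmin(pmax(ix, 0), length(xs) - 2)
  iy <- pmin(pmax(iy, 0), length(ys) - 2)
  wx <- fx - ix; wy <- fy - iy
  d <- g$dose
  i1 <- ix + 1L; j1 <- iy + 1L
  v <- outer((1 - wx), (1 - wy)) * d[cbind(rep(i1, length(j1)), rep(j1, each = length(i1)))] +
       outer(wx, (1 - wy)) * d[cbind(rep(i1 + 1L, length(j1)), rep(j1, each = length(i1)))] +
       outer((1 - wx), wy) * d[cbind(rep(i1, length(j1)), rep(j1 + 1L, each = length(i1)))] +
       outer(wx, wy) * d[cbind(rep(i1 + 1L, length(j1)), rep(j1 + 1L, each = length(i1)))]
  v <- matrix(v, nrow = length(xq))
  v[!okx, ] <- NA_real_
  v[, !oky] <- NA_real_
  v
}

#' Global gamma-index comparison of two dose planes
#'
#' Computes the 2D gamma index of an evaluated (calculated) plane against a
#' reference (measured) plane with a global dose criterion: the dose
#' difference is scaled by `dose_pct` percent of the reference-plane maximum
#' everywhere. Reference points below `threshold_pct` percent of that
#' maximum are masked and excluded from the pass rate. The evaluated plane
#' is sampled by bilinear interpolation on a search disk of radius
#' `3 * dta_mm` with step at most `dta_mm / 10`, and
#' `gamma = min sqrt(dr^2/dta^2 + dD^2/(dose_pct% of Dmax)^2)` over the disk.
#'
#' @param reference Reference [dose_grid()] (the measurement).
#' @param evaluated Evaluated [dose_grid()] (the calculation).
#' @param dose_pct Dose-difference criterion, percent of the global maximum.
#' @param dta_mm Distance-to-agreement criterion, mm.
#' @param threshold_pct Low-dose threshold, percent of the global maximum.
#' @return An object of class `gamma_result`: `gamma` (matrix, `NA` where
#'   masked), `pass_rate` (percent of evaluated points with gamma <= 1),
#'   `criteria`, and `search` metadata (step and radius used).
#' @export
gamma_map <- function(reference, evaluated, dose_pct = 3, dta_mm = 2,
                      threshold_pct = 10) {
  stopifnot(inherits(reference, "dose_grid"), inherits(evaluated, "dose_grid"))
  if (dose_pct <= 0 || dta_mm <= 0) stop("criteria must be > 0")
  ref_max <- max(reference$dose)
  if (ref_max <= 0) stop("reference maximum must be > 0")
  xs_r <- grid_axis(reference, 1L); ys_r <- grid_axis(reference, 2L)
  xs_e <- grid_axis(evaluated, 1L); ys_e <- grid_axis(evaluated, 2L)
  if (max(xs_r) < min(xs_e) || min(xs_r) > max(xs_e) ||
      max(ys_r) < min(ys_e) || min(ys_r) > max(ys_e)) {
    stop("reference and evaluated grids do not overlap")
  }
  dd_abs <- dose_pct / 100 * ref_max
  mask <- reference$dose < threshold_pct / 100 * ref_max
  if (all(mask)) stop("all reference points fall below the dose threshold")

  step <- dta_mm / 10
  radius <- 3 * dta_mm
  offs <- seq(-radius, radius, by = step)
  gamma2 <- matrix(Inf, nrow = nrow(reference$dose), ncol = ncol(reference$dose))
  for (ox in offs) {
    for (oy in offs) {
      r2 <- ox^2 + oy^2
      if (r2 > radius^2) next
      ev <- bilinear_sample(evaluated, xs_r + ox, ys_r + oy)
      g2 <- r2 / dta_mm^2 + (ev - reference$dose)^2 / dd_abs^2
      upd <- !is.na(g2) & g2 < gamma2
      gamma2[upd] <- g2[upd]
    }
  }
  gam <- sqrt(gamma2)
  gam[mask] <- NA_real_
  evaluated_pts <- gam[!mask]
  if (!all(is.finite(evaluated_pts))) {
    stop("some reference points have no evaluated dose within the search radius")
  }
  structure(
    list(gamma = gam,
         pass_rate = 100 * mean(evaluated_pts <= 1),
         criteria = list(dose_pct = dose_pct, dta_mm = dta_mm,
                         threshold_pct = threshold_pct,
                         normalization = "global"),
         search = list(step_mm = step, radius_mm = radius,
                       interpolation = "bilinear"),
         n_evaluated = length(evaluated_pts)),
    class = "gamma_result"
  )
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %g%%/%g mm global, %g%% threshold: pass rate %.1f%% (%s)\n",
              x$criteria$dose_pct, x$criteria$dta_mm, x$criteria$threshold_pct,
              x$pass_rate, qa_verdict(x$pass_rate)))
  invisible(x)
}

#' Plan QA verdict from a gamma pass rate
#'
#' Applies the universal tolerance (95%) and action (90%) limits: a pass
#' rate at or above the tolerance limit passes, one between the action and
#' tolerance limits warrants investigation, and one below the action limit
#' fails.
#'
#' @param pass_rate Gamma pass rate, percent.
#' @return `"pass"`, `"investigate"` or `"fail"`.
#' @export
qa_verdict <- function(pass_rate) {
  stopifnot(is.numeric(pass_rate), length(pass_rate) == 1L,
            pass_rate >= 0, pass_rate <= 100)
  if (pass_rate >= 95) "pass" else if (pass_rate >= 90) "investigate" else "fail"
}
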