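#' A 1D scanned dose profile
#'
#' @param axis Scan axis, `"crossline"` or `"inline"`.
#' @param field_size MLC-defined field side, mm.
#' @param positions Strictly increasing scan positions, mm, at the isocenter
#'   plane; must bracket the central axis (x = 0).
#' @param readings Dose readings (arbitrary units or percent), one per
#'   position.
#' @param depth Measurement depth, mm.
#' @param ssd Source-surface distance, mm.
#' @param label Free-text label.
#' @return An object of class `profile`.
#' @export
profile <- function(axis = c("crossline", "inline"), field_size, positions,
                    readings, depth = 100, ssd = 900, label = "") {
  axis <- match.arg(axis)
  stopifnot(is.numeric(positions), is.numeric(readings),
            is.numeric(field_size), length(field_size) == 1L)
  if (length(positions) != length(readings)) {
    stop("positions and readings must have equal length")
  }
  if (length(positions) < 2L || is.unsorted(positions, strictly = TRUE)) {
    stop("positions must be strictly increasing (length >= 2)")
  }
  if (min(positions) > 0 || max(positions) < 0) {
    stop("central axis position 0 must lie within the scan range")
  }
  if (field_size <= 0) stop("field_size must be > 0")
  structure(
    list(axis = axis, field_size = field_size,
         positions = as.numeric(positions), readings = as.numeric(readings),
         depth = depth, ssd = ssd, label = label),
    class = "profile"
  )
}

#' @export
print.profile <- function(x, ...) {
  cat(sprintf("<profile> %s, field %g mm, %d points [%g, %g] mm%s\n",
              x$axis, x$field_size, length(x$positions),
              min(x$positions), max(x$positions),
              if (nzchar(x$label)) paste0(", ", x$label) else ""))
  invisible(x)
}

#' Normalize a profile to 100% at the beam central axis
#'
#' The reading at x = 0 (linearly interpolated if 0 is not a sample point) is
#' set to 100; this central-axis convention is used even for FFF beams, where
#' the profile maximum may sit off-axis.
#'
#' @param p A [profile()].
#' @return The profile with rescaled readings.
#' @export
normalize_profile <- function(p) {
  stopifnot(inherits(p, "profile"))
  central <- stats::approx(p$positions, p$readings, xout = 0, rule = 1)$y
  if (is.na(central) || central <= 0) {
    stop("central-axis reading is missing, zero or negative; cannot normalize")
  }
  p$readings <- 100 * p$readings / central
  p
}

# Interpolated position at which readings on one side cross `level`.
# x, r are ordered from the central axis outwards.
crossing_position <- function(x, r, level, side) {
  d <- r - level
  hits <- which(d == 0)
  brackets <- which(d[-length(d)] * d[-1] < 0)
  n_cross <- length(hits) + length(brackets)
  if (n_cross == 0L) {
    stop(sprintf("no %g%% crossing found on the %s side", level, side))
  }
  if (n_cross > 1L) {
    stop(sprintf("multiple %g%% crossings on the %s side; edge region not monotone",
                 level, side))
  }
  if (length(hits) == 1L) return(x[hits])
  i <- brackets
  x[i] + (level - r[i]) * (x[i + 1] - x[i]) / (r[i + 1] - r[i])
}

#' Extract the 20-80% penumbras of a profile
#'
#' The penumbra of each field edge is the lateral distance between the 20%
#' and 80% dose levels, with 100% defined at the beam central axis. Crossing
#' positions are located by linear interpolation between the bracketing
#' samples; each side must cross each level exactly once.
#'
#' @param p A [profile()], normalized to 100 at x = 0 (it is re-normalized
#'   internally, so absolute reading scale does not matter).
#' @return A list of class `penumbra_pair` with elements `left` and `right`
#'   (mm).
#' @export
extract_penumbra <- function(p) {
  p <- normalize_profile(p)
  x <- p$positions
  r <- p$readings
  one_side <- function(side) {
    if (side == "right") {
      idx <- x >= 0
      xs <- x[idx]; rs <- r[idx]
    } else {
      idx <- x <= 0
      xs <- rev(-x[idx]); rs <- rev(r[idx])  # mirror so both run outwards
    }
    x80 <- crossing_position(xs, rs, 80, side)
    x20 <- crossing_position(xs, rs, 20, side)
    abs(x20 - x80)
  }
  out <- list(left = one_side("left"), right = one_side("right"))
  if (!all(is.finite(unlist(out))) || any(unlist(out) <= 0)) {
    stop("degenerate penumbra extracted")
  }
  class(out) <- "penumbra_pair"
  out
}

#' @export
print.penumbra_pair <- function(x, ...) {
  cat(sprintf("<penumbra_pair> left %.3f mm, right %.3f mm\n", x$left, x$right))
  invisible(x)
}

#' Mean signed penumbra deviation, calculated minus measured
#'
#' Averages `calculated - measured` over all matched (axis, field size)
#' profile pairs and both edges (left and right), with equal weight. The sign
#' is preserved: the deviation curve as a function of spot size crosses zero
#' at the optimum.
#'
#' @param calc,meas Lists of [profile()] objects; every calculated profile
#'   must have a measured counterpart with the same axis and field size.
#' @return Signed mean deviation, mm.
#' @export
mean_penumbra_deviation <- function(calc, meas) {
  stopifnot(is.list(calc), is.list(meas), length(calc) > 0)
  key <- function(p) sprintf("%s|%g", p$axis, p$field_size)
  meas_map <- stats::setNames(meas, vapply(meas, key, character(1)))
  devs <- unlist(lapply(calc, function(cp) {
    mp <- meas_map[[key(cp)]]
    if (is.null(mp)) {
      stop("no measured profile matching axis=", cp$axis,
           " field_size=", cp$field_size)
    }
    pc <- extract_penumbra(cp)
    pm <- extract_penumbra(mp)
    c(pc$left - pm$left, pc$right - pm$right)
  }))
  mean(devs)
}

#' Tune an effective target spot size on measured penumbras
#'
#' Evaluates the mean signed penumbra deviation (calculated minus measured)
#' on a grid of candidate spot sizes and returns the spot size at which the
#' deviation curve crosses zero (linearly interpolated). When the curve never
#' changes sign — as happens when even a point source over-broadens the
#' calculated penumbra — the grid value minimizing the absolute deviation is
#' returned and the method is recorded as `"argmin"`.
#'
#' @param meas List of measured [profile()] objects (one axis).
#' @param calc_provider Function of one argument (the candidate spot size,
#'   mm) returning the matching list of calculated profiles.
#' @param grid Candidate spot sizes, mm; default 0 to 2 mm in 0.2 mm steps.
#' @return An object of class `spot_tune_result` with fields `grid`,
#'   `mean_deviation`, `optimum`, `method` (`"zero_crossing"` or `"argmin"`),
#'   `ambiguous` and `crossings`.
#' @export
tune_spot_size <- function(meas, calc_provider, grid = seq(0, 2, by = 0.2)) {
  stopifnot(is.function(calc_provider), is.numeric(grid), length(grid) >= 2,
            !is.unsorted(grid, strictly = TRUE))
  dev <- vapply(grid, function(s) {
    mean_penumbra_deviation(calc_provider(s), meas)
  }, numeric(1))
  sgn <- sign(dev)
  idx <- which(sgn[-length(sgn)] * sgn[-1] < 0)
  exact <- which(dev == 0)
  crossings <- numeric(0)
  for (i in idx) {
    crossings <- c(crossings,
                   grid[i] - dev[i] * (grid[i + 1] - grid[i]) / (dev[i + 1] - dev[i]))
  }
  crossings <- sort(unique(c(crossings, grid[exact])))
  ambiguous <- length(crossings) > 1L
  if (ambiguous) {
    warning("deviation curve crosses zero more than once; result flagged ambiguous")
  }
  if (length(crossings) >= 1L) {
    optimum <- crossings[1]
    method <- "zero_crossing"
  } else {
    optimum <- grid[which.min(abs(dev))]
    method <- "argmin"
  }
  structure(
    list(grid = grid, mean_deviation = dev, optimum = optimum,
         method = method, ambiguous = ambiguous, crossings = crossings),
    class = "spot_tune_result"
  )
}

#' @export
print.spot_tune_result <- function(x, ...) {
  cat(sprintf("<spot_tune_result> optimum %.3f mm (%s%s)\n",
              x$optimum, x$method, if (x$ambiguous) ", AMBIGUOUS" else ""))
  cat(sprintf("  grid: %g to %g mm (%d points), deviation %+.3f to %+.3f mm\n",
              min(x$grid), max(x$grid), length(x$grid),
              min(x$mean_deviation), max(x$mean_deviation)))
  invisible(x)
}
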