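#' Build the asynchronous oscillating sweeping gap (aOSG) plan set
#'
#' Full cross product of gap widths and tongue-and-groove fractions; each
#' plan's leaf-pair shift is `shift = tg_fraction * gap`. The defaults (gaps
#' 10, 20, 30 mm; TG fractions 0, 0.25, 0.5, 0.75, 1) span a wide range of
#' plan complexity and yield fifteen plans.
#'
#' @param gaps Gap widths, mm.
#' @param tg_fractions Tongue-and-groove fractions in `[0, 1]`.
#' @return Data frame of class `aosg_plans` with columns `label`, `gap_mm`,
#'   `tg_fraction`, `shift_mm`.
#' @export
build_aosg_plans <- function(gaps = c(10, 20, 30),
                             tg_fractions = c(0, 0.25, 0.5, 0.75, 1)) {
  stopifnot(is.numeric(gaps), is.numeric(tg_fractions))
  if (length(gaps) == 0 || length(tg_fractions) == 0) {
    stop("gaps and tg_fractions must be non-empty")
  }
  if (any(gaps <= 0)) stop("gaps must be > 0")
  if (any(tg_fractions < 0) || any(tg_fractions > 1)) {
    stop("tg_fractions must lie in [0, 1]")
  }
  grid <- expand.grid(tg_fraction = tg_fractions, gap_mm = gaps,
                      KEEP.OUT.ATTRS = FALSE)[, c("gap_mm", "tg_fraction")]
  plans <- data.frame(
    label = sprintf("g%g_tg%g", grid$gap_mm, grid$tg_fraction),
    gap_mm = grid$gap_mm,
    tg_fraction = grid$tg_fraction,
    shift_mm = grid$gap_mm * grid$tg_fraction,
    stringsAsFactors = FALSE
  )
  class(plans) <- c("aosg_plans", "data.frame")
  plans
}

#' Pair aOSG plans with measured doses and a calculated-dose provider
#'
#' @param plans Plan table from [build_aosg_plans()].
#' @param measured Measured point dose per plan (same order), all > 0.
#' @param calculated_provider Function `(plan_row, dlg) -> dose` returning
#'   the planning-system dose of one plan for a candidate DLG value.
#' @return An object of class `aosg_reading_set`.
#' @export
aosg_reading_set <- function(plans, measured, calculated_provider) {
  stopifnot(inherits(plans, "aosg_plans"), is.numeric(measured),
            is.function(calculated_provider))
  if (length(measured) != nrow(plans)) {
    stop("need exactly one measured dose per plan")
  }
  if (any(measured <= 0)) stop("measured doses must be > 0")
  structure(
    list(plans = plans, measured = as.numeric(measured),
         calculated_provider = calculated_provider),
    class = "aosg_reading_set"
  )
}

#' Tune the dosimetric leaf gap on the aOSG plan set
#'
#' For each candidate DLG on the grid, computes the per-plan relative dose
#' difference `(calculated - measured) / measured` and minimizes the mean
#' absolute difference over the plans. The per-plan standard deviation of the
#' signed differences is also tracked: at a well-chosen DLG the model agrees
#' with measurement across plan complexities, so the spread shrinks together
#' with the mean.
#'
#' @param readings An [aosg_reading_set()].
#' @param dlg_grid Candidate DLG values, mm; default 0 to 3.4 mm, 0.1 mm step.
#' @param refine If `TRUE`, refine the grid argmin by a 3-point parabolic
#'   fit (the cost curve is approximately parabolic near its minimum).
#' @return An object of class `dlg_curve` with fields `dlg_grid`,
#'   `mean_abs_diff`, `per_plan_sd`, `optimum`, `value_at_optimum`, `tie`.
#' @export
tune_dlg <- function(readings, dlg_grid = seq(0, 3.4, by = 0.1),
                     refine = FALSE) {
  stopifnot(inherits(readings, "aosg_reading_set"), is.numeric(dlg_grid),
            length(dlg_grid) >= 2, !is.unsorted(dlg_grid, strictly = TRUE))
  plans <- readings$plans
  diffs_at <- function(d) {
    calc <- vapply(seq_len(nrow(plans)), function(i) {
      readings$calculated_provider(plans[i, ], d)
    }, numeric(1))
    (calc - readings$measured) / readings$measured
  }
  mad_curve <- numeric(length(dlg_grid))
  sd_curve <- numeric(length(dlg_grid))
  for (j in seq_along(dlg_grid)) {
    dd <- diffs_at(dlg_grid[j])
    mad_curve[j] <- mean(abs(dd))
    sd_curve[j] <- stats::sd(dd)
  }
  best <- which(mad_curve == min(mad_curve))
  tie <- length(best) > 1L
  if (tie) warning("multiple DLG grid values attain the minimum; using the smallest")
  j0 <- best[1]
  optimum <- dlg_grid[j0]
  if (refine && j0 > 1L && j0 < length(dlg_grid)) {
    x <- dlg_grid[(j0 - 1):(j0 + 1)]
    y <- mad_curve[(j0 - 1):(j0 + 1)]
    denom <- (x[1] - x[2]) * (x[1] - x[3]) * (x[2] - x[3])
    a <- (x[3] * (y[2] - y[1]) + x[2] * (y[1] - y[3]) + x[1] * (y[3] - y[2])) / denom
    b <- (x[3]^2 * (y[1] - y[2]) + x[2]^2 * (y[3] - y[1]) + x[1]^2 * (y[2] - y[3])) / denom
    if (a > 0) optimum <- max(min(-b / (2 * a), x[3]), x[1])
  }
  structure(
    list(dlg_grid = dlg_grid, mean_abs_diff = mad_curve,
         per_plan_sd = sd_curve, optimum = optimum,
         value_at_optimum = mad_curve[j0], tie = tie),
    class = "dlg_curve"
  )
}

#' @export
print.dlg_curve <- function(x, ...) {
  cat(sprintf("<dlg_curve> optimum DLG %.2f mm, mean |diff| %.3f%% there\n",
              x$optimum, 100 * x$value_at_optimum))
  cat(sprintf("  grid: %g to %g mm (%d points)\n",
              min(x$dlg_grid), max(x$dlg_grid), length(x$dlg_grid)))
  invisible(x)
}

#' Estimate the MLC transmission from open and closed-leaf readings
#'
#' The transmission is the ratio of the dose measured with all leaves closed
#' behind the jaws to the open-field dose at the same field size.
#'
#' @param open_reading Open-field dose reading, > 0.
#' @param closed_reading Closed-MLC dose reading, >= 0 and < `open_reading`.
#' @return Transmission fraction.
#' @export
estimate_transmission <- function(open_reading, closed_reading) {
  stopifnot(is.numeric(open_reading), is.numeric(closed_reading),
            length(open_reading) == 1L, length(closed_reading) == 1L)
  if (open_reading <= 0) stop("open_reading must be > 0")
  if (closed_reading < 0) stop("closed_reading must be >= 0")
  if (closed_reading >= open_reading) {
    stop("closed_reading must be smaller than open_reading")
  }
  closed_reading / open_reading
}

#' Sweeping-gap reading series
#'
#' @param gaps Strictly increasing gap widths, mm, all below `sweep_length`.
#' @param readings Dose reading per gap.
#' @param open_reading Open-field reading (same calibration).
#' @param closed_reading Closed-MLC reading.
#' @param sweep_length Total leaf travel, mm.
#' @return An object of class `sweeping_series`.
#' @export
sweeping_series <- function(gaps, readings, open_reading, closed_reading,
                            sweep_length = 100) {
  stopifnot(is.numeric(gaps), is.numeric(readings),
            length(gaps) == length(readings))
  if (is.unsorted(gaps, strictly = TRUE)) stop("gaps must be strictly increasing")
  if (any(gaps <= 0) || any(gaps >= sweep_length)) {
    stop("gaps must lie strictly between 0 and sweep_length")
  }
  if (!(closed_reading > 0 && closed_reading < open_reading)) {
    stop("need 0 < closed_reading < open_reading")
  }
  structure(
    list(gaps = as.numeric(gaps), readings = as.numeric(readings),
         open_reading = open_reading, closed_reading = closed_reading,
         sweep_length = sweep_length),
    class = "sweeping_series"
  )
}

#' Classic sweeping-gap estimate of the dosimetric leaf gap
#'
#' Readings of synchronous sweeping gap deliveries are first corrected for
#' the transmission through the closed part of the sweep,
#' `R'(g) = R(g) - T * open * (1 - g / L)`, then a straight line
#' `R' = m g + b` is fitted by least squares; the rounded-leaf-end model
#' makes the corrected dose proportional to `g + DLG`, so `DLG = b / m`.
#'
#' @param series A [sweeping_series()].
#' @param transmission Transmission fraction `T`, measured independently.
#' @return DLG estimate, mm.
#' @export
estimate_dlg_sweeping <- function(series, transmission) {
  stopifnot(inherits(series, "sweeping_series"),
            is.numeric(transmission), length(transmission) == 1L)
  if (length(series$gaps) < 2L) stop("need at least 2 gap readings")
  corrected <- series$readings -
    transmission * series$open_reading * (1 - series$gaps / series$sweep_length)
  fit <- stats::lm(corrected ~ series$gaps)
  m <- unname(stats::coef(fit)[2])
  b <- unname(stats::coef(fit)[1])
  if (!is.finite(m) || m <= 0) {
    stop("sweeping-gap series has non-positive slope; cannot extrapolate DLG")
  }
  b / m
}
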