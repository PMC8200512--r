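# All tabular output is plain CSV with `# key=value` header lines; numbers
# are written with 12 significant digits so write/read round-trips are
# lossless at that precision.

fmt_num <- function(x) formatC(x, digits = 12, format = "g", width = -1)

read_header <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*)$", h))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- trimws(m[3])
  }
  kv
}

#' Write / read a profile CSV
#'
#' Format: `# axis=`, `# field_size_mm=`, `# depth_mm=`, `# ssd_mm=` header
#' lines followed by `position_mm,reading` rows.
#'
#' @param p A [profile()].
#' @param path File path.
#' @return `write_profile_csv` returns `path` invisibly; `read_profile_csv`
#'   returns a [profile()].
#' @export
write_profile_csv <- function(p, path) {
  stopifnot(inherits(p, "profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# axis=%s", p$axis),
    sprintf("# field_size_mm=%s", fmt_num(p$field_size)),
    sprintf("# depth_mm=%s", fmt_num(p$depth)),
    sprintf("# ssd_mm=%s", fmt_num(p$ssd)),
    sprintf("# label=%s", p$label),
    "position_mm,reading",
    paste(fmt_num(p$positions), fmt_num(p$readings), sep = ",")
  ), con)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  kv <- read_header(path)
  tab <- utils::read.csv(path, comment.char = "#")
  profile(axis = kv$axis, field_size = as.numeric(kv$field_size_mm),
          positions = tab$position_mm, readings = tab$reading,
          depth = as.numeric(kv$depth_mm %||% 100),
          ssd = as.numeric(kv$ssd_mm %||% 900),
          label = kv$label %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read the aOSG plan and reading tables
#'
#' Plans: `label,gap_mm,tg_fraction,shift_mm`. Readings:
#' `label,measured_dose`.
#'
#' @param plans An `aosg_plans` table.
#' @param path File path.
#' @export
write_aosg_plans_csv <- function(plans, path) {
  stopifnot(inherits(plans, "aosg_plans"))
  utils::write.csv(as.data.frame(lapply(plans, function(col) {
    if (is.numeric(col)) fmt_num(col) else col
  })), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_aosg_plans_csv
#' @export
read_aosg_plans_csv <- function(path) {
  tab <- utils::read.csv(path)
  plans <- data.frame(label = as.character(tab$label), gap_mm = tab$gap_mm,
                      tg_fraction = tab$tg_fraction, shift_mm = tab$shift_mm,
                      stringsAsFactors = FALSE)
  if (max(abs(plans$shift_mm - plans$gap_mm * plans$tg_fraction)) > 1e-6) {
    stop("plan table violates shift = tg_fraction * gap")
  }
  class(plans) <- c("aosg_plans", "data.frame")
  plans
}

#' @rdname write_aosg_plans_csv
#' @param readings Data frame with `label` and `measured_dose`.
#' @export
write_readings_csv <- function(readings, path) {
  stopifnot(all(c("label", "measured_dose") %in% names(readings)))
  utils::write.csv(data.frame(label = readings$label,
                              measured_dose = fmt_num(readings$measured_dose)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_aosg_plans_csv
#' @export
read_readings_csv <- function(path) {
  utils::read.csv(path)
}

#' Write / read a sweeping-gap series CSV
#'
#' Header lines carry the open and closed readings and the sweep length;
#' rows are `gap_mm,reading`.
#'
#' @param series A [sweeping_series()].
#' @param path File path.
#' @export
write_sweeping_csv <- function(series, path) {
  stopifnot(inherits(series, "sweeping_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# open_reading=%s", fmt_num(series$open_reading)),
    sprintf("# closed_reading=%s", fmt_num(series$closed_reading)),
    sprintf("# sweep_length_mm=%s", fmt_num(series$sweep_length)),
    "gap_mm,reading",
    paste(fmt_num(series$gaps), fmt_num(series$readings), sep = ",")
  ), con)
  invisible(path)
}

#' @rdname write_sweeping_csv
#' @export
read_sweeping_csv <- function(path) {
  kv <- read_header(path)
  tab <- utils::read.csv(path, comment.char = "#")
  sweeping_series(gaps = tab$gap_mm, readings = tab$reading,
                  open_reading = as.numeric(kv$open_reading),
                  closed_reading = as.numeric(kv$closed_reading),
                  sweep_length = as.numeric(kv$sweep_length_mm))
}

#' Write / read the measured output-factor table
#'
#' Columns: `field_size_mm,detector,raw_ratio,correction_factor,measured_of`
#' with `measured_of = raw_ratio * correction_factor`.
#'
#' @param of Data frame with at least the first four columns above.
#' @param path File path.
#' @export
write_of_csv <- function(of, path) {
  stopifnot(all(c("field_size_mm", "detector", "raw_ratio",
                  "correction_factor") %in% names(of)))
  of$measured_of <- of$raw_ratio * of$correction_factor
  out <- data.frame(field_size_mm = fmt_num(of$field_size_mm),
                    detector = of$detector,
                    raw_ratio = fmt_num(of$raw_ratio),
                    correction_factor = fmt_num(of$correction_factor),
                    measured_of = fmt_num(of$measured_of))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_of_csv
#' @export
read_of_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a 2D dose plane as gridded text
#'
#' Header lines give spacing, origin and units; then one whitespace-separated
#' row of doses per x index (columns run along y).
#'
#' @param g A [dose_grid()].
#' @param path File path.
#' @export
write_dose_plane <- function(g, path) {
  stopifnot(inherits(g, "dose_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# spacing_mm=%s,%s", fmt_num(g$spacing[1]), fmt_num(g$spacing[2])),
    sprintf("# origin_mm=%s,%s", fmt_num(g$origin[1]), fmt_num(g$origin[2])),
    sprintf("# units=%s", g$units),
    apply(g$dose, 1L, function(row) paste(fmt_num(row), collapse = " "))
  ), con)
  invisible(path)
}

#' @rdname write_dose_plane
#' @export
read_dose_plane <- function(path) {
  kv <- read_header(path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  dose <- do.call(rbind, lapply(lines, function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  dose_grid(dose,
            spacing = as.numeric(strsplit(kv$spacing_mm, ",")[[1]]),
            origin = as.numeric(strsplit(kv$origin_mm, ",")[[1]]),
            units = kv$units %||% "normalized")
}

#' Read a commissioning run configuration
#'
#' The configuration is a YAML file naming the beam, the seed, the input
#' files per stage (any stage may be omitted and is then skipped), the
#' tuning grids, the DOE levels and alpha, the gamma criteria, and the
#' synthetic-TPS engine settings used for the calculated side
#' (`tg_loss_calculated`, `sweep_length`, `calibration`).
#'
#' @param path YAML file path.
#' @return A list of class `run_config`; grids are expanded to numeric
#'   vectors and validated.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$config_path <- normalizePath(path)
  cfg$config_md5 <- unname(tools::md5sum(path))
  expand_grid_spec <- function(g, what) {
    if (is.null(g) || (is.list(g) && length(g) == 0)) {
      stop(what, " grid must be non-empty and sorted")
    }
    v <- if (is.list(g)) {
      if (!all(c("from", "to", "by") %in% names(g))) {
        stop(what, " grid needs from/to/by fields (or a numeric vector)")
      }
      seq(g$from, g$to, by = g$by)
    } else as.numeric(g)
    if (length(v) == 0 || is.unsorted(v, strictly = TRUE)) {
      stop(what, " grid must be non-empty and sorted")
    }
    v
  }
  cfg$sigma_grid <- expand_grid_spec(cfg$sigma_grid, "sigma")
  cfg$dlg_grid <- expand_grid_spec(cfg$dlg_grid, "dlg")
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$engine$tg_loss_calculated <- cfg$engine$tg_loss_calculated %||% 0
  cfg$engine$sweep_length <- cfg$engine$sweep_length %||% 100
  cfg$engine$calibration <- cfg$engine$calibration %||% 1
  cfg$gamma <- utils::modifyList(
    list(dose_pct = 3, dta_mm = 2, threshold_pct = 10), cfg$gamma %||% list())
  cfg$doe$alpha <- cfg$doe$alpha %||% 0.01
  class(cfg) <- "run_config"
  cfg
}
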