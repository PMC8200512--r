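# --- L27 orthogonal array over GF(3) ---------------------------------------
#
# The 27 runs are indexed by three base digits (x1, x2, x3) in {0,1,2}; the 13
# columns are the non-proportional nonzero coefficient vectors (a,b,c) over
# GF(3), normalized so the first nonzero coefficient is 1, with column level
# = (a x1 + b x2 + c x3) mod 3. Two assigned columns u, v confound their
# interaction in the columns u+v and u+2v (normalized), which is how
# interaction columns are located.

l27_coefficients <- function() {
  cols <- list()
  for (a in 0:2) for (b in 0:2) for (c in 0:2) {
    v <- c(a, b, c)
    if (all(v == 0)) next
    first <- v[which(v != 0)[1]]
    if (first != 1) next  # keep one representative per proportional pair
    cols[[length(cols) + 1L]] <- v
  }
  cols  # 13 columns
}

l27_normalize <- function(v) {
  v <- v %% 3
  if (all(v == 0)) stop("degenerate column combination")
  first <- v[which(v != 0)[1]]
  if (first == 2) v <- (2 * v) %% 3
  v
}

l27_column_index <- function(v, cols) {
  v <- l27_normalize(v)
  for (i in seq_along(cols)) if (all(cols[[i]] == v)) return(i)
  stop("column not found in L27 coefficient table")
}

# Indices of the two columns confounding the interaction of columns i and j.
l27_interaction_cols <- function(i, j, cols) {
  c(l27_column_index(cols[[i]] + cols[[j]], cols),
    l27_column_index(cols[[i]] + 2 * cols[[j]], cols))
}

l27_array <- function() {
  cols <- l27_coefficients()
  runs <- expand.grid(x3 = 0:2, x2 = 0:2, x1 = 0:2)[, c("x1", "x2", "x3")]
  arr <- matrix(0L, nrow = 27, ncol = length(cols))
  for (k in seq_along(cols)) {
    v <- cols[[k]]
    arr[, k] <- as.integer((v[1] * runs$x1 + v[2] * runs$x2 + v[3] * runs$x3) %% 3 + 1L)
  }
  arr
}

#' Construct a Taguchi L27 design for the four beam parameters
#'
#' Builds the standard 27-run, 13-column, three-level orthogonal array and
#' assigns one column per factor plus two columns per requested two-factor
#' interaction (a three-level interaction carries 4 degrees of freedom and
#' occupies two columns). Columns left unassigned estimate the residual
#' error. The default interactions are DLG x sigma_x and DLG x sigma_y, the
#' pairs most relevant to small-field output factors.
#'
#' @param factors Factor names (default the four beam parameters).
#' @param interactions List of length-2 character vectors naming factor
#'   pairs whose interaction must be estimable.
#' @return An object of class `taguchi_design` with the 27 x 13 level array
#'   (`array`), `factor_columns`, `interaction_columns` and `error_columns`.
#' @export
build_l27 <- function(factors = c("sigma_x", "sigma_y", "dlg", "transmission"),
                      interactions = list(c("dlg", "sigma_x"),
                                          c("dlg", "sigma_y"))) {
  stopifnot(is.character(factors), length(factors) >= 1,
            !anyDuplicated(factors))
  if (length(factors) > 13) stop("L27 has only 13 columns")
  interactions <- lapply(interactions, function(p) {
    if (length(p) != 2 || !all(p %in% factors)) {
      stop("each interaction must name two of the declared factors")
    }
    p
  })
  need <- length(factors) + 2L * length(interactions)
  if (need > 13L) {
    stop(sprintf(
      "requested %d factors and %d interactions need %d columns; L27 has 13",
      length(factors), length(interactions), need))
  }
  cols <- l27_coefficients()

  # Depth-first search for a conflict-free column assignment. In strict mode
  # a factor is additionally kept off any column confounded with a
  # two-factor interaction of already-placed factors, so main effects stay
  # clear of all pairwise interactions whenever the array permits it.
  assign_cols <- function(assigned, strict) {
    k <- length(assigned) + 1L
    if (k > length(factors)) return(assigned)
    for (cand in seq_along(cols)) {
      if (cand %in% assigned) next
      if (strict) {
        # keep the three diagonal runs (all-low / all-mid / all-high)
        # distinguishable on every factor column
        if (sum(cols[[cand]]) %% 3 == 0) next
        if (length(assigned) >= 2L) {
          clash <- FALSE
          pairs <- utils::combn(assigned, 2L)
          for (q in seq_len(ncol(pairs))) {
            if (cand %in% l27_interaction_cols(pairs[1, q], pairs[2, q], cols)) {
              clash <- TRUE; break
            }
          }
          if (clash) next
        }
      }
      trial <- c(assigned, cand)
      ok <- TRUE
      used <- trial
      for (p in interactions) {
        ia <- match(p[1], factors); ib <- match(p[2], factors)
        if (ia <= length(trial) && ib <= length(trial)) {
          ic <- l27_interaction_cols(trial[ia], trial[ib], cols)
          if (any(ic %in% used)) { ok <- FALSE; break }
          used <- c(used, ic)
        }
      }
      if (anyDuplicated(used)) ok <- FALSE
      if (ok) {
        res <- assign_cols(trial, strict)
        if (!is.null(res)) return(res)
      }
    }
    NULL
  }
  factor_cols <- assign_cols(integer(0), strict = TRUE)
  if (is.null(factor_cols)) factor_cols <- assign_cols(integer(0), strict = FALSE)
  if (is.null(factor_cols)) {
    stop("requested interaction set is not representable in L27 ",
         "without confounding; reduce the interactions")
  }
  names(factor_cols) <- factors
  interaction_cols <- lapply(interactions, function(p) {
    l27_interaction_cols(factor_cols[[p[1]]], factor_cols[[p[2]]], cols)
  })
  names(interaction_cols) <- vapply(interactions,
                                    function(p) paste(p, collapse = ":"),
                                    character(1))
  used <- c(factor_cols, unlist(interaction_cols))
  structure(
    list(array = l27_array(),
         coefficients = cols,
         factors = factors,
         interactions = interactions,
         factor_columns = factor_cols,
         interaction_columns = interaction_cols,
         error_columns = setdiff(seq_along(cols), used)),
    class = "taguchi_design"
  )
}

#' @export
print.taguchi_design <- function(x, ...) {
  cat(sprintf("<taguchi_design> L27(3^13): %d trials, %d factors, %d interactions\n",
              nrow(x$array), length(x$factors), length(x$interactions)))
  cat("  factor columns:", paste(sprintf("%s=%d", names(x$factor_columns),
                                         x$factor_columns), collapse = ", "), "\n")
  if (length(x$interaction_columns)) {
    cat("  interaction columns:",
        paste(sprintf("%s=(%s)", names(x$interaction_columns),
                      vapply(x$interaction_columns, paste, character(1),
                             collapse = ",")), collapse = ", "), "\n")
  }
  cat("  error columns:", paste(x$error_columns, collapse = ", "), "\n")
  invisible(x)
}

#' Three-level factor settings for the design of experiments
#'
#' @param sigma_x,sigma_y,dlg Three strictly increasing levels each, mm.
#' @param transmission Three strictly increasing levels, as fractions.
#' @return An object of class `factor_levels`.
#' @export
factor_levels <- function(sigma_x, sigma_y, dlg, transmission) {
  lv <- list(sigma_x = sigma_x, sigma_y = sigma_y, dlg = dlg,
             transmission = transmission)
  for (nm in names(lv)) {
    v <- lv[[nm]]
    if (!is.numeric(v) || length(v) != 3L || is.unsorted(v, strictly = TRUE)) {
      stop(nm, " must supply exactly 3 strictly increasing levels")
    }
  }
  structure(lv, class = "factor_levels")
}

#' Level presets for the three studied beam models
#'
#' Parameter levels bracketing the tuned values of each beam model:
#' a 6 MV beam with a Millennium 120 MLC, a 6 MV beam with a
#' high-definition (HD 120) MLC, and a 6 MV FFF beam with an HD 120 MLC.
#' Transmission levels are stored as fractions.
#'
#' @return A [factor_levels()] object.
#' @export
levels_millennium_x6 <- function() {
  factor_levels(sigma_x = c(0.7, 1.3, 1.8), sigma_y = c(0, 1.1, 1.4),
                dlg = c(0.75, 2.3, 3), transmission = c(0.01, 0.018, 0.02))
}

#' @rdname levels_millennium_x6
#' @export
levels_hd_x6 <- function() {
  factor_levels(sigma_x = c(0, 0.6, 1.2), sigma_y = c(0, 0.6, 1.2),
                dlg = c(0.2, 1.5, 2.5), transmission = c(0.008, 0.012, 0.018))
}

#' @rdname levels_millennium_x6
#' @export
levels_hd_x6fff <- function() {
  factor_levels(sigma_x = c(0, 0.6, 1.2), sigma_y = c(0, 0.6, 1.2),
                dlg = c(0, 0.8, 1.6), transmission = c(0.008, 0.012, 0.018))
}

#' Map design rows to beam-model parameter settings
#'
#' @param design A [build_l27()] design whose factors are the four beam
#'   parameters.
#' @param levels A [factor_levels()] object.
#' @return List of 27 [beam_params()] objects, one per trial.
#' @export
design_to_settings <- function(design, levels) {
  stopifnot(inherits(design, "taguchi_design"), inherits(levels, "factor_levels"))
  if (!all(c("sigma_x", "sigma_y", "dlg", "transmission") %in% design$factors)) {
    stop("design must carry the four beam-parameter factors")
  }
  lapply(seq_len(nrow(design$array)), function(i) {
    val <- function(f) {
      lev <- design$array[i, design$factor_columns[[f]]]
      if (!lev %in% 1:3) stop("level index out of range 1..3")
      levels[[f]][lev]
    }
    beam_params(sigma_x = val("sigma_x"), sigma_y = val("sigma_y"),
                dlg = val("dlg"), transmission = val("transmission"))
  })
}

#' Per-trial output-factor responses
#'
#' For every trial's parameter setting, computes the signed difference
#' between the calculated output factor and the detector-corrected measured
#' output factor, in percent, averaged over the detectors.
#'
#' @param settings List of 27 [beam_params()] from [design_to_settings()].
#' @param measured_of Data frame with columns `field_size_mm`, `detector`,
#'   `raw_ratio` and `correction_factor`; the measured output factor is
#'   `raw_ratio * correction_factor`.
#' @param calc_provider Function `(params, field_sizes) -> numeric` returning
#'   the calculated output factor per field size.
#' @param field_sizes Field sizes (mm) to analyze; default the six sizes
#'   0.5 to 2 cm in 0.5 cm steps plus 3 and 4 cm.
#' @return A 27 x length(field_sizes) matrix of class `response_table`,
#'   columns named by field size, in percent.
#' @export
compute_responses <- function(settings, measured_of, calc_provider,
                              field_sizes = c(5, 10, 15, 20, 30, 40)) {
  stopifnot(is.list(settings), is.function(calc_provider),
            is.data.frame(measured_of),
            all(c("field_size_mm", "detector", "raw_ratio",
                  "correction_factor") %in% names(measured_of)))
  measured_of$measured_of <- measured_of$raw_ratio * measured_of$correction_factor
  meas_by_fs <- vapply(field_sizes, function(fs) {
    rows <- measured_of[measured_of$field_size_mm == fs, ]
    if (nrow(rows) == 0) stop("no measured output factor for field size ", fs)
    mean(rows$measured_of)
  }, numeric(1))
  resp <- t(vapply(settings, function(p) {
    calc <- calc_provider(p, field_sizes)
    100 * (calc - meas_by_fs)
  }, numeric(length(field_sizes))))
  colnames(resp) <- as.character(field_sizes)
  class(resp) <- c("response_table", class(resp))
  resp
}

# Sum of squares of one array column: 9 runs per level in L27.
column_ss <- function(y, col_levels) {
  gm <- mean(y)
  means <- tapply(y, col_levels, mean)
  sum(table(col_levels) * (means - gm)^2)
}

#' Level effects, amplitudes and ANOVA of the L27 responses
#'
#' Each field size is analyzed separately. Main-effect sums of squares use
#' the three level means of the factor's column (2 df); an interaction pools
#' its two confounding columns (4 df); the error pools all unassigned
#' columns. Factor amplitudes are the spread (max - min) of the level means;
#' interaction amplitudes are the spread of the 3 x 3 cell means after
#' removing the additive part. Sources are ordered by decreasing
#' significance. When the responses are an exact function of the factors the
#' error sum of squares vanishes; F tests are then impossible and sources
#' are ranked by their sum of squares instead, with a flag.
#'
#' @param design A [build_l27()] design.
#' @param responses A [compute_responses()] table (or any 27-row matrix).
#' @param alpha Significance level; default 0.01.
#' @return List of class `doe_analysis` with `effects` (data frame: source,
#'   field_size_mm, amplitude_pct), `anova` (data frame: field_size_mm,
#'   source, ss, df, ms, f, p, significant, one block per field size ordered
#'   by significance) and a `zero_error` flag.
#' @export
effects_and_anova <- function(design, responses, alpha = 0.01) {
  stopifnot(inherits(design, "taguchi_design"), is.matrix(responses),
            nrow(responses) == nrow(design$array))
  fs_names <- colnames(responses)
  if (is.null(fs_names)) fs_names <- as.character(seq_len(ncol(responses)))
  arr <- design$array
  err_df <- 2L * length(design$error_columns)

  effects <- list(); anova <- list()
  zero_error <- FALSE
  for (j in seq_len(ncol(responses))) {
    y <- responses[, j]
    gm <- mean(y)
    ss_err <- sum(vapply(design$error_columns, function(k) {
      column_ss(y, arr[, k])
    }, numeric(1)))
    if (ss_err < 1e-12 * max(1, sum((y - gm)^2))) zero_error <- TRUE
    ms_err <- if (err_df > 0) ss_err / err_df else NA_real_

    rows <- list()
    for (f in design$factors) {
      k <- design$factor_columns[[f]]
      lm_f <- tapply(y, arr[, k], mean)
      rows[[f]] <- list(source = f, ss = column_ss(y, arr[, k]), df = 2L,
                        amplitude = max(lm_f) - min(lm_f))
    }
    for (nm in names(design$interaction_columns)) {
      ks <- design$interaction_columns[[nm]]
      ss <- sum(vapply(ks, function(k) column_ss(y, arr[, k]), numeric(1)))
      pair <- design$interactions[[match(nm, names(design$interaction_columns))]]
      la <- arr[, design$factor_columns[[pair[1]]]]
      lb <- arr[, design$factor_columns[[pair[2]]]]
      cell <- tapply(y, list(la, lb), mean)
      inter <- cell - outer(tapply(y, la, mean), tapply(y, lb, mean), `+`) + gm
      rows[[nm]] <- list(source = nm, ss = ss, df = 4L,
                         amplitude = max(inter) - min(inter))
    }
    tab <- do.call(rbind, lapply(rows, function(r) {
      ms <- r$ss / r$df
      fstat <- if (is.na(ms_err) || ms_err <= 0) NA_real_ else ms / ms_err
      p <- if (is.na(fstat)) NA_real_ else stats::pf(fstat, r$df, err_df,
                                                     lower.tail = FALSE)
      data.frame(field_size_mm = fs_names[j], source = r$source, ss = r$ss,
                 df = r$df, ms = ms, f = fstat, p = p,
                 significant = !is.na(p) && p < alpha,
                 stringsAsFactors = FALSE)
    }))
    tab <- rbind(tab, data.frame(field_size_mm = fs_names[j],
                                 source = "error", ss = ss_err, df = err_df,
                                 ms = ms_err, f = NA_real_, p = NA_real_,
                                 significant = NA, stringsAsFactors = FALSE))
    src <- tab$source != "error"
    ord <- if (all(is.na(tab$p[src]))) order(-tab$ss[src]) else order(tab$p[src])
    tab <- rbind(tab[src, ][ord, ], tab[!src, ])
    anova[[j]] <- tab
    effects[[j]] <- do.call(rbind, lapply(rows, function(r) {
      data.frame(source = r$source, field_size_mm = fs_names[j],
                 amplitude_pct = r$amplitude, stringsAsFactors = FALSE)
    }))
  }
  out <- list(effects = do.call(rbind, c(effects, make.row.names = FALSE)),
              anova = do.call(rbind, c(anova, make.row.names = FALSE)),
              zero_error = zero_error, alpha = alpha)
  if (zero_error) {
    out$note <- paste("error sum of squares is (numerically) zero for at",
                      "least one response; sources ranked by sum of squares")
  }
  class(out) <- "doe_analysis"
  out
}

#' @export
print.doe_analysis <- function(x, ...) {
  cat("<doe_analysis>\n")
  sig <- x$anova[!is.na(x$anova$significant) & x$anova$significant, ]
  if (nrow(sig)) {
    for (fs in unique(x$anova$field_size_mm)) {
      s <- sig$source[sig$field_size_mm == fs]
      cat(sprintf("  field %s mm: %s\n", fs,
                  if (length(s)) paste(s, collapse = ", ") else "none"))
    }
  } else {
    cat("  no significant sources (or error df unavailable)\n")
  }
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' 3 x 3 interaction surface of two factors
#'
#' Mean response per combination of the two factors' levels; in the L27
#' array each of the nine cells holds exactly three trials. A significant
#' interaction shows as a non-parallel (often single-corner) pattern.
#'
#' @param design A [build_l27()] design.
#' @param responses A [compute_responses()] table.
#' @param pair Character vector of the two factor names.
#' @param field_size Which response column to use (name or index).
#' @return 3 x 3 matrix of cell means (rows: levels of `pair[1]`).
#' @export
interaction_surface <- function(design, responses, pair, field_size = 1L) {
  stopifnot(inherits(design, "taguchi_design"), length(pair) == 2,
            all(pair %in% design$factors))
  y <- responses[, field_size]
  la <- design$array[, design$factor_columns[[pair[1]]]]
  lb <- design$array[, design$factor_columns[[pair[2]]]]
  out <- tapply(y, list(la, lb), mean)
  dimnames(out) <- list(paste0(pair[1], "_L", 1:3), paste0(pair[2], "_L", 1:3))
  out
}
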