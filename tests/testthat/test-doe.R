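# Taguchi L27 construction, response mapping, ANOVA and interaction
# surfaces.

test_that("the L27 array is balanced and pairwise orthogonal", {
  d <- build_l27()
  expect_equal(nrow(d$array), 27L)
  expect_equal(ncol(d$array), 13L)
  for (k in seq_len(13)) {
    expect_equal(as.vector(table(d$array[, k])), c(9L, 9L, 9L))
  }
  # every ordered pair of columns shows each of the 9 combinations 3 times
  for (i in 1:12) for (j in (i + 1):13) {
    expect_true(all(table(d$array[, i], d$array[, j]) == 3L))
  }
})

test_that("column bookkeeping keeps factors, interactions and error disjoint", {
  d <- build_l27()
  used <- c(d$factor_columns, unlist(d$interaction_columns))
  expect_false(anyDuplicated(used) > 0)
  expect_setequal(c(used, d$error_columns), 1:13)
  expect_length(d$error_columns, 5L)
})

test_that("impossible interaction sets are refused", {
  five <- letters[1:5]
  all_pairs <- utils::combn(five, 2, simplify = FALSE)
  expect_error(build_l27(five, all_pairs), "13")
  expect_error(build_l27(c("a", "b"), list(c("a", "x"))), "declared factors")
})

test_that("design rows map to parameter settings through the level table", {
  d <- build_l27()
  # the level-2 setting of the Millennium model and level-1 of the FFF model
  mil <- design_to_settings(d, levels_millennium_x6())
  all2 <- which(apply(d$array[, d$factor_columns], 1, function(r) all(r == 2)))
  expect_length(all2, 1L)
  expect_equal(unclass(mil[[all2]])[c("sigma_x", "sigma_y", "dlg", "transmission")],
               list(sigma_x = 1.3, sigma_y = 1.1, dlg = 2.3, transmission = 0.018))
  fff <- design_to_settings(d, levels_hd_x6fff())
  all1 <- which(apply(d$array[, d$factor_columns], 1, function(r) all(r == 1)))
  expect_equal(unclass(fff[[all1]])[c("sigma_x", "sigma_y", "dlg", "transmission")],
               list(sigma_x = 0, sigma_y = 0, dlg = 0, transmission = 0.008))
  # a corrupted level index is caught
  d_bad <- d
  d_bad$array[1, d$factor_columns[["dlg"]]] <- 4L
  expect_error(design_to_settings(d_bad, levels_millennium_x6()), "level index")
})

test_that("responses are the detector-mean calculated-minus-measured difference", {
  d <- build_l27()
  settings <- design_to_settings(d, levels_hd_x6())
  fs <- c(5, 10)
  # calc == measured for both detectors -> all responses zero
  of_equal <- do.call(rbind, lapply(c("diamond", "razor"), function(det) {
    data.frame(field_size_mm = fs, detector = det,
               raw_ratio = c(0.8, 0.9), correction_factor = 1)
  }))
  resp0 <- compute_responses(settings, of_equal,
                             function(p, f) c(0.8, 0.9), field_sizes = fs)
  expect_equal(dim(resp0), c(27L, 2L))
  expect_equal(max(abs(resp0)), 0)
  # detectors disagreeing by 2%: the response offsets to their midpoint
  of_split <- of_equal
  of_split$raw_ratio[of_split$detector == "diamond"] <- c(0.79, 0.89)
  of_split$raw_ratio[of_split$detector == "razor"] <- c(0.81, 0.91)
  resp1 <- compute_responses(settings, of_split,
                             function(p, f) c(0.8, 0.9), field_sizes = fs)
  expect_equal(max(abs(resp1)), 0, tolerance = 1e-10)
  # a non-unit correction factor rescales the measured side
  of_corr <- of_equal
  of_corr$correction_factor <- 1.01
  resp2 <- compute_responses(settings, of_corr,
                             function(p, f) c(0.8, 0.9), field_sizes = fs)
  expect_equal(as.numeric(resp2[1, "5"]), 100 * (0.8 - 0.8 * 1.01),
               tolerance = 1e-10)
})

test_that("a response driven by one factor is flagged by the ANOVA alone", {
  d <- build_l27()
  y <- c(-3, 0, 2)[d$array[, d$factor_columns[["dlg"]]]]
  set.seed(4)
  resp <- matrix(y + stats::rnorm(27, sd = 0.02), ncol = 1,
                 dimnames = list(NULL, "5"))
  res <- effects_and_anova(d, resp, alpha = 0.01)
  an <- res$anova[res$anova$source != "error", ]
  expect_identical(an$source[1], "dlg")
  expect_true(an$significant[an$source == "dlg"])
  expect_false(any(an$significant[an$source != "dlg"]))
  # amplitude is the spread of the level means
  amp <- res$effects$amplitude_pct[res$effects$source == "dlg"]
  expect_equal(amp, 5, tolerance = 0.05)
  # decomposition: sum of all source SS equals the total SS
  tot <- sum((resp[, 1] - mean(resp[, 1]))^2)
  expect_equal(sum(res$anova$ss), tot, tolerance = 1e-12)
})

test_that("constant responses yield no significant source and zero amplitudes", {
  d <- build_l27()
  resp <- matrix(1.5, 27, 1, dimnames = list(NULL, "10"))
  res <- suppressWarnings(effects_and_anova(d, resp))
  expect_true(res$zero_error)
  expect_false(any(res$anova$significant, na.rm = TRUE))
  expect_equal(res$effects$amplitude_pct, rep(0, nrow(res$effects)))
})

test_that("a planted single-cell interaction is recovered with its surface", {
  d <- build_l27()
  la <- d$array[, d$factor_columns[["dlg"]]]
  lb <- d$array[, d$factor_columns[["sigma_x"]]]
  y <- ifelse(la == 1 & lb == 3, -7, 0)
  set.seed(9)
  resp <- matrix(y + stats::rnorm(27, sd = 0.05), ncol = 1,
                 dimnames = list(NULL, "5"))
  res <- effects_and_anova(d, resp)
  an <- res$anova
  expect_true(an$significant[an$source == "dlg:sigma_x"])
  surf <- interaction_surface(d, resp, c("dlg", "sigma_x"))
  expect_equal(dim(surf), c(3L, 3L))
  expect_lt(surf[1, 3], -6.5)          # the deviant corner
  expect_equal(max(abs(surf[-c(7)])), 0, tolerance = 0.2)  # the other 8 cells
})

test_that("interaction surfaces of additive responses have parallel rows", {
  d <- build_l27()
  la <- d$array[, d$factor_columns[["dlg"]]]
  lb <- d$array[, d$factor_columns[["sigma_y"]]]
  resp <- matrix(2 * la - 3 * lb, ncol = 1, dimnames = list(NULL, "20"))
  surf <- interaction_surface(d, resp, c("dlg", "sigma_y"))
  # rows differ by a constant: the interaction part vanishes
  row_diffs <- apply(surf, 2, diff)
  expect_equal(row_diffs[, 1], row_diffs[, 2], tolerance = 1e-12)
  expect_equal(row_diffs[, 2], row_diffs[, 3], tolerance = 1e-12)
  # constant responses: all nine cells equal
  surf0 <- interaction_surface(d, matrix(4, 27, 1), c("dlg", "sigma_y"))
  expect_true(all(surf0 == 4))
})

test_that("permuting trial order leaves every level mean unchanged", {
  d <- build_l27()
  settings <- design_to_settings(d, levels_hd_x6())
  truth_of <- vapply(settings, function(p) output_factor(5, p), numeric(1))
  resp <- matrix(truth_of, ncol = 1, dimnames = list(NULL, "5"))
  res <- effects_and_anova(d, resp)
  set.seed(2)
  perm <- sample(27)
  d2 <- d; d2$array <- d$array[perm, , drop = FALSE]
  res2 <- effects_and_anova(d2, resp[perm, , drop = FALSE])
  expect_equal(res2$effects$amplitude_pct, res$effects$amplitude_pct,
               tolerance = 1e-12)
  expect_equal(res2$anova$ss[order(res2$anova$source)],
               res$anova$ss[order(res$anova$source)], tolerance = 1e-12)
})

test_that("engine responses reproduce the known sensitivity directions", {
  # the response grows when DLG or T grow and shrinks when the spot sizes
  # grow; at the smallest field the level contrasts show the same directions
  d <- build_l27()
  lv <- levels_hd_x6()
  settings <- design_to_settings(d, lv)
  fs <- c(5, 10, 20)
  meas_params <- beam_params(0.6, 0.6, 1.5, 0.012)  # mid-level truth
  of_meas <- output_factor(fs, meas_params)
  of_tab <- do.call(rbind, lapply(c("d1", "d2"), function(det) {
    data.frame(field_size_mm = fs, detector = det, raw_ratio = of_meas,
               correction_factor = 1)
  }))
  resp <- compute_responses(settings, of_tab,
                            function(p, f) output_factor(f, p),
                            field_sizes = fs)
  arr <- d$array
  y5 <- resp[, "5"]
  contrast <- function(f) {
    m <- tapply(y5, arr[, d$factor_columns[[f]]], mean)
    m[[3]] - m[[1]]
  }
  expect_gt(contrast("dlg"), 0)
  expect_lt(contrast("sigma_x"), 0)
  expect_lt(contrast("sigma_y"), 0)
  # transmission acts pointwise: raising only T raises the response
  lo <- compute_responses(list(beam_params(0.6, 0.6, 1.5, 0.008)), of_tab,
                          function(p, f) output_factor(f, p), field_sizes = fs)
  hi <- compute_responses(list(beam_params(0.6, 0.6, 1.5, 0.018)), of_tab,
                          function(p, f) output_factor(f, p), field_sizes = fs)
  expect_gt(hi[1, 1], lo[1, 1])
  expect_gte(hi[1, 2], lo[1, 2])
  # small-field concentration: more significant sources at 5 mm than 20 mm
  res <- effects_and_anova(d, resp)
  sig_count <- vapply(as.character(fs), function(f) {
    a <- res$anova[res$anova$field_size_mm == f, ]
    sum(a$significant, na.rm = TRUE)
  }, numeric(1))
  expect_gte(sig_count[["5"]], sig_count[["20"]])
})
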