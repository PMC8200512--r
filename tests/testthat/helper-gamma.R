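# Independent brute-force oracle: exhaustive search over the same offset
# disk, scalar arithmetic and hand-written bilinear interpolation.
gamma_brute <- function(ref, ev, dose_pct = 3, dta_mm = 2, threshold_pct = 10) {
  xs_r <- ref$origin[1] + (seq_len(nrow(ref$dose)) - 1) * ref$spacing[1]
  ys_r <- ref$origin[2] + (seq_len(ncol(ref$dose)) - 1) * ref$spacing[2]
  xs_e <- ev$origin[1] + (seq_len(nrow(ev$dose)) - 1) * ev$spacing[1]
  ys_e <- ev$origin[2] + (seq_len(ncol(ev$dose)) - 1) * ev$spacing[2]
  interp <- function(x, y) {
    if (x < xs_e[1] || x > xs_e[length(xs_e)] ||
        y < ys_e[1] || y > ys_e[length(ys_e)]) return(NA_real_)
    i <- min(max(floor((x - xs_e[1]) / ev$spacing[1]) + 1, 1), length(xs_e) - 1)
    j <- min(max(floor((y - ys_e[1]) / ev$spacing[2]) + 1, 1), length(ys_e) - 1)
    wx <- (x - xs_e[i]) / ev$spacing[1]
    wy <- (y - ys_e[j]) / ev$spacing[2]
    (1 - wx) * (1 - wy) * ev$dose[i, j] + wx * (1 - wy) * ev$dose[i + 1, j] +
      (1 - wx) * wy * ev$dose[i, j + 1] + wx * wy * ev$dose[i + 1, j + 1]
  }
  dd <- dose_pct / 100 * max(ref$dose)
  offs <- seq(-3 * dta_mm, 3 * dta_mm, by = dta_mm / 10)
  gam <- matrix(NA_real_, nrow(ref$dose), ncol(ref$dose))
  for (i in seq_along(xs_r)) for (j in seq_along(ys_r)) {
    if (ref$dose[i, j] < threshold_pct / 100 * max(ref$dose)) next
    best <- Inf
    for (ox in offs) for (oy in offs) {
      if (ox^2 + oy^2 > (3 * dta_mm)^2) next
      v <- interp(xs_r[i] + ox, ys_r[j] + oy)
      if (is.na(v)) next
      g2 <- (ox^2 + oy^2) / dta_mm^2 + (v - ref$dose[i, j])^2 / dd^2
      if (g2 < best) best <- g2
    }
    gam[i, j] <- sqrt(best)
  }
  gam
}
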