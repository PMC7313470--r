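## Independent brute-force oracle for the regime segmentation: enumerate
## every admissible breakpoint quadruple on the sample grid, fit the
## continuous piecewise-linear model by QR (lm.fit on the explicit hinge
## design matrix) and return the minimum SSE. Shares no code with the
## package's prefix-sum search.
oracle_min_sse <- function(d, f, min_seg = 10L, plateau_slope_frac = 0.1) {
  n <- length(d)
  best_sse <- Inf
  best_bp <- NULL
  for (i1 in seq(min_seg, n - 4L * min_seg)) {
    for (i2 in seq(i1 + min_seg, n - 3L * min_seg)) {
      for (i3 in seq(i2 + min_seg, n - 2L * min_seg)) {
        for (i4 in seq(i3 + min_seg, n - min_seg)) {
          X <- cbind(1, d,
                     pmax(d - d[i1], 0), pmax(d - d[i2], 0),
                     pmax(d - d[i3], 0), pmax(d - d[i4], 0))
          ft <- lm.fit(X, f)
          sl <- cumsum(unname(ft$coefficients)[2:6])
          if (anyNA(sl)) next
          k1 <- sl[2]; s2 <- sl[3]; k3 <- sl[4]; s4 <- sl[5]
          if (k1 <= 0 || k3 <= 0) next
          if (abs(s2) > plateau_slope_frac * k1) next
          if (abs(s4) > plateau_slope_frac * k3) next
          sse <- sum(ft$residuals^2)
          if (sse < best_sse) {
            best_sse <- sse
            best_bp <- c(i1, i2, i3, i4)
          }
        }
      }
    }
  }
  list(sse = best_sse, bp = best_bp)
}

## regime parameters whose corners are well separated on a short grid, so
## the exhaustive oracle stays tractable (n ~ 80)
oracle_params <- function() {
  regime_params(rate = 2e-6, toe_end = 1e-4, k1 = 10, F_y1 = 2e-3,
                plateau2_len = 2e-4, k3 = 25, F_y2 = 4.5e-3, d_max = 8e-4)
}

## standard gravity as used by the calibration relation
G_STD <- 9.81
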