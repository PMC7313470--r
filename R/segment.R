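#' Segment a force-distance curve into toe + four deformation regimes
#'
#' Fits a continuous five-piece piecewise-linear model (nonlinear toe treated
#' as a free-slope first piece, linear regime 1, constant-force regime 2, a
#' steeper linear regime 3, constant-force regime 4) to an FD curve by least
#' squares. Breakpoints are restricted to the sample grid and located by a
#' coarse grid search followed by local stride-halving refinement, which on
#' these curve shapes finds the same optimum as exhaustive search over all
#' admissible breakpoint quadruples.
#'
#' A candidate quadruple is admissible when every segment keeps at least
#' `min_seg` samples, the fitted regime-1 slope is positive and the fitted
#' plateau slopes are small relative to the neighbouring rises
#' (`|s2| <= plateau_slope_frac * k1`, `|s4| <= plateau_slope_frac * k3`);
#' optionally `k3 > k1` can be required. Slopes reported in the result are
#' re-estimated by plain OLS on the interior samples of each linear segment
#' (a small buffer next to each breakpoint is dropped so that an off-grid
#' corner cannot bias the slope); samples with displacement below
#' `toe_init` never enter the regime-1 slope fit. Yield forces are read off
#' the data as the maximum measured force within `yield_window` samples of
#' the corresponding breakpoint.
#'
#' @param curve an [fd_curve]
#' @param options a list of segmentation settings, see
#'   [segment_options()]
#' @return An object of class `regime_fit`: breakpoints (4 displacements,
#'   toe->1, 1->2, 2->3, 3->4), slopes `k1` and `k3`, yield forces `F_y1`,
#'   `F_y2`, mean plateau forces, the residual sum of squares `sse` of the
#'   piecewise model and bookkeeping flags.
#' @examples
#' crv <- generate_fd_curve(make_rate_preset(2.0), n_points = 400,
#'                          noise_sd = 0, seed = 1)
#' fit <- segment_regimes(crv)
#' c(fit$k1, fit$F_y1 * 1e3)  # 21.5 N/m, 1.5 mN
#' @export
segment_regimes <- function(curve, options = segment_options()) {
  stopifnot(inherits(curve, "fd_curve"))
  d <- curve$displacement
  f <- curve$force
  if (any(diff(d) <= 0)) stop("non-monotone displacement", call. = FALSE)
  n <- length(d)
  if (n < 5L * options$min_seg && !options$allow_partial) {
    stop("segmentation failure: too few samples (", n, ") for five segments",
         call. = FALSE)
  }
  if (options$smooth_window > 1L) {
    f <- moving_average(f, options$smooth_window)
  }

  ## scale to O(1) for numerical conditioning of the normal equations
  ds <- d / max(d)
  fs <- f / max(abs(f))

  pre <- hinge_prefix(ds, fs)
  toe_idx <- which.min(abs(d - options$toe_init))
  full <- NULL
  if (n >= 5L * options$min_seg) {
    best <- search_breakpoints(ds, fs, pre, options, toe_idx)
    if (!is.null(best)) {
      full <- tryCatch(full_regime_fit(curve, d, f, best$bp, options),
                       error = function(e) if (options$allow_partial) NULL
                       else stop(e))
    }
  }
  if (!is.null(full)) return(full)
  if (options$allow_partial) {
    ## reduced model: toe + linear rise + first plateau only (curve stopped
    ## before the second rise, or no admissible full fit)
    best <- search_breakpoints2(ds, fs, pre, options, toe_idx)
    if (!is.null(best)) return(partial_regime_fit(curve, d, f, best, options))
  }
  stop("segmentation failure: no admissible breakpoint quadruple ",
       "(no_yield_detected): the curve may lack constant-force plateaus",
       call. = FALSE)
}

full_regime_fit <- function(curve, d, f, bp_idx, options) {
  n <- length(d)

  ## explicit (QR) refit of the continuous piecewise model at the chosen
  ## breakpoints: accurate SSE, unscaled
  fit <- piecewise_fit(d, f, d[bp_idx])
  seg <- findInterval(seq_len(n), c(bp_idx + 1L)) + 1L # segment id 1..5

  ## interior OLS refit for the reported slopes
  buf <- options$slope_buffer
  k1 <- interior_slope(d, f, seg == 2L, buf, d_min = options$toe_init)
  k3 <- interior_slope(d, f, seg == 4L, buf)
  if (!is.finite(k1) || k1 <= 0 || !is.finite(k3) || k3 <= 0) {
    stop("segmentation failure: non-positive regime slope", call. = FALSE)
  }

  ## yield forces: maximum measured force near the line->plateau transitions
  w <- options$yield_window
  F_y1 <- max(f[max(1L, bp_idx[2] - w):min(n, bp_idx[2] + w)])
  F_y2 <- max(f[max(1L, bp_idx[4] - w):min(n, bp_idx[4] + w)])

  plateau2 <- interior_mean(f, seg == 3L, buf)
  plateau4 <- interior_mean(f, seg == 5L, buf)

  flags <- character(0)
  if (F_y2 <= F_y1) flags <- c(flags, "yield_order_violated")
  if (abs(F_y1 - plateau2) > 0.1 * abs(plateau2)) {
    flags <- c(flags, "yield_plateau_mismatch")
  }
  ## a toe boundary far from its nominal position usually means the sampling
  ## is too coarse for the minimum segment length to resolve the early
  ## regimes, and the model has latched onto later features
  if (d[bp_idx[1]] > 10 * options$toe_init) {
    flags <- c(flags, "toe_boundary_far_from_nominal")
  }
  structure(
    list(breakpoints = d[bp_idx], breakpoint_idx = bp_idx,
         k1 = k1, k3 = k3, F_y1 = F_y1, F_y2 = F_y2,
         plateau_forces = c(plateau2, plateau4),
         sse = fit$sse, coef = fit$coef, flags = flags,
         rate = curve$rate, n = n),
    class = "regime_fit"
  )
}

#' @export
print.regime_fit <- function(x, ...) {
  cat("Regime fit:\n")
  cat(sprintf("  breakpoints [mm]: %s\n",
              paste(sprintf("%.4g", x$breakpoints * 1e3), collapse = ", ")))
  cat(sprintf("  k1 = %.4g N/m, k3 = %.4g N/m\n", x$k1, x$k3))
  cat(sprintf("  F_y1 = %.4g mN, F_y2 = %.4g mN\n",
              x$F_y1 * 1e3, x$F_y2 * 1e3))
  cat(sprintf("  plateau forces: %.4g / %.4g mN, SSE %.3g N^2\n",
              x$plateau_forces[1] * 1e3, x$plateau_forces[2] * 1e3, x$sse))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Segmentation settings
#'
#' @param min_seg minimum number of samples per segment (candidates with
#'   fewer are rejected)
#' @param plateau_slope_frac admissibility bound on plateau slopes relative
#'   to the neighbouring rise
#' @param require_k3_gt_k1 require the second rise to be steeper than the
#'   first (off by default)
#' @param toe_init initial toe/regime-1 boundary \[m\]; samples below it are
#'   excluded from the regime-1 slope fit
#' @param yield_window half-width (in samples) of the window around a
#'   breakpoint within which the yield force is read off the data
#' @param slope_buffer samples dropped next to each breakpoint in the
#'   interior slope/plateau refits
#' @param smooth_window moving-average pre-smoothing width in samples
#'   (1 = off, the default for synthetic data; 11 is a reasonable value for
#'   measured curves)
#' @param coarse_grid approximate number of candidate positions per
#'   breakpoint in the coarse search
#' @param top_k number of leading candidates re-scored with the exact QR fit
#' @param allow_partial fit a reduced model (toe + rise + first plateau, or
#'   toe + rise alone) when the curve stops before the later regimes; such
#'   fits carry the flag `partial_fit` (and `no_yield_detected` when no
#'   plateau is present)
#' @return A list of settings for [segment_regimes()].
#' @export
segment_options <- function(min_seg = 10L, plateau_slope_frac = 0.1,
                            require_k3_gt_k1 = FALSE, toe_init = 0.01e-3,
                            yield_window = 5L, slope_buffer = 2L,
                            smooth_window = 1L, coarse_grid = 25L,
                            top_k = 20L, allow_partial = TRUE) {
  list(min_seg = as.integer(min_seg),
       plateau_slope_frac = plateau_slope_frac,
       require_k3_gt_k1 = isTRUE(require_k3_gt_k1),
       toe_init = toe_init,
       yield_window = as.integer(yield_window),
       slope_buffer = as.integer(slope_buffer),
       smooth_window = as.integer(smooth_window),
       coarse_grid = as.integer(coarse_grid),
       top_k = as.integer(top_k),
       allow_partial = isTRUE(allow_partial))
}

#' Summarize replicate regime fits at one displacement rate
#'
#' Arithmetic mean and (n-1)-denominator standard deviation of the elastic
#' constants and yield forces across replicate stretching experiments
#' performed at the same displacement rate.
#'
#' @param fits list of [segment_regimes()] results from curves at one rate
#' @param rate displacement rate \[m/s\] of the replicates
#' @return An object of class `replicate_summary`: per-parameter `mean` and
#'   `sd` (named vectors over `k1`, `k3`, `F_y1`, `F_y2`) and the replicate
#'   count `n`.
#' @export
summarize_replicates <- function(fits, rate) {
  if (length(fits) == 0L) stop("no fits supplied", call. = FALSE)
  if (!all(vapply(fits, inherits, logical(1), "regime_fit"))) {
    stop("fits must be a list of regime_fit objects", call. = FALSE)
  }
  rates <- vapply(fits, `[[`, numeric(1), "rate")
  if (any(abs(rates - rate) > 1e-12 * rate)) {
    stop("all fits must come from curves at the given rate", call. = FALSE)
  }
  pars <- c("k1", "k3", "F_y1", "F_y2")
  m <- vapply(pars, function(p) mean(vapply(fits, `[[`, numeric(1), p)),
              numeric(1))
  s <- vapply(pars, function(p) {
    v <- vapply(fits, `[[`, numeric(1), p)
    if (length(v) > 1L) stats::sd(v) else 0
  }, numeric(1))
  structure(list(mean = m, sd = s, n = length(fits), rate = rate),
            class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("Replicate summary (rate %.3g um/s, n = %d):\n",
              x$rate * 1e6, x$n))
  cat(sprintf("  k1   = %.4g +/- %.2g N/m\n", x$mean["k1"], x$sd["k1"]))
  cat(sprintf("  k3   = %.4g +/- %.2g N/m\n", x$mean["k3"], x$sd["k3"]))
  cat(sprintf("  F_y1 = %.4g +/- %.2g mN\n",
              x$mean["F_y1"] * 1e3, x$sd["F_y1"] * 1e3))
  cat(sprintf("  F_y2 = %.4g +/- %.2g mN\n",
              x$mean["F_y2"] * 1e3, x$sd["F_y2"] * 1e3))
  invisible(x)
}

## ---- internals ------------------------------------------------------------

moving_average <- function(x, w) {
  if (w %% 2L == 0L) w <- w + 1L
  as.numeric(stats::filter(x, rep(1 / w, w), sides = 2)) -> y
  ## keep edges unsmoothed rather than NA
  y[is.na(y)] <- x[is.na(y)]
  y
}

## Suffix sums used to evaluate the normal equations of the hinge basis
## [1, d, (d-b1)+, ..., (d-b4)+] in O(1) per breakpoint quadruple.
hinge_prefix <- function(d, f) {
  rev_cum <- function(v) rev(cumsum(rev(v)))
  list(d = d, f = f,
       S0 = rev_cum(rep(1, length(d))), S1 = rev_cum(d), S2 = rev_cum(d^2),
       Sy0 = rev_cum(f), Sy1 = rev_cum(f * d), Syy = sum(f^2),
       T0 = length(d), T1 = sum(d), T2 = sum(d^2),
       Ty0 = sum(f), Ty1 = sum(f * d))
}

## Fast SSE of the continuous piecewise-linear LS fit with breakpoints at
## sample indices bp (hinges start at sample bp+1); any number of
## breakpoints. Returns list(sse, slopes) or NULL if the system is singular.
hinge_sse <- function(pre, bp) {
  m <- length(bp)
  b <- pre$d[bp]
  j <- bp + 1L # first sample strictly above each breakpoint
  p <- m + 2L
  XtX <- matrix(0, p, p)
  Xty <- numeric(p)
  XtX[1, 1] <- pre$T0; XtX[1, 2] <- pre$T1; XtX[2, 2] <- pre$T2
  Xty[1] <- pre$Ty0;  Xty[2] <- pre$Ty1
  for (a in seq_len(m)) {
    ja <- j[a]; ba <- b[a]
    S0 <- pre$S0[ja]; S1 <- pre$S1[ja]; S2 <- pre$S2[ja]
    XtX[1, a + 2] <- S1 - ba * S0
    XtX[2, a + 2] <- S2 - ba * S1
    Xty[a + 2] <- pre$Sy1[ja] - ba * pre$Sy0[ja]
    for (c in a:m) {
      jc <- j[c]; bc <- b[c]
      ## both hinges active only above the later breakpoint
      XtX[a + 2, c + 2] <- pre$S2[jc] - (ba + bc) * pre$S1[jc] +
        ba * bc * pre$S0[jc]
    }
  }
  XtX[lower.tri(XtX)] <- t(XtX)[lower.tri(XtX)]
  beta <- tryCatch(solve(XtX, Xty), error = function(e) NULL)
  if (is.null(beta)) return(NULL)
  sse <- pre$Syy - sum(beta * Xty)
  ## cumulative slopes of the pieces
  slopes <- cumsum(beta[2:p])
  list(sse = max(sse, 0), slopes = slopes, beta = beta)
}

admissible_slopes <- function(slopes, options) {
  k1 <- slopes[2]; s2 <- slopes[3]; k3 <- slopes[4]; s4 <- slopes[5]
  if (!is.finite(k1) || k1 <= 0) return(FALSE)
  if (!is.finite(k3) || k3 <= 0) return(FALSE)
  if (abs(s2) > options$plateau_slope_frac * k1) return(FALSE)
  if (abs(s4) > options$plateau_slope_frac * k3) return(FALSE)
  if (options$require_k3_gt_k1 && k3 <= k1) return(FALSE)
  TRUE
}

## Enumerate admissible quadruples from per-breakpoint candidate index sets,
## score with the fast SSE, keep the best `top_k`.
score_candidates <- function(pre, cand, options) {
  n <- pre$T0
  ms <- options$min_seg
  out <- list()
  worst <- Inf
  keep <- options$top_k
  scores <- numeric(0)
  bps <- list()
  for (i1 in cand[[1]]) {
    if (i1 < ms || i1 > n - 4L * ms) next
    for (i2 in cand[[2]]) {
      if (i2 < i1 + ms || i2 > n - 3L * ms) next
      for (i3 in cand[[3]]) {
        if (i3 < i2 + ms || i3 > n - 2L * ms) next
        for (i4 in cand[[4]]) {
          if (i4 < i3 + ms || i4 > n - ms) next
          r <- hinge_sse(pre, c(i1, i2, i3, i4))
          if (is.null(r)) next
          if (!admissible_slopes(r$slopes, options)) next
          scores <- c(scores, r$sse)
          bps <- c(bps, list(c(i1, i2, i3, i4)))
        }
      }
    }
  }
  if (!length(scores)) return(NULL)
  ord <- order(scores)[seq_len(min(keep, length(scores)))]
  list(bp = bps[ord], sse = scores[ord])
}

search_breakpoints <- function(ds, fs, pre, options, toe_idx) {
  n <- length(ds)
  stride <- max(1L, floor(n / options$coarse_grid))
  ## candidate positions: coarse grid plus the sample nearest the nominal
  ## toe boundary (initialization of the toe/regime-1 breakpoint)
  grid <- sort(unique(c(seq(1L, n, by = stride), toe_idx)))
  cand <- list(grid, grid, grid, grid)
  top <- score_candidates(pre, cand, options)
  if (is.null(top)) return(NULL)

  ## refinement: from each coarse leader, coordinate-descent sweeps in which
  ## each breakpoint in turn is re-optimized by a full-range scan at sample
  ## resolution while the other three are held fixed
  n_lead <- min(5L, length(top$bp))
  leaders <- unique(top$bp[seq_len(n_lead)])
  refined <- lapply(leaders, function(bp0) {
    coord_descent(pre, bp0, options)
  })
  refined <- refined[!vapply(refined, is.null, logical(1))]
  if (!length(refined)) return(NULL)

  ## exact re-scoring of the refined candidates via QR on the scaled data
  best_bp <- NULL
  best_sse <- Inf
  for (bp in unique(lapply(refined, `[[`, "bp"))) {
    ft <- piecewise_fit(ds, fs, ds[bp])
    if (ft$sse < best_sse) {
      best_sse <- ft$sse
      best_bp <- bp
    }
  }
  list(bp = best_bp, sse = best_sse)
}

## Cyclic coordinate descent over breakpoint indices: each pass scans one
## breakpoint over its whole admissible range (respecting min_seg spacing to
## its neighbours) with the fast SSE, keeping the admissible argmin. Stops
## when a full sweep leaves the quadruple unchanged.
coord_descent <- function(pre, bp, options, max_sweeps = 12L,
                          admissible = admissible_slopes) {
  n <- pre$T0
  m <- length(bp)
  ms <- options$min_seg
  cur <- bp
  cur_sse <- Inf
  r0 <- hinge_sse(pre, cur)
  if (!is.null(r0) && admissible(r0$slopes, options)) cur_sse <- r0$sse
  for (sweep in seq_len(max_sweeps)) {
    moved <- FALSE
    for (a in rev(seq_len(m))) {
      lo <- if (a == 1L) ms else cur[a - 1L] + ms
      hi <- if (a == m) n - ms else cur[a + 1L] - ms
      if (lo > hi) next
      for (pos in lo:hi) {
        if (pos == cur[a]) next
        trial <- cur
        trial[a] <- pos
        r <- hinge_sse(pre, trial)
        if (is.null(r) || !admissible(r$slopes, options)) next
        if (r$sse < cur_sse) {
          cur_sse <- r$sse
          cur <- trial
          moved <- TRUE
        }
      }
    }
    if (!moved) break
  }
  if (!is.finite(cur_sse)) return(NULL)
  list(bp = cur, sse = cur_sse)
}

## Continuous piecewise-linear LS fit with fixed breakpoints b (same units
## as d), via QR on the explicit hinge design matrix.
piecewise_fit <- function(d, f, b) {
  X <- cbind(1, d,
             pmax(d - b[1], 0), pmax(d - b[2], 0),
             pmax(d - b[3], 0), pmax(d - b[4], 0))
  fit <- stats::lm.fit(X, f)
  list(sse = sum(fit$residuals^2), coef = unname(fit$coefficients),
       slopes = cumsum(unname(fit$coefficients)[2:6]))
}

## Reduced-model search for partial curves: toe + linear rise + first
## plateau (2 breakpoints); falls back to toe + rise only (1 breakpoint)
## when no plateau is present in the recorded span.
search_breakpoints2 <- function(ds, fs, pre, options, toe_idx) {
  n <- length(ds)
  ms <- options$min_seg
  adm2 <- function(slopes, options) {
    k1 <- slopes[2]; s2 <- slopes[3]
    is.finite(k1) && k1 > 0 && abs(s2) <= options$plateau_slope_frac * k1
  }
  adm1 <- function(slopes, options) is.finite(slopes[2]) && slopes[2] > 0
  if (n >= 3L * ms) {
    stride <- max(1L, floor(n / options$coarse_grid))
    grid <- sort(unique(c(seq(1L, n, by = stride), toe_idx)))
    cands <- list()
    sses <- numeric(0)
    for (i1 in grid) {
      if (i1 < ms || i1 > n - 2L * ms) next
      for (i2 in grid) {
        if (i2 < i1 + ms || i2 > n - ms) next
        r <- hinge_sse(pre, c(i1, i2))
        if (is.null(r) || !adm2(r$slopes, options)) next
        cands <- c(cands, list(c(i1, i2)))
        sses <- c(sses, r$sse)
      }
    }
    if (length(sses)) {
      leaders <- cands[order(sses)][seq_len(min(5L, length(sses)))]
      best <- NULL
      for (bp0 in leaders) {
        r <- coord_descent(pre, bp0, options, admissible = adm2)
        if (!is.null(r) && (is.null(best) || r$sse < best$sse)) best <- r
      }
      if (!is.null(best)) return(list(bp = best$bp, sse = best$sse,
                                      pieces = 3L))
    }
  }
  ## no plateau: toe + single rise
  if (n < 2L * ms) return(NULL)
  best <- NULL
  for (i1 in ms:(n - ms)) {
    r <- hinge_sse(pre, i1)
    if (is.null(r) || !adm1(r$slopes, options)) next
    if (is.null(best) || r$sse < best$sse) best <- list(bp = i1, sse = r$sse)
  }
  if (is.null(best)) return(NULL)
  list(bp = best$bp, sse = best$sse, pieces = 2L)
}

partial_regime_fit <- function(curve, d, f, best, options) {
  n <- length(d)
  bp_idx <- best$bp
  b <- d[bp_idx]
  X <- cbind(1, d)
  for (bb in b) X <- cbind(X, pmax(d - bb, 0))
  ft <- stats::lm.fit(X, f)
  seg <- findInterval(seq_len(n), bp_idx + 1L) + 1L
  buf <- options$slope_buffer
  k1 <- interior_slope(d, f, seg == 2L, buf, d_min = options$toe_init)
  flags <- "partial_fit"
  if (best$pieces >= 3L) {
    w <- options$yield_window
    F_y1 <- max(f[max(1L, bp_idx[2] - w):min(n, bp_idx[2] + w)])
    plateau2 <- interior_mean(f, seg == 3L, buf)
  } else {
    F_y1 <- NA_real_
    plateau2 <- NA_real_
    flags <- c(flags, "no_yield_detected")
  }
  structure(
    list(breakpoints = b, breakpoint_idx = bp_idx,
         k1 = k1, k3 = NA_real_, F_y1 = F_y1, F_y2 = NA_real_,
         plateau_forces = c(plateau2, NA_real_),
         sse = sum(ft$residuals^2), coef = unname(ft$coefficients),
         flags = flags, rate = curve$rate, n = n),
    class = "regime_fit"
  )
}

interior_slope <- function(d, f, in_seg, buffer, d_min = -Inf) {
  idx <- which(in_seg)
  if (length(idx) <= 2L * buffer + 1L) buffer <- 0L
  idx <- idx[(1L + buffer):(length(idx) - buffer)]
  idx <- idx[d[idx] >= d_min]
  if (length(idx) < 2L) return(NA_real_)
  x <- d[idx]; y <- f[idx]
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

interior_mean <- function(f, in_seg, buffer) {
  idx <- which(in_seg)
  if (length(idx) <= 2L * buffer + 1L) buffer <- 0L
  idx <- idx[(1L + buffer):(length(idx) - buffer)]
  mean(f[idx])
}
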