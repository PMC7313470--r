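#' Regime parameters for a synthetic force-distance experiment
#'
#' Bundle of the piecewise parameters that define the mean (noise-free)
#' force-distance response of a stretched tissue sample: a nonlinear toe
#' region, a first linear rise with slope `k1` up to the first yield force
#' `F_y1`, a constant-force plateau of length `plateau2_len`, a second
#' steeper linear rise with slope `k3` up to `F_y2`, and a final
#' constant-force plateau out to `d_max`.
#'
#' @param rate displacement rate \[m/s\]
#' @param toe_end displacement at which the response becomes linear \[m\]
#' @param k1 slope of the first linear regime \[N/m\]
#' @param F_y1 first yield force (level of the first plateau) \[N\]
#' @param plateau2_len length of the first constant-force plateau \[m\]
#' @param k3 slope of the second linear regime \[N/m\]; must exceed `k1`
#' @param F_y2 second yield force (level of the final plateau) \[N\]
#' @param d_max total displacement of the experiment \[m\]
#' @param invented_default logical; `TRUE` when some fields were filled with
#'   package defaults rather than taken from measured presets
#' @param extrapolated logical; `TRUE` when the preset was interpolated or
#'   extrapolated to a rate without a measured preset
#'
#' @return An object of class `regime_params`.
#' @seealso [make_rate_preset()], [generate_fd_curve()]
#' @export
regime_params <- function(rate, toe_end, k1, F_y1, plateau2_len, k3, F_y2,
                          d_max, invented_default = FALSE,
                          extrapolated = FALSE) {
  vals <- c(rate = rate, toe_end = toe_end, k1 = k1, F_y1 = F_y1,
            plateau2_len = plateau2_len, k3 = k3, F_y2 = F_y2, d_max = d_max)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all regime parameters must be finite and positive", call. = FALSE)
  }
  if (k3 <= k1) {
    stop("k3 must exceed k1 (the second rise is steeper than the first)",
         call. = FALSE)
  }
  if (F_y2 <= F_y1) {
    stop("F_y2 must exceed F_y1", call. = FALSE)
  }
  ## end of regime 1 (and beyond) must fit inside the experiment
  d_regime1_end <- toe_end + (F_y1 - toe_force(toe_end, k1, toe_end)) / k1
  if (d_regime1_end >= d_max) {
    stop("regime 1 ends beyond d_max; parameters inconsistent", call. = FALSE)
  }
  structure(
    list(rate = rate, toe_end = toe_end, k1 = k1, F_y1 = F_y1,
         plateau2_len = plateau2_len, k3 = k3, F_y2 = F_y2, d_max = d_max,
         invented_default = isTRUE(invented_default),
         extrapolated = isTRUE(extrapolated)),
    class = "regime_params"
  )
}

#' @export
print.regime_params <- function(x, ...) {
  cat("Regime parameters (rate ", format(x$rate * 1e6), " um/s)\n", sep = "")
  cat(sprintf("  toe end        : %.4g mm\n", x$toe_end * 1e3))
  cat(sprintf("  k1 / k3        : %.4g / %.4g N/m\n", x$k1, x$k3))
  cat(sprintf("  F_y1 / F_y2    : %.4g / %.4g mN\n", x$F_y1 * 1e3, x$F_y2 * 1e3))
  cat(sprintf("  plateau 2 len  : %.4g mm, d_max %.4g mm\n",
              x$plateau2_len * 1e3, x$d_max * 1e3))
  if (x$invented_default) cat("  (some fields are package defaults)\n")
  if (x$extrapolated) cat("  (interpolated/extrapolated rate)\n")
  invisible(x)
}

## Measured regime-1 anchors: elastic constant and first yield force at the
## slowest and fastest displacement rates. Slower pulling stiffens the
## response (non-Newtonian, friction-dominated behaviour of layered tissue).
.preset_anchor <- list(
  slow = list(rate = 0.1e-6, k1 = 33.5, F_y1 = 2.2e-3),
  fast = list(rate = 2.0e-6, k1 = 21.5, F_y1 = 1.5e-3)
)

#' Rate presets for synthetic force-distance curves
#'
#' Returns the regime parameters used to emulate a stretching experiment at a
#' given displacement rate. The regime-1 elastic constant and first yield
#' force at 0.1 and 2.0 um/s are the measured anchors (33.5 N/m, 2.2 mN and
#' 21.5 N/m, 1.5 mN respectively); other rates are linearly interpolated
#' between them (extrapolated and flagged beyond the anchors). Fields never
#' reported by the measurements take package defaults: `k3 = 2 k1`,
#' `F_y2 = 2.5 F_y1`, `d_max` = 1 mm, toe end 0.01 mm, first plateau length
#' 200 um; such presets carry `invented_default = TRUE`.
#'
#' @param rate displacement rate in um/s (e.g. 0.1, 0.5 or 2.0)
#' @return A [regime_params] object.
#' @examples
#' make_rate_preset(2.0)$k1   # 21.5 N/m
#' make_rate_preset(0.1)$F_y1 # 2.2 mN
#' @export
make_rate_preset <- function(rate) {
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    stop("rate must be a single positive number (um/s)", call. = FALSE)
  }
  rate_ms <- rate * 1e-6
  a <- .preset_anchor$slow
  b <- .preset_anchor$fast
  frac <- (rate_ms - a$rate) / (b$rate - a$rate)
  k1 <- a$k1 + frac * (b$k1 - a$k1)
  F_y1 <- a$F_y1 + frac * (b$F_y1 - a$F_y1)
  extrapolated <- frac < 0 || frac > 1
  if (k1 <= 0 || F_y1 <= 0) {
    stop("rate too far outside the measured range: extrapolated preset ",
         "would be non-physical", call. = FALSE)
  }
  regime_params(
    rate = rate_ms,
    toe_end = 0.01e-3,          # linearity starts at 0.01 mm
    k1 = k1,
    F_y1 = F_y1,
    plateau2_len = 200e-6,      # first plateau spans ~200 um
    k3 = 2 * k1,                # default: second rise twice as steep
    F_y2 = 2.5 * F_y1,          # default: final plateau at 2.5x first yield
    d_max = 1e-3,               # motor travel up to 1 mm
    invented_default = TRUE,
    extrapolated = extrapolated
  )
}

## Toe model: the unique cubic through (0,0) with zero initial slope whose
## slope and curvature match the regime-1 line at toe_end (C2 junction):
## f(d) = k1 d^2 / T - k1 d^3 / (3 T^2), so f(T) = (2/3) k1 T.
toe_force <- function(d, k1, toe_end) {
  k1 * d^2 / toe_end - k1 * d^3 / (3 * toe_end^2)
}

#' Breakpoints of the noise-free piecewise response
#'
#' Displacements at the four transitions toe->1, 1->2, 2->3 and 3->4 implied
#' by a set of regime parameters.
#'
#' @param params a [regime_params] object
#' @return Numeric vector of four strictly increasing displacements \[m\].
#' @export
regime_breakpoints <- function(params) {
  stopifnot(inherits(params, "regime_params"))
  f_toe <- toe_force(params$toe_end, params$k1, params$toe_end)
  b1 <- params$toe_end
  b2 <- b1 + (params$F_y1 - f_toe) / params$k1
  b3 <- b2 + params$plateau2_len
  b4 <- b3 + (params$F_y2 - params$F_y1) / params$k3
  if (b4 >= params$d_max) {
    stop("regime 4 starts beyond d_max; parameters inconsistent", call. = FALSE)
  }
  c(b1, b2, b3, b4)
}

#' Noise-free force of the piecewise regime model
#'
#' Evaluates the mean force-distance response defined by `params` at given
#' displacements: cubic toe, linear rise `k1`, plateau at `F_y1`, linear rise
#' `k3`, plateau at `F_y2`. Continuous everywhere and zero at zero
#' displacement.
#'
#' @param d displacements \[m\]
#' @param params a [regime_params] object
#' @return Forces \[N\], same length as `d`.
#' @export
regime_force <- function(d, params) {
  stopifnot(inherits(params, "regime_params"))
  b <- regime_breakpoints(params)
  f_toe <- toe_force(params$toe_end, params$k1, params$toe_end)
  f <- numeric(length(d))
  i <- d <= b[1]
  f[i] <- toe_force(pmax(d[i], 0), params$k1, params$toe_end)
  i <- d > b[1] & d <= b[2]
  f[i] <- f_toe + params$k1 * (d[i] - b[1])
  i <- d > b[2] & d <= b[3]
  f[i] <- params$F_y1
  i <- d > b[3] & d <= b[4]
  f[i] <- params$F_y1 + params$k3 * (d[i] - b[3])
  i <- d > b[4]
  f[i] <- params$F_y2
  f
}

#' Generate a synthetic force-distance curve
#'
#' Samples the noise-free piecewise response on a uniform displacement grid
#' over \[0, `d_max`\] and adds zero-mean Gaussian noise to the force channel.
#' Output is reproducible: the same `(params, n_points, noise_sd, seed)`
#' always yields the identical curve.
#'
#' @param params a [regime_params] object
#' @param n_points number of samples (>= 50)
#' @param noise_sd standard deviation of the additive force noise \[N\];
#'   default 0.02 mN, the scale of the sensor noise
#' @param seed integer seed (mandatory; no hidden global RNG state is used)
#' @return An [fd_curve] with provenance `"synthetic"`.
#' @examples
#' crv <- generate_fd_curve(make_rate_preset(2.0), n_points = 200, seed = 1)
#' @export
generate_fd_curve <- function(params, n_points = 1000L, noise_sd = 0.02e-3,
                              seed) {
  stopifnot(inherits(params, "regime_params"))
  if (missing(seed)) stop("seed is a mandatory argument", call. = FALSE)
  n_points <- as.integer(n_points)
  if (n_points < 50L) stop("n_points must be at least 50", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be non-negative", call. = FALSE)
  }
  d <- seq(0, params$d_max, length.out = n_points)
  f <- regime_force(d, params)
  if (noise_sd > 0) {
    f <- f + with_seed(seed, stats::rnorm(n_points, 0, noise_sd))
  }
  fd_curve(d, f, rate = params$rate, provenance = "synthetic",
           meta = list(seed = as.integer(seed), noise_sd = noise_sd,
                       params = params))
}

#' Calibration table of a Hookean force sensor
#'
#' Paired (mass, extension) records from hanging known masses off the sensor
#' fiber. For synthetic tables the generating spring constant is carried in
#' `k_true`.
#'
#' @param mass masses \[kg\], strictly positive (a zero mass is allowed as an
#'   explicit tare record)
#' @param extension fiber extensions \[m\], non-negative up to noise
#' @param k_true generating spring constant \[N/m\] or `NA` for measured data
#' @return An object of class `calibration_table` (also a data.frame).
#' @export
calibration_table <- function(mass, extension, k_true = NA_real_) {
  if (length(mass) != length(extension)) {
    stop("mass and extension must have equal length", call. = FALSE)
  }
  if (any(mass < 0)) stop("masses must be non-negative", call. = FALSE)
  out <- data.frame(mass_kg = as.numeric(mass),
                    extension_m = as.numeric(extension))
  attr(out, "k_true") <- k_true
  class(out) <- c("calibration_table", "data.frame")
  out
}

#' Generate a synthetic sensor-calibration table
#'
#' Emulates the calibration of the glass-fiber force sensor: known brass
#' masses are added and the fiber extension recorded. The noise-free relation
#' is Hooke's law against the gravitational load,
#' `extension = mass * g / k_true` with g = 9.81 m/s^2; Gaussian noise of
#' standard deviation `noise_sd` is added to the extension channel.
#'
#' @param k_true true spring constant \[N/m\]; default 54.96, the calibrated
#'   value of the sensor this package models
#' @param masses masses \[kg\]; default 10 values evenly spanning 150-2200 mg
#' @param noise_sd extension noise standard deviation \[m\]
#' @param seed integer seed (mandatory)
#' @return A [calibration_table] with `k_true` recorded.
#' @examples
#' tab <- generate_calibration_table(noise_sd = 0, seed = 1)
#' @export
generate_calibration_table <- function(k_true = 54.96,
                                       masses = default_calibration_masses(),
                                       noise_sd = 0, seed) {
  if (missing(seed)) stop("seed is a mandatory argument", call. = FALSE)
  if (!is.numeric(k_true) || length(k_true) != 1L || !is.finite(k_true) ||
      k_true <= 0) {
    stop("k_true must be a single positive number", call. = FALSE)
  }
  if (any(masses < 0)) stop("masses must be non-negative", call. = FALSE)
  ext <- masses * .g_std / k_true
  if (noise_sd > 0) {
    ext <- ext + with_seed(seed, stats::rnorm(length(masses), 0, noise_sd))
  }
  calibration_table(masses, ext, k_true = k_true)
}

#' Default calibration mass grid
#'
#' @param n number of masses
#' @return Masses \[kg\] evenly spanning 150-2200 mg, the range of the brass
#'   calibration wires.
#' @export
default_calibration_masses <- function(n = 10L) {
  seq(150e-6, 2200e-6, length.out = n) # kg: 150 mg .. 2200 mg
}

## standard gravity used throughout the calibration relation F = m g
.g_std <- 9.81

## Run code with a local, restored RNG state so generators never disturb the
## caller's random stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
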