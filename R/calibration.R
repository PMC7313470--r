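#' Force-distance curve
#'
#' The central measured object of a stretching experiment: motor displacement
#' (the "distance" of the experiment) paired with the force read off the
#' calibrated fiber sensor, plus the displacement rate at which the motor
#' moved.
#'
#' @param displacement motor travel \[m\]; strictly increasing from 0
#' @param force sensor force \[N\]
#' @param rate displacement rate \[m/s\]
#' @param provenance `"synthetic"` or `"measured"`
#' @param meta optional list of metadata (seed, noise level, generator
#'   parameters, source file, ...)
#' @return An object of class `fd_curve`.
#' @export
fd_curve <- function(displacement, force, rate,
                     provenance = c("measured", "synthetic"), meta = list()) {
  provenance <- match.arg(provenance)
  displacement <- as.numeric(displacement)
  force <- as.numeric(force)
  if (length(displacement) != length(force)) {
    stop("displacement and force must have equal length", call. = FALSE)
  }
  if (length(displacement) < 2L) {
    stop("an fd_curve needs at least 2 samples", call. = FALSE)
  }
  if (displacement[1] != 0) {
    stop("displacement must start at 0 (subtract the initial motor position)",
         call. = FALSE)
  }
  if (any(diff(displacement) <= 0)) {
    stop("displacement must be strictly increasing", call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    stop("rate must be a single positive number (m/s)", call. = FALSE)
  }
  structure(
    list(displacement = displacement, force = force, rate = rate,
         provenance = provenance, meta = meta),
    class = "fd_curve"
  )
}

#' @export
print.fd_curve <- function(x, ...) {
  cat(sprintf(
    "Force-distance curve (%s): %d samples, rate %.3g um/s\n",
    x$provenance, length(x$displacement), x$rate * 1e6))
  cat(sprintf("  displacement 0 .. %.4g mm, force %.4g .. %.4g mN\n",
              max(x$displacement) * 1e3, min(x$force) * 1e3,
              max(x$force) * 1e3))
  invisible(x)
}

#' @export
as.data.frame.fd_curve <- function(x, ...) {
  data.frame(displacement_m = x$displacement, force_N = x$force)
}

#' Calibrated spring model of the glass-fiber force sensor
#'
#' @param k spring constant \[N/m\]
#' @param k_se standard error of `k` \[N/m\]
#' @param intercept fitted force offset \[N\] (calibration diagnostic only;
#'   never applied when converting extensions to forces)
#' @param n number of calibration points used in the fit
#' @return An object of class `spring_model`.
#' @export
spring_model <- function(k, k_se, intercept, n) {
  if (!is.finite(k) || k <= 0) stop("k must be positive", call. = FALSE)
  if (!is.finite(k_se) || k_se < 0) stop("k_se must be >= 0", call. = FALSE)
  n <- as.integer(n)
  if (n < 2L) stop("a spring model needs n >= 2 points", call. = FALSE)
  structure(list(k = k, k_se = k_se, intercept = intercept, n = n),
            class = "spring_model")
}

#' @export
print.spring_model <- function(x, ...) {
  cat(sprintf("Spring model: k = %.4g +/- %.2g N/m (n = %d, intercept %.3g mN)\n",
              x$k, x$k_se, x$n, x$intercept * 1e3))
  invisible(x)
}

#' Fit the sensor spring constant from a calibration table
#'
#' Ordinary least squares of the gravitational load `F = m g` (g = 9.81
#' m/s^2) against the measured fiber extension, with a free intercept. The
#' slope is the spring constant; the intercept is retained only as a
#' diagnostic for a constant tracking offset and is never applied when
#' converting extensions to forces.
#'
#' @param table a [calibration_table] (or data.frame with columns `mass_kg`,
#'   `extension_m`)
#' @return A [spring_model].
#' @examples
#' tab <- generate_calibration_table(k_true = 54.96, noise_sd = 0, seed = 1)
#' fit_spring_constant(tab)$k  # 54.96, recovered exactly
#' @export
fit_spring_constant <- function(table) {
  if (!all(c("mass_kg", "extension_m") %in% names(table))) {
    stop("table needs columns mass_kg and extension_m", call. = FALSE)
  }
  x <- table$extension_m
  y <- table$mass_kg * .g_std
  if (length(x) < 2L || length(unique(x)) < 2L) {
    stop("degenerate calibration fit: need at least 2 distinct extensions",
         call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  k <- unname(fit$coefficients[2])
  if (!is.finite(k) || k <= 0) {
    stop("calibration failure: fitted slope is not positive", call. = FALSE)
  }
  n <- length(x)
  rss <- sum(fit$residuals^2)
  sxx <- sum((x - mean(x))^2)
  k_se <- if (n > 2L) sqrt(rss / (n - 2L) / sxx) else 0
  spring_model(k = k, k_se = k_se, intercept = unname(fit$coefficients[1]),
               n = n)
}

#' Convert fiber extensions to forces via Hooke's law
#'
#' `force = k * extension`. The calibration intercept is intentionally not
#' applied: it is a diagnostic of the calibration, not part of the sensor
#' response. Negative extensions yield negative forces (compression of the
#' fiber pair) and are passed through unchanged.
#'
#' @param extension fiber extensions \[m\]
#' @param model a [spring_model]
#' @return Forces \[N\].
#' @export
extension_to_force <- function(extension, model) {
  stopifnot(inherits(model, "spring_model"))
  model$k * as.numeric(extension)
}

#' Assemble a force-distance curve from raw position series
#'
#' Takes the motor position series and the tracked sensor-dot position
#' series, converts the dot displacement (fiber extension) to force through
#' the calibrated spring model, and references both series to their first
#' sample. By convention the curve's distance axis is the motor travel; the
#' sensor-deflection-corrected scaffold gap (`motor - extension`) is kept as
#' an auxiliary column in `meta$gap_m` for downstream use.
#'
#' @param motor_positions motor positions \[m\], non-decreasing
#' @param dot_positions tracked dot positions \[m\], same length
#' @param model a [spring_model]
#' @param rate displacement rate \[m/s\]
#' @param provenance passed to [fd_curve()]
#' @return An [fd_curve].
#' @export
assemble_fd_curve <- function(motor_positions, dot_positions, model, rate,
                              provenance = "measured") {
  if (length(motor_positions) != length(dot_positions)) {
    stop("motor and dot position series must have equal length", call. = FALSE)
  }
  if (length(motor_positions) < 2L) {
    stop("need at least 2 samples to assemble a curve", call. = FALSE)
  }
  if (any(diff(motor_positions) < 0)) {
    stop("motor positions must be non-decreasing", call. = FALSE)
  }
  displacement <- motor_positions - motor_positions[1]
  extension <- dot_positions - dot_positions[1]
  force <- extension_to_force(extension, model)
  ## duplicate motor positions (motor at rest) cannot enter the strictly
  ## increasing distance axis; drop repeats, keeping the last reading
  keep <- c(diff(displacement) > 0, TRUE)
  fd_curve(displacement[keep], force[keep], rate = rate,
           provenance = provenance,
           meta = list(gap_m = (displacement - extension)[keep]))
}

## ---- file formats ---------------------------------------------------------

#' Read and write force-distance curves as CSV
#'
#' Curves are stored as two-column CSV (`displacement_m,force_N`, '.'
#' decimal separator) with metadata (rate, provenance, generator seed) in a
#' sidecar JSON file `<path>.json`.
#'
#' @param curve an [fd_curve]
#' @param path CSV file path
#' @return `write_fd_curve` returns `path` invisibly; `read_fd_curve`
#'   returns an [fd_curve].
#' @export
write_fd_curve <- function(curve, path) {
  stopifnot(inherits(curve, "fd_curve"))
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE,
                   quote = FALSE)
  meta <- list(rate_m_s = curve$rate, provenance = curve$provenance)
  if (!is.null(curve$meta$seed)) meta$seed <- curve$meta$seed
  if (!is.null(curve$meta$noise_sd)) meta$noise_sd_N <- curve$meta$noise_sd
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_fd_curve
#' @param rate displacement rate \[m/s\]; overrides the sidecar value if given
#' @export
read_fd_curve <- function(path, rate = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("displacement_m", "force_N") %in% names(df))) {
    stop("FD curve CSV needs columns displacement_m and force_N",
         call. = FALSE)
  }
  provenance <- "measured"
  sidecar <- paste0(path, ".json")
  if (is.null(rate) && file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    rate <- meta$rate_m_s
    if (!is.null(meta$provenance)) provenance <- meta$provenance
  }
  if (is.null(rate)) {
    stop("no rate given and no sidecar JSON found for ", path, call. = FALSE)
  }
  fd_curve(df$displacement_m, df$force_N, rate = as.numeric(rate),
           provenance = provenance, meta = list(source = path))
}

#' Read and write calibration tables as CSV
#'
#' Stored as two-column CSV with header `mass_kg,extension_m`.
#'
#' @param table a [calibration_table]
#' @param path CSV file path
#' @return `write_calibration_table` returns `path` invisibly;
#'   `read_calibration_table` returns a [calibration_table].
#' @export
write_calibration_table <- function(table, path) {
  utils::write.csv(table[, c("mass_kg", "extension_m")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_calibration_table
#' @export
read_calibration_table <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("mass_kg", "extension_m") %in% names(df))) {
    stop("calibration CSV needs columns mass_kg and extension_m",
         call. = FALSE)
  }
  calibration_table(df$mass_kg, df$extension_m)
}

#' Serialize a spring model to JSON
#'
#' @param model a [spring_model]
#' @param path JSON file path
#' @return `write_spring_model` returns `path` invisibly; `read_spring_model`
#'   returns a [spring_model].
#' @export
write_spring_model <- function(model, path) {
  stopifnot(inherits(model, "spring_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spring_model
#' @export
read_spring_model <- function(path) {
  x <- jsonlite::read_json(path)
  spring_model(k = x$k, k_se = x$k_se, intercept = x$intercept, n = x$n)
}
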