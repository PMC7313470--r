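#' Pipeline configuration
#'
#' Settings for an end-to-end run: sensor calibration, force-distance curve
#' acquisition (synthetic generation or CSV ingestion), regime segmentation,
#' replicate summaries and inverse modulus identification.
#'
#' @param mode `"synthetic"` (curves are generated) or `"measured"` (curves
#'   are read from `curve_files`)
#' @param rates displacement rates \[um/s\]
#' @param replicates number of replicate curves per rate (synthetic mode);
#'   the experimental campaign used 5 replicates at 0.1 um/s and 3 at the
#'   two faster rates
#' @param n_points samples per synthetic curve
#' @param noise_sd force noise \[N\] for synthetic curves
#' @param cal_noise_sd extension noise \[m\] for the synthetic calibration
#'   table
#' @param k_true generating spring constant \[N/m\] (synthetic mode)
#' @param seed integer master seed; per-curve seeds are derived from it
#' @param stretcher a [stretcher_config]
#' @param segmentation a [segment_options()] list
#' @param resolution FE mesh density for the inversions
#' @param tol inversion tolerance
#' @param curve_files measured mode: named list mapping each rate (as
#'   character, in um/s) to a vector of FD-curve CSV paths
#' @param calibration_file measured mode: calibration table CSV
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "measured"),
                            rates = c(0.1, 0.5, 2.0),
                            replicates = c(5, 3, 3),
                            n_points = 1000L, noise_sd = 0.02e-3,
                            cal_noise_sd = 2e-6, k_true = 54.96,
                            seed, stretcher = stretcher_config(),
                            segmentation = segment_options(),
                            resolution = 2, tol = 1e-3,
                            curve_files = NULL, calibration_file = NULL) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("seed is a mandatory argument", call. = FALSE)
  if (length(replicates) == 1L) replicates <- rep(replicates, length(rates))
  if (length(replicates) != length(rates)) {
    stop("replicates must match rates in length", call. = FALSE)
  }
  if (any(replicates < 1L)) stop("replicates must be >= 1", call. = FALSE)
  if (mode == "measured") {
    files <- unlist(c(curve_files, calibration_file))
    if (is.null(files) || !length(files)) {
      stop("measured mode needs curve_files (and a calibration_file)",
           call. = FALSE)
    }
    missing_files <- files[!file.exists(files)]
    if (length(missing_files)) {
      stop("missing input file(s): ", paste(missing_files, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(
    list(mode = mode, rates = rates, replicates = as.integer(replicates),
         n_points = as.integer(n_points), noise_sd = noise_sd,
         cal_noise_sd = cal_noise_sd, k_true = k_true,
         seed = as.integer(seed), stretcher = stretcher,
         segmentation = segmentation, resolution = resolution, tol = tol,
         curve_files = curve_files, calibration_file = calibration_file),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes calibrate -> acquire/generate -> segment -> summarize -> invert
#' and writes all intermediate artifacts plus a JSON report to `out_dir`.
#' Deterministic for a fixed `(config, seed)`: per-curve seeds are derived
#' as `seed * 1000 + curve index`, and no stage touches the global RNG.
#'
#' @param config a [pipeline_config]
#' @param out_dir output directory (created if needed)
#' @return The report, an object of class `pipeline_report`, invisibly
#'   written to `out_dir/report.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(stage, ...) {
    message(sprintf("[retmech] %-10s %s", stage, sprintf(...)))
  }

  ## stage 1: sensor calibration
  t0 <- proc.time()[["elapsed"]]
  cal <- tryCatch({
    if (config$mode == "synthetic") {
      generate_calibration_table(k_true = config$k_true,
                                 noise_sd = config$cal_noise_sd,
                                 seed = config$seed)
    } else {
      read_calibration_table(config$calibration_file)
    }
  }, error = function(e) stop("stage 'calibrate' failed: ",
                              conditionMessage(e), call. = FALSE))
  spring <- fit_spring_constant(cal)
  write_calibration_table(cal, file.path(out_dir, "calibration.csv"))
  write_spring_model(spring, file.path(out_dir, "spring_model.json"))
  log_stage("calibrate", "k = %.4g N/m (%.1fs)", spring$k,
            proc.time()[["elapsed"]] - t0)

  ## stage 2: curves
  curves <- list()
  curve_id <- 0L
  for (i in seq_along(config$rates)) {
    rate <- config$rates[i]
    per_rate <- list()
    for (j in seq_len(config$replicates[i])) {
      curve_id <- curve_id + 1L
      crv <- tryCatch({
        if (config$mode == "synthetic") {
          generate_fd_curve(make_rate_preset(rate),
                            n_points = config$n_points,
                            noise_sd = config$noise_sd,
                            seed = config$seed * 1000L + curve_id)
        } else {
          read_fd_curve(config$curve_files[[as.character(rate)]][j])
        }
      }, error = function(e) stop("stage 'curves' failed (rate ", rate,
                                  ", replicate ", j, "): ",
                                  conditionMessage(e), call. = FALSE))
      write_fd_curve(crv, file.path(out_dir,
                                    sprintf("curve_rate%s_rep%d.csv",
                                            format(rate), j)))
      per_rate[[j]] <- crv
    }
    curves[[as.character(rate)]] <- per_rate
  }
  log_stage("curves", "%d curves over %d rate(s)", curve_id,
            length(config$rates))

  ## stage 3: segmentation + replicate summaries
  t0 <- proc.time()[["elapsed"]]
  fits <- list()
  summaries <- list()
  for (rate in names(curves)) {
    fr <- lapply(curves[[rate]], function(crv) {
      tryCatch(segment_regimes(crv, config$segmentation),
               error = function(e) stop("stage 'segment' failed (rate ",
                                        rate, "): ", conditionMessage(e),
                                        call. = FALSE))
    })
    fits[[rate]] <- fr
    summaries[[rate]] <- summarize_replicates(fr, as.numeric(rate) * 1e-6)
  }
  log_stage("segment", "mean k1 per rate: %s N/m (%.1fs)",
            paste(vapply(summaries, function(s) sprintf("%.3g", s$mean["k1"]),
                         character(1)), collapse = ", "),
            proc.time()[["elapsed"]] - t0)

  ## stage 4: inverse identification
  t0 <- proc.time()[["elapsed"]]
  rate_table <- tryCatch(
    modulus_rate_table(unname(summaries), config$stretcher,
                       resolution = config$resolution, tol = config$tol),
    error = function(e) stop("stage 'invert' failed: ", conditionMessage(e),
                             call. = FALSE))
  write_rate_table(rate_table, file.path(out_dir, "modulus_rate_table.csv"))
  log_stage("invert", "E per rate: %s Pa (%.1fs)",
            paste(sprintf("%.4g", rate_table$E_Pa), collapse = ", "),
            proc.time()[["elapsed"]] - t0)

  ## report
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(serialize_config(config), cfg_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report <- list(
    schema_version = "1.0",
    package_version = as.character(utils::packageVersion("retmech")),
    config_hash = unname(tools::md5sum(cfg_path)),
    spring_model = unclass(spring),
    regime_fits = lapply(fits, function(fr) lapply(fr, regime_fit_record)),
    replicate_summaries = lapply(summaries, function(s) {
      list(rate_um_s = s$rate * 1e6, n = s$n,
           mean = as.list(s$mean), sd = as.list(s$sd))
    }),
    modulus_rate_table = rate_table[, c("rate_um_s", "k1_N_m", "E_Pa")]
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  class(report) <- "pipeline_report"
  invisible(report)
}

regime_fit_record <- function(fit) {
  list(breakpoints_m = fit$breakpoints, k1_N_m = fit$k1, k3_N_m = fit$k3,
       F_y1_N = fit$F_y1, F_y2_N = fit$F_y2,
       plateau_forces_N = fit$plateau_forces, sse = fit$sse,
       flags = fit$flags)
}

serialize_config <- function(config) {
  out <- unclass(config)
  out$stretcher <- unclass(out$stretcher)
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report (schema", x$schema_version, ")\n")
  cat(sprintf("  spring k = %.4g N/m\n", x$spring_model$k))
  tab <- x$modulus_rate_table
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  rate %.3g um/s: k1 = %.4g N/m -> E = %.4g Pa\n",
                tab$rate_um_s[i], tab$k1_N_m[i], tab$E_Pa[i]))
  }
  invisible(x)
}

#' Read a pipeline configuration from YAML
#'
#' Maps a flat YAML document onto [pipeline_config()]; the `stretcher` block
#' is passed to [stretcher_config()] and `segmentation` to
#' [segment_options()].
#'
#' @param path YAML file
#' @return A [pipeline_config].
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$stretcher)) x$stretcher <- do.call(stretcher_config, x$stretcher)
  if (!is.null(x$segmentation)) x$segmentation <- do.call(segment_options, x$segmentation)
  do.call(pipeline_config, x)
}
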