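test_that("noiseless calibration recovers the spring constant exactly", {
  tab <- generate_calibration_table(k_true = 54.96, noise_sd = 0, seed = 1)
  fit <- fit_spring_constant(tab)
  expect_equal(fit$k, 54.96, tolerance = 1e-10)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$n, 10L)
})

test_that("two exact points give the hand-computed slope", {
  m <- c(150e-6, 2200e-6)
  x <- m * G_STD / 54.96
  fit <- fit_spring_constant(calibration_table(m, x))
  expect_equal(fit$k, G_STD * diff(m) / diff(x), tolerance = 1e-12)
  expect_equal(fit$k, 54.96, tolerance = 1e-10)
})

test_that("the fitted k is invariant under record reordering", {
  tab <- generate_calibration_table(noise_sd = 2e-6, seed = 3)
  perm <- c(7, 2, 9, 1, 10, 4, 6, 3, 8, 5)
  tab2 <- calibration_table(tab$mass_kg[perm], tab$extension_m[perm])
  expect_equal(fit_spring_constant(tab2)$k, fit_spring_constant(tab)$k,
               tolerance = 1e-12)
})

test_that("calibration is unbiased under realistic noise (Monte Carlo)", {
  ks <- vapply(1:500, function(s) {
    fit_spring_constant(
      generate_calibration_table(k_true = 54.96, noise_sd = 2e-6,
                                 seed = s))$k
  }, numeric(1))
  expect_lt(abs(mean(ks) - 54.96) / 54.96, 0.01)
  ## the reported standard error is the right scale
  expect_lt(abs(sd(ks) / mean(ks) - 0.01), 0.02)
})

test_that("degenerate calibration inputs raise calibration errors", {
  expect_error(fit_spring_constant(calibration_table(c(1e-3, 2e-3),
                                                     c(1e-4, 1e-4))),
               "degenerate")
  ## negative slope: extension decreasing with mass
  expect_error(fit_spring_constant(calibration_table(c(1e-3, 2e-3),
                                                     c(2e-4, 1e-4))),
               "slope")
  expect_error(fit_spring_constant(data.frame(a = 1)), "columns")
})

test_that("extension-to-force is pure Hooke with no intercept applied", {
  model <- spring_model(k = 54.96, k_se = 0.52, intercept = 1e-5, n = 10)
  expect_equal(extension_to_force(0, model), 0)
  ## hand value: 27.29 um at 54.96 N/m is 1.50 mN
  expect_equal(extension_to_force(27.29e-6, model), 1.4999e-3,
               tolerance = 1e-4)
  x <- c(1e-5, 2e-5, -1e-5)
  expect_equal(extension_to_force(2 * x, model),
               2 * extension_to_force(x, model))
})

test_that("curve assembly reconstructs force from dot tracking", {
  model <- spring_model(k = 54.96, k_se = 0, intercept = 0, n = 10)
  ## constant dot position: no fiber extension, all forces zero
  motor <- seq(0, 1e-4, length.out = 20)
  crv <- assemble_fd_curve(motor, rep(0.5e-3, 20), model, rate = 2e-6)
  expect_true(all(crv$force == 0))
  expect_equal(crv$displacement, motor)

  ## round trip: a dot series equal to F/k reproduces a synthetic curve
  p <- make_rate_preset(2.0)
  ref <- generate_fd_curve(p, 200, 0, seed = 1)
  dots <- 0.2e-3 + ref$force / model$k
  got <- assemble_fd_curve(0.01 + ref$displacement, dots, model,
                           rate = p$rate)
  expect_equal(got$displacement, ref$displacement, tolerance = 1e-9)
  expect_equal(got$force, ref$force, tolerance = 1e-12)
  ## the sensor-corrected gap column is displacement minus extension
  expect_equal(got$meta$gap_m, ref$displacement - ref$force / model$k,
               tolerance = 1e-12)

  expect_error(assemble_fd_curve(1:3 * 1e-5, 1:4 * 1e-5, model, 2e-6),
               "equal length")
  expect_error(assemble_fd_curve(1e-5, 1e-5, model, 2e-6), "2 samples")
  expect_error(assemble_fd_curve(c(1e-5, 0.5e-5), c(0, 0), model, 2e-6),
               "non-decreasing")
})

test_that("file round trips preserve curves, tables and spring models", {
  tmp <- withr::local_tempdir()
  p <- make_rate_preset(0.5)
  crv <- generate_fd_curve(p, 120, 1e-5, seed = 5)
  path <- file.path(tmp, "curve.csv")
  write_fd_curve(crv, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_fd_curve(path)
  expect_equal(back$displacement, crv$displacement, tolerance = 1e-12)
  expect_equal(back$force, crv$force, tolerance = 1e-12)
  expect_equal(back$rate, crv$rate)
  expect_equal(back$provenance, "synthetic")

  tab <- generate_calibration_table(noise_sd = 1e-6, seed = 2)
  tpath <- file.path(tmp, "cal.csv")
  write_calibration_table(tab, tpath)
  tback <- read_calibration_table(tpath)
  expect_equal(tback$mass_kg, tab$mass_kg, tolerance = 1e-12)
  expect_equal(tback$extension_m, tab$extension_m, tolerance = 1e-12)

  sm <- fit_spring_constant(tab)
  spath <- file.path(tmp, "spring.json")
  write_spring_model(sm, spath)
  sback <- read_spring_model(spath)
  expect_equal(sback$k, sm$k, tolerance = 1e-12)
  expect_equal(sback$n, sm$n)
})
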