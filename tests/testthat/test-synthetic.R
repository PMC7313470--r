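test_that("rate presets carry the measured anchors and documented defaults", {
  fast <- make_rate_preset(2.0)
  expect_equal(fast$k1, 21.5)
  expect_equal(fast$F_y1, 1.5e-3)
  slow <- make_rate_preset(0.1)
  expect_equal(slow$k1, 33.5)
  expect_equal(slow$F_y1, 2.2e-3)
  for (p in list(fast, slow, make_rate_preset(0.5))) {
    expect_equal(p$toe_end, 0.01e-3)
    expect_equal(p$plateau2_len, 200e-6)
    expect_equal(p$d_max, 1e-3)
    expect_equal(p$k3, 2 * p$k1)
    expect_equal(p$F_y2, 2.5 * p$F_y1)
    expect_true(p$invented_default)
  }
  ## intermediate rates interpolate linearly between the anchors
  mid <- make_rate_preset(0.5)
  frac <- (0.5 - 0.1) / (2.0 - 0.1)
  expect_equal(mid$k1, 33.5 + frac * (21.5 - 33.5))
  expect_false(mid$extrapolated)
  expect_true(make_rate_preset(3.0)$extrapolated)
  expect_error(make_rate_preset(0), "positive")
  expect_error(make_rate_preset(-1), "positive")
})

test_that("regime parameter invariants are enforced", {
  expect_error(regime_params(2e-6, 1e-5, 21.5, 1.5e-3, 2e-4,
                             k3 = 20, F_y2 = 3e-3, d_max = 1e-3), "k3")
  expect_error(regime_params(2e-6, 1e-5, 21.5, 1.5e-3, 2e-4,
                             k3 = 43, F_y2 = 1e-3, d_max = 1e-3), "F_y2")
  expect_error(regime_params(2e-6, 1e-5, -21.5, 1.5e-3, 2e-4,
                             k3 = 43, F_y2 = 3.75e-3, d_max = 1e-3),
               "positive")
})

test_that("the noise-free piecewise response has the stated closed form", {
  p <- make_rate_preset(2.0)
  ## anchored origin
  expect_equal(regime_force(0, p), 0)
  ## cubic toe ends at 2/3 of the linear extrapolation
  expect_equal(regime_force(p$toe_end, p), 2 / 3 * p$k1 * p$toe_end)
  ## inside regime 1 the response is the toe end value plus k1 x distance
  d1 <- p$toe_end + 0.02e-3
  expect_equal(regime_force(d1, p),
               2 / 3 * 21.5 * 1e-5 + 21.5 * 0.02e-3)
  ## regime 2 sits at the first yield force
  b <- regime_breakpoints(p)
  expect_equal(regime_force(mean(b[2:3]), p), p$F_y1)
  ## final plateau at the second yield force
  expect_equal(regime_force(p$d_max, p), p$F_y2)
})

test_that("noiseless curves are continuous and non-decreasing", {
  for (rate in c(0.1, 0.5, 2.0)) {
    p <- make_rate_preset(rate)
    crv <- generate_fd_curve(p, n_points = 2000, noise_sd = 0, seed = 1)
    expect_true(all(diff(crv$force) >= -1e-15))
    ## continuity at the four breakpoints
    b <- regime_breakpoints(p)
    ## any residual jump must be of slope scale (continuous function),
    ## not of force scale
    eps <- 1e-12
    expect_lt(max(abs(regime_force(b - eps, p) - regime_force(b + eps, p))),
              10 * p$k3 * eps)
  }
})

test_that("curve generation is reproducible and noise is unbiased", {
  p <- make_rate_preset(2.0)
  a <- generate_fd_curve(p, 500, 0.02e-3, seed = 42)
  b <- generate_fd_curve(p, 500, 0.02e-3, seed = 42)
  expect_identical(a$displacement, b$displacement)
  expect_identical(a$force, b$force)
  expect_false(identical(
    a$force, generate_fd_curve(p, 500, 0.02e-3, seed = 43)$force))

  ## the sample mean of noisy draws converges to the noiseless curve
  probe_idx <- c(30, 250, 480)
  clean <- generate_fd_curve(p, 500, 0, seed = 1)
  n_draws <- 1000
  sums <- numeric(3)
  for (s in seq_len(n_draws)) {
    crv <- generate_fd_curve(p, 500, 0.02e-3, seed = s)
    sums <- sums + crv$force[probe_idx]
  }
  means <- sums / n_draws
  se <- 0.02e-3 / sqrt(n_draws)
  expect_true(all(abs(means - clean$force[probe_idx]) < 3 * se))
})

test_that("generator argument validation", {
  p <- make_rate_preset(2.0)
  expect_error(generate_fd_curve(p, 10, 0, seed = 1), "at least 50")
  expect_error(generate_fd_curve(p, 100, -1, seed = 1), "non-negative")
  expect_error(generate_fd_curve(p, 100, 0), "seed")
})

test_that("synthetic calibration tables follow Hooke's law against gravity", {
  ## hand value: 1 g mass on a 54.96 N/m spring extends 178.49 um
  tab <- generate_calibration_table(k_true = 54.96, masses = 1e-3,
                                    noise_sd = 0, seed = 1)
  expect_equal(tab$extension_m, 1e-3 * G_STD / 54.96, tolerance = 1e-12)
  ## zero mass is an explicit tare record
  tab0 <- generate_calibration_table(k_true = 54.96, masses = c(0, 1e-3),
                                     noise_sd = 0, seed = 1)
  expect_equal(tab0$extension_m[1], 0)
  ## default mass grid spans the calibration wires, 150-2200 mg
  m <- default_calibration_masses()
  expect_equal(range(m), c(150e-6, 2200e-6))
  expect_length(m, 10)
  expect_error(generate_calibration_table(k_true = -5, seed = 1), "positive")
  ## reproducible
  t1 <- generate_calibration_table(noise_sd = 2e-6, seed = 7)
  t2 <- generate_calibration_table(noise_sd = 2e-6, seed = 7)
  expect_identical(t1$extension_m, t2$extension_m)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_fd_curve(make_rate_preset(2.0), 100, 1e-5, seed = 9))
  invisible(generate_calibration_table(noise_sd = 1e-6, seed = 9))
  expect_identical(.Random.seed, before)
})
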