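test_that("zero-amplitude model degenerates to a flat waveform at baseline", {
  m <- waveform_model(amplitude = 0, noise_sd = 0)
  w <- generate_waveform(m, duration = 40, rate = 2)
  expect_length(w$positions, 80)
  expect_equal(w$positions, rep(m$baseline, 80))
})

test_that("waveform extrema match the analytic kernel", {
  # symmetric cycle, tau = 4 s at 2 Hz: the trough (full inhale) falls
  # exactly on a sample, so min = baseline - A and max = baseline
  m <- waveform_model(amplitude = 16, inhale_fraction = 0.5,
                      amplitude_jitter = 0, period_jitter = 0,
                      noise_sd = 0)
  w <- generate_waveform(m, duration = 40, rate = 2)
  expect_equal(min(w$positions), m$baseline - 16)
  expect_equal(max(w$positions), m$baseline)
  trough_t <- w$times[which(w$positions == min(w$positions))]
  expect_true(all(abs((trough_t - 2) %% 4) < 1e-9))
  # asymmetric default: trough at the inhale fraction of the cycle,
  # within one sample of the analytic extremum time
  ma <- waveform_model(amplitude = 16, amplitude_jitter = 0,
                       period_jitter = 0, noise_sd = 0)
  wa <- generate_waveform(ma, duration = 8, rate = 2)
  expect_lte(abs(wa$times[which.min(wa$positions)] -
                   ma$inhale_fraction * ma$period), 0.5)
})

test_that("waveform generation honors the seed contract", {
  m <- waveform_model(seed = 42L)
  w1 <- generate_waveform(m)
  w2 <- generate_waveform(m)
  expect_identical(w1$positions, w2$positions)
  m2 <- waveform_model(seed = 43L)
  expect_false(identical(generate_waveform(m2)$positions, w1$positions))
})

test_that("invalid waveform arguments are rejected", {
  expect_error(waveform_model(amplitude = -1), "invalid-argument")
  expect_error(waveform_model(period = 0), "invalid-argument")
  expect_error(waveform_model(amplitude_jitter = 0.7), "invalid-argument")
  expect_error(generate_waveform(waveform_model(), duration = -5),
               "invalid-argument")
  expect_error(generate_waveform(waveform_model(), duration = 0.2,
                                 rate = 2), "invalid-argument")
})

test_that("three series of a 40-s 2-Hz scan hold 3 x 80 frames", {
  m <- small_model(noise_sd = 0)
  w <- generate_waveform(m, duration = 40, rate = 2)
  series <- generate_series(small_config(image_noise_sd = 0), w,
                            n_series = 3)
  expect_length(series, 3)
  counts <- vapply(series, function(s) length(s$frames), integer(1))
  expect_equal(counts, rep(80L, 3))
  for (s in series) {
    ts <- vapply(s$frames, `[[`, numeric(1), "timestamp")
    expect_true(all(diff(ts) > 0))
    expect_equal(diff(ts), rep(1 / s$frame_rate, 79))
    expect_false(anyDuplicated(ts) > 0)
  }
})

test_that("hysteresis separates inhale and exhale branches by 2*h*g(u)", {
  h <- 3
  cfg <- small_config(hysteresis_width = h, tumor_si_coupling = 1,
                      image_noise_sd = 0)
  m <- small_model(inhale_fraction = 0.5, amplitude_jitter = 0,
                   period_jitter = 0, noise_sd = 0)
  w <- generate_waveform(m, duration = 4, rate = 2)
  ser <- generate_series(cfg, w, n_series = 1)[[1]]
  # tau = 4 s at 2 Hz, symmetric: samples at t = 0.5 and 3.5 share u on
  # opposite branches
  i1 <- which(abs(w$times - 0.5) < 1e-9)
  i2 <- which(abs(w$times - 3.5) < 1e-9)
  expect_equal(w$truth$u[i1], w$truth$u[i2])
  expect_equal(w$truth$direction[i1], "inhale")
  expect_equal(w$truth$direction[i2], "exhale")
  u <- w$truth$u[i1]
  expected_gap <- 2 * h * sqrt(u * (1 - u))  # analytic phase-loop oracle
  f1 <- ser$frames[[i1]]; f2 <- ser$frames[[i2]]
  expect_equal(f2$true_tumor_center[2] - f1$true_tumor_center[2],
               expected_gap)
  com_ap <- function(fr) {
    idx <- which(fr$tumor_mask, arr.ind = TRUE)
    mean((idx[, 2] - 1) * fr$voxel_size)
  }
  expect_lt(abs((com_ap(f2) - com_ap(f1)) - expected_gap),
            cfg$voxel_size / 2)
})

test_that("hysteresis off gives identical masks at equal displacement", {
  cfg <- small_config(hysteresis_width = 0, shape_modulation = 0,
                      image_noise_sd = 0)
  m <- small_model(inhale_fraction = 0.5, amplitude_jitter = 0,
                   period_jitter = 0, noise_sd = 0)
  w <- generate_waveform(m, duration = 4, rate = 2)
  ser <- generate_series(cfg, w, n_series = 1)[[1]]
  i1 <- which(abs(w$times - 0.5) < 1e-9)
  i2 <- which(abs(w$times - 3.5) < 1e-9)
  expect_identical(ser$frames[[i1]]$tumor_mask,
                   ser$frames[[i2]]$tumor_mask)
})

test_that("doubling the amplitude doubles the tumor SI range", {
  mk_range <- function(A) {
    m <- small_model(amplitude = A, amplitude_jitter = 0,
                     period_jitter = 0, noise_sd = 0)
    w <- generate_waveform(m, duration = 8, rate = 2)
    ser <- generate_series(small_config(image_noise_sd = 0), w, 1)[[1]]
    si <- vapply(ser$frames, function(f) f$true_tumor_center[3],
                 numeric(1))
    diff(range(si))
  }
  r1 <- mk_range(6)
  r2 <- mk_range(12)
  expect_lt(abs(r2 - 2 * r1), 5)  # within one voxel
})

test_that("a tumor leaving the grid is an invalid configuration", {
  cfg <- small_config(tumor_rest_center = c(80, 110, 20))
  m <- small_model(noise_sd = 0)
  w <- generate_waveform(m, duration = 4, rate = 2)
  expect_error(generate_series(cfg, w, 1), "invalid-configuration")
})

test_that("cohort configuration encodes the study conditions", {
  co <- cohort_config(seed = 5L)
  expect_length(co, 8)
  amps <- vapply(co, function(p) p$model$amplitude, numeric(1))
  expect_equal(amps, c(15.8, 12.9, 20.7, 14.4, 9.6, 15.8, 11.6, 29.1))
  expect_true(all(vapply(co, function(p) p$model$amplitude_jitter,
                         numeric(1)) >= 0.05))
  hw <- vapply(co, function(p) p$config$hysteresis_width, numeric(1))
  expect_true(all(hw >= 2 & hw <= 4))
  # distinct deterministic seeds
  seeds <- vapply(co, function(p) p$model$seed, integer(1))
  expect_false(anyDuplicated(seeds) > 0)
  expect_identical(seeds, vapply(cohort_config(seed = 5L),
                                 function(p) p$model$seed, integer(1)))
})
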