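test_that("noise generation is a pure function of config and seed", {
  a <- gen_noise(n_trials = 3, duration = 1, fs = 250, exponent = 1, seed = 30)
  b <- gen_noise(n_trials = 3, duration = 1, fs = 250, exponent = 1, seed = 30)
  expect_identical(a, b)
  c <- gen_noise(n_trials = 3, duration = 1, fs = 250, exponent = 1, seed = 31)
  expect_false(identical(a, c))
  expect_error(gen_noise(exponent = -1), "invalid config")
  expect_error(gen_noise(band = c(0.5, 200)), "invalid config")
})

test_that("generated noise has the requested spectral exponent", {
  white <- gen_noise(n_trials = 40, duration = 8, fs = 250, exponent = 0,
                     seed = 32)
  expect_lt(abs(fit_slope(compute_psd(white), exclude = NULL)$slope), 0.12)
  pink <- gen_noise(n_trials = 40, duration = 8, fs = 250, exponent = 1,
                    seed = 33)
  expect_equal(fit_slope(compute_psd(pink), exclude = NULL)$slope, -1,
               tolerance = 0.15)
  expect_equal(sd(unlist(pink$segments[[1]])), 1, tolerance = 1e-12)
})

test_that("added rhythms are phase-locked pure sinusoids of the right variance", {
  base <- gen_noise(n_trials = 4, duration = 2, fs = 250, exponent = 1,
                    seed = 34)
  expect_identical(add_rhythm(base, 10, 0), base)
  withr <- add_rhythm(base, 10, 2)
  d1 <- withr$segments[[1]] - base$segments[[1]]
  d2 <- withr$segments[[2]] - base$segments[[2]]
  expect_equal(d1, d2) # phase-locked across trials
  expect_equal(mean(d1^2), 2^2 / 2, tolerance = 1e-10) # integer cycles
  t <- (seq_along(d1) - 1) / 250
  expect_gt(cor(d1, sin(2 * pi * 10 * t)), 0.999)
})

test_that("global SNR behaves as (RMS ratio)^2", {
  base <- gen_noise(n_trials = 30, duration = 8, fs = 250, exponent = 1,
                    seed = 35)
  expect_equal(snr_global(base, base), 1)
  withr <- add_rhythm(base, 10, 2)
  expect_equal(snr_global(withr, base), 3, tolerance = 0.1) # 1 + (4/2)/1
  half <- map_segments(base, function(s) s / 2)
  halfr <- map_segments(withr, function(s) s / 2)
  expect_equal(snr_global(halfr, half), snr_global(withr, base))
})

test_that("slope sweeps are seed-paired and ordered", {
  same <- gen_slope_sweep(c(1, 1), n_trials = 2, duration = 2, seed = 36)
  expect_identical(same[[1]]$segments, same[[2]]$segments)
  sw <- gen_slope_sweep(c(0, 0.8, 1.5), n_trials = 20, duration = 4, seed = 37)
  slopes <- vapply(sw, function(s) fit_slope(compute_psd(s),
                                             exclude = NULL)$slope, numeric(1))
  expect_true(all(diff(slopes) < 0)) # steeper requested -> steeper fitted
  # white noise is more irregular than pink at scale 1 (scale-wise bounds)
  e0 <- compute_mmse(sw[["x0"]], taus = 1)$entropy
  e15 <- compute_mmse(sw[["x1.5"]], taus = 1)$entropy
  expect_gt(e0, e15)
})

test_that("alpha segment factorial is paired and alpha adds a unit sinusoid", {
  sets <- gen_alpha_segments(n = 20, seed = 38)
  expect_named(sets, c("x1_alpha0", "x1_alpha1", "x1.2_alpha0", "x1.2_alpha1"))
  d <- sets[["x1_alpha1"]]$segments[[3]] - sets[["x1_alpha0"]]$segments[[3]]
  t <- (seq_along(d) - 1) / sets[[1]]$fs
  expect_equal(d, sin(2 * pi * 10 * t), tolerance = 1e-12)
  expect_equal(length(d), 125) # 250 ms at 500 Hz
})

test_that("event streams carry a consistent ground-truth table", {
  ev <- gen_event_stream(n_trials = 10, seed = 39)
  n <- length(ev$data$segments[[1]])
  expect_equal(nrow(ev$truth), 10)
  expect_true(all(ev$truth$onset >= 1 & ev$truth$offset <= n))
  # burst region has elevated energy relative to the same-length pre window
  tr <- ev$truth[1, ]
  seg <- ev$data$segments[[1]]
  burst_rms <- sqrt(mean(seg[tr$onset:(tr$offset - 1)]^2))
  pre_rms <- sqrt(mean(seg[1:(tr$onset - 1)]^2))
  expect_gt(burst_rms, 1.5 * pre_rms)
  none <- gen_event_stream(amplitude = 0, n_trials = 3, seed = 40)
  expect_equal(nrow(none$truth), 0)
})
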