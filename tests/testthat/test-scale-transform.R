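test_that("cutoff formulas follow the scale-to-frequency mapping", {
  expect_equal(cutoffs_for_scale(1, 250, "lowpass")$lp_hz, 125)
  expect_equal(cutoffs_for_scale(4, 250, "lowpass")$lp_hz, 31.25)
  expect_equal(cutoffs_for_scale(4, 250, "highpass")$hp_hz, 25)
  expect_equal(cutoffs_for_scale(5, 500, "bandpass")$band, c(47.5, 52.5))
  expect_error(cutoffs_for_scale(0, 250, "lowpass"), ">= 1")
})

test_that("filter designs follow the per-variant conventions", {
  # scale 1 bandpass: only a 10th-order Butterworth high-pass
  f1 <- design_scale_filter(1, 250, "bandpass")
  expect_length(f1$stages, 1)
  expect_equal(f1$stages[[1]]$order, 10L)
  expect_equal(f1$stages[[1]]$type, "high")
  expect_equal(f1$stages[[1]]$family, "butterworth")
  # scale 1 lowpass is the identity (cutoff would sit at Nyquist)
  expect_length(design_scale_filter(1, 250, "lowpass")$stages, 0)
  # narrow passbands use the Chebyshev-I cascade, broad ones Butterworth
  expect_equal(design_scale_filter(3, 250, "bandpass")$stages[[1]]$family,
               "chebyshev1")
  expect_equal(design_scale_filter(2, 250, "bandpass")$stages[[1]]$family,
               "butterworth")
  expect_equal(design_scale_filter(5, 250, "lowpass")$stages[[1]]$order, 6L)
  expect_equal(design_scale_filter(5, 250, "highpass")$stages[[1]]$order, 6L)
})

test_that("two-pass magnitude response has the expected cutoff gain and rejection", {
  f <- design_scale_filter(5, 250, "lowpass") # LP = 25 Hz
  expect_equal(filter_gain(f, 25), 0.5, tolerance = 1e-6) # (-3 dB)^2
  # >= 20 dB rejection one octave beyond the cutoff
  expect_lt(filter_gain(f, 50), 0.1)
  fh <- design_scale_filter(4, 250, "highpass") # HP = 25 Hz
  expect_lt(filter_gain(fh, 12.5), 0.1)
  fb <- design_scale_filter(5, 500, "bandpass") # band 47.5-52.5 Hz
  expect_lt(filter_gain(fb, 25), 0.1)
  expect_lt(filter_gain(fb, 105), 0.1)
  expect_gt(filter_gain(fb, 50), 0.6)
})

test_that("a strong out-of-band rhythm is attenuated by the scale filter", {
  t <- (0:1999) / 250
  s <- sin(2 * pi * 10 * t)
  f <- design_scale_filter(25, 250, "lowpass") # LP = 5 Hz
  out <- unlist(filt_skip(s, f))
  expect_lt(sqrt(mean(out^2)), 0.05 * sqrt(mean(s^2)))
})

test_that("symmetric mean padding pads with the mean and trims back", {
  expect_equal(pad_symmetric_mean(c(1, 2, 3), 2), c(2, 2, 1, 2, 3, 2, 2))
  expect_equal(pad_symmetric_mean(c(1, 2, 3), 0), c(1, 2, 3))
  set.seed(7)
  x <- rnorm(300)
  f <- design_scale_filter(3, 250, "lowpass")
  expect_length(filt_skip(x, f)[[1]], 100) # length preserved through pad/trim
})

test_that("point averaging bins correctly and equals an FIR+decimate oracle", {
  expect_equal(point_average(1:9, 3), c(2, 5, 8))
  set.seed(8)
  x <- rnorm(101)
  expect_equal(point_average(x, 1), x)
  expect_equal(point_average(rep(3, 50), 7), rep(3, 7))
  for (tau in c(2, 5, 10)) {
    ma <- as.numeric(stats::filter(x, rep(1 / tau, tau), sides = 1))
    expect_equal(point_average(x, tau),
                 ma[seq(tau, tau * floor(length(x) / tau), by = tau)])
  }
})

test_that("filt-skip emits offset sub-series for lowpass, one series otherwise", {
  set.seed(9)
  x <- rnorm(300)
  f3 <- design_scale_filter(3, 250, "lowpass")
  subs <- filt_skip(x, f3)
  expect_length(subs, 3)
  expect_true(all(lengths(subs) == 100))
  f1 <- design_scale_filter(1, 250, "lowpass")
  expect_equal(filt_skip(x, f1), list(x)) # scale-1 contract: identity
  expect_length(filt_skip(x, design_scale_filter(4, 250, "highpass")), 1)
  expect_length(filt_skip(x, design_scale_filter(6, 250, "bandpass")), 1)
  expect_length(filt_skip(x, design_scale_filter(
    1, 250, "bandstop", bandstop_band = c(8, 15))), 1)
})

test_that("two-pass filtering is zero-phase (symmetric pulse stays centred)", {
  n <- 501
  pulse <- exp(-((seq_len(n) - 251)^2) / (2 * 15^2))
  f <- design_scale_filter(5, 250, "lowpass")
  filtered <- mmse:::apply_scale_filter(pad_symmetric_mean(pulse, 250), f)
  filtered <- filtered[251:(250 + n)]
  expect_equal(which.max(filtered), 251)
})

test_that("scale-wise SD is non-increasing with tau for lowpass coarse-graining", {
  ss <- gen_noise(n_trials = 5, duration = 4, fs = 250, exponent = 1, seed = 10)
  res <- compute_mmse(ss, taus = c(1, 2, 4, 8, 16, 32), variant = "lowpass")
  expect_true(all(diff(res$scale_sd) <= 1e-12))
})

test_that("lowpass-decimated white noise stays spectrally flat", {
  ss <- gen_noise(n_trials = 10, duration = 8, fs = 250, exponent = 0,
                  band = NULL, seed = 11)
  f <- design_scale_filter(10, 250, "lowpass")
  subs <- lapply(ss$segments, function(s) filt_skip(s, f)[[1]])
  psd <- compute_psd(segment_set(subs, fs = 25),
                     freqs = 2^seq(log2(0.8), log2(10), length.out = 20))
  expect_lt(abs(fit_slope(psd, exclude = NULL)$slope), 0.25)
})
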