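test_that("wavelet power is tuned to the stimulus frequency and scales quadratically", {
  t <- (0:1999) / 250
  s <- sin(2 * pi * 10 * t)
  tfr <- wavelet_tfr(s, fs = 250)
  mp <- rowMeans(tfr$power, na.rm = TRUE)
  expect_equal(tfr$freqs[which.max(mp)], 10, tolerance = 0.06)
  tfr2 <- wavelet_tfr(2 * s, fs = 250)
  expect_equal(tfr2$power[tfr2$valid], 4 * tfr$power[tfr$valid],
               tolerance = 1e-10)
  # octave-separated sinusoids produce separable ridges
  s2 <- sin(2 * pi * 8 * t) + sin(2 * pi * 16 * t)
  mp2 <- rowMeans(wavelet_tfr(s2, fs = 250)$power, na.rm = TRUE)
  i8 <- which.min(abs(tfr$freqs - 8))
  i16 <- which.min(abs(tfr$freqs - 16))
  imid <- which.min(abs(tfr$freqs - sqrt(8 * 16)))
  expect_gt(mp2[i8], 2 * mp2[imid])
  expect_gt(mp2[i16], 2 * mp2[imid])
})

test_that("background fit recovers the 1/f slope and calibrates the threshold", {
  ss <- gen_noise(n_trials = 8, duration = 8, fs = 250, exponent = 1, seed = 70)
  tfrs <- lapply(ss$segments, wavelet_tfr, fs = 250)
  bg <- fit_background(tfrs)
  expect_equal(bg$slope, -1, tolerance = 0.3)
  frac <- mean(vapply(tfrs, function(tf)
    mean((tf$power > bg$threshold)[tf$valid]), numeric(1)))
  expect_gt(frac, 0.035)
  expect_lt(frac, 0.065)
  # scaling the signal scales the background quadratically
  tfrs2 <- lapply(ss$segments, function(s) wavelet_tfr(3 * s, fs = 250))
  bg2 <- fit_background(tfrs2)
  expect_equal(bg2$background, 9 * bg$background, tolerance = 1e-6)
})

test_that("episode detection recovers inserted bursts with cycle precision", {
  ev <- gen_event_stream(n_trials = 40, seed = 71)
  tfrs <- lapply(ev$data$segments, wavelet_tfr, fs = 250)
  bg <- fit_background(tfrs)
  hit <- 0
  for (i in seq_len(40)) {
    eps <- detect_episodes(tfrs[[i]], bg, min_cycles = 1)
    eps <- eps[eps$duration_cycles >= 3 & eps$mean_freq > 7 &
                 eps$mean_freq < 14, , drop = FALSE]
    if (nrow(eps) == 0) next
    ov <- pmin(eps$offset, ev$truth$offset[i]) -
      pmax(eps$onset, ev$truth$onset[i])
    j <- which.max(ov)
    cyc <- 25 # one 10 Hz cycle at 250 Hz
    if (abs(eps$onset[j] - ev$truth$onset[i]) <= cyc &&
        abs(eps$offset[j] - ev$truth$offset[i]) <= cyc) hit <- hit + 1
  }
  expect_gte(hit, 36) # >= 90% in this reduced run
  # zero signal produces an empty table
  flat <- wavelet_tfr(rep(0, 2000), fs = 250)
  expect_equal(nrow(detect_episodes(flat, bg)), 0)
})

test_that("spurious coherent-episode rate on noise-only trials is low", {
  ss <- gen_noise(n_trials = 20, duration = 8, fs = 250, exponent = 1, seed = 72)
  tfrs <- lapply(ss$segments, wavelet_tfr, fs = 250)
  bg <- fit_background(tfrs)
  n_spur <- vapply(tfrs, function(tf) {
    eps <- detect_episodes(tf, bg, min_cycles = 1)
    sum(eps$duration_cycles >= 3 & eps$mean_freq > 8 & eps$mean_freq < 12.5)
  }, numeric(1))
  expect_lte(mean(n_spur), 0.1) # per 8-s trial at 10 Hz
})

test_that("episode rates count only windows containing the episode frequency", {
  freqs <- 2^seq(log2(1), log2(64), length.out = 49)
  empty <- data.frame(mean_freq = numeric(0), onset = integer(0),
                      offset = integer(0), duration_cycles = numeric(0),
                      mean_amplitude = numeric(0))
  expect_true(all(episode_rate(empty, freqs, total_time = 10)$rate == 0))
  one <- data.frame(mean_freq = 10, onset = 1, offset = 100,
                    duration_cycles = 4, mean_amplitude = 1)
  r <- episode_rate(one, freqs, total_time = 10)
  nz <- r$freq[r$rate > 0]
  half_step <- freqs[2] / freqs[1]
  expect_true(all(nz >= 10 / half_step^2 & nz <= 10 * half_step^2))
  expect_gt(length(nz), 0)
  short <- one; short$duration_cycles <- 2
  expect_true(all(episode_rate(short, freqs, total_time = 10)$rate == 0))
  # doubling the table doubles raw counts
  expect_equal(episode_rate(rbind(one, one), freqs)$rate,
               2 * episode_rate(one, freqs)$rate)
})

test_that("trough-locked averages align a sinusoid's trough at lag zero", {
  t <- (0:1999) / 250
  s <- sin(2 * pi * 10 * t)
  eps <- data.frame(mean_freq = 10, onset = 500, offset = 1000,
                    duration_cycles = 20, mean_amplitude = 1)
  out <- trough_lock_average(s, 250, eps, band = "alpha", snippet_s = 0.2)
  expect_equal(out$n_events, 1)
  mid <- (length(out$waveform) + 1) / 2
  # a trough sits at lag 0 (the waveform is periodic, so equal troughs recur)
  expect_equal(out$waveform[mid], min(out$waveform), tolerance = 1e-6)
  none <- trough_lock_average(s, 250, eps[0, ], band = "alpha")
  expect_equal(none$n_events, 0)
})

test_that("window entropy drops inside alpha bursts and band-stop removes the drop", {
  ev <- gen_event_stream(freq = 10, n_cycles = 8, amplitude = 2,
                         n_trials = 60, duration = 4, fs = 250, seed = 73)
  tab_raw <- tab_bs <- list()
  for (i in seq_len(60)) {
    eps <- data.frame(mean_freq = 10, onset = ev$truth$onset[i],
                      offset = ev$truth$offset[i], duration_cycles = 8,
                      mean_amplitude = 1)
    seg <- ev$data$segments[[i]]
    tab_raw[[i]] <- event_window_entropy(seg, 250, eps)
    tab_bs[[i]] <- event_window_entropy(seg, 250, eps, bandstop = c(8, 15))
  }
  raw <- do.call(rbind, tab_raw)
  bs <- do.call(rbind, tab_bs)
  expect_gt(nrow(raw), 50)
  d_raw <- raw$within - raw$outside
  d_bs <- bs$within - bs$outside
  expect_lt(sign_test_p(d_raw), 0.01) # circularity: entropy drops inside
  expect_lt(mean(d_raw), -0.05)
  expect_gt(sign_test_p(d_bs), 0.1) # band-stop removes the circular drop
  expect_lt(abs(mean(d_bs)), 0.05)
  expect_true(all(raw$amplitude_class %in% c("high", "low")))
})

test_that("band-stopped window entropy is invariant to adding a pure alpha tone", {
  ss <- gen_noise(n_trials = 1, duration = 4, fs = 250, exponent = 1, seed = 74)
  x <- ss$segments[[1]]
  t <- (seq_along(x) - 1) / 250
  eps <- data.frame(mean_freq = 10, onset = 400, offset = 600,
                    duration_cycles = 8, mean_amplitude = 1)
  a <- event_window_entropy(x, 250, eps, bandstop = c(8, 15))
  b <- event_window_entropy(x + 2 * sin(2 * pi * 10 * t), 250, eps,
                            bandstop = c(8, 15))
  for (col in c("pre_onset", "post_onset", "pre_offset", "post_offset"))
    expect_equal(a[[col]], b[[col]], tolerance = 0.08)
})
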