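test_that("scale 1 reduces to plain sample entropy on the raw segments", {
  set.seed(20)
  ss <- segment_set(matrix(rnorm(3 * 400), nrow = 3), fs = 250)
  raw <- as.numeric(sample_entropy(ss, m = 2, r = 0.5))
  for (variant in c("lowpass", "original_pointavg")) {
    for (policy in c("global", "scalewise")) {
      res <- compute_mmse(ss, taus = 1L, variant = variant, policy = policy)
      expect_equal(res$entropy[1], raw, info = paste(variant, policy))
    }
  }
})

test_that("scale frequency labels follow the variant convention", {
  expect_equal(scale_frequency_labels(1, 250, "lowpass"), 125)
  expect_equal(scale_frequency_labels(12, 500, "lowpass"), 250 / 12)
  expect_equal(scale_frequency_labels(4, 250, "highpass"), 25)
  labs <- scale_frequency_labels(1:42, 250, "bandpass")
  expect_true(all(diff(labs) < 0))
})

test_that("bound policies produce the documented bound structure", {
  set.seed(21)
  ss <- segment_set(matrix(rnorm(4 * 500), nrow = 4), fs = 250)
  g <- compute_mmse(ss, taus = c(1, 4, 8), policy = "global")
  expect_equal(g$bound, rep(0.5 * sd(unlist(ss$segments)), 3))
  s <- compute_mmse(ss, taus = c(1, 4, 8), policy = "scalewise")
  expect_equal(s$bound, 0.5 * s$scale_sd)
})

test_that("global bounds depress coarse-scale white-noise entropy, scale-wise bounds do not", {
  ss <- gen_noise(n_trials = 20, duration = 8, fs = 250, exponent = 0,
                  band = NULL, seed = 22)
  g <- compute_mmse(ss, taus = c(1, 20), policy = "global")
  s <- compute_mmse(ss, taus = c(1, 20), policy = "scalewise")
  expect_gt(g$entropy[1] - g$entropy[2], 0.3)
  expect_lt(abs(s$entropy[2] - s$entropy[1]), 0.15)
  expect_gt(s$entropy[2] - g$entropy[2], 0.3)
})

test_that("refined-composite counting stabilises coarse-scale estimates", {
  comp <- single <- numeric(20)
  for (i in 1:20) {
    ss <- gen_noise(n_trials = 1, duration = 8, fs = 250, exponent = 0,
                    band = NULL, seed = 300 + i)
    comp[i] <- compute_mmse(ss, taus = 30, policy = "scalewise")$entropy
    f <- design_scale_filter(30, 250, "lowpass")
    sub1 <- filt_skip(ss$segments[[1]], f)[[1]] # first offset only
    single[i] <- as.numeric(sample_entropy(sub1, bound = 0.5 * sd(sub1), fs = 1))
  }
  expect_lt(var(comp), var(single))
})

test_that("flagged scales propagate without aborting the curve", {
  set.seed(23)
  ss <- segment_set(rnorm(80), fs = 250) # too short for coarse scales
  res <- compute_mmse(ss, taus = c(1, 30), policy = "scalewise")
  expect_equal(res$flag[1], "ok")
  expect_false(res$flag[2] == "ok")
  expect_true(is.na(res$entropy[2]))
})

test_that("spline interpolation recovers linear and quadratic curves", {
  set.seed(24)
  ss <- segment_set(matrix(rnorm(2 * 600), nrow = 2), fs = 250)
  res <- compute_mmse(ss, taus = seq(1, 22, by = 3), policy = "scalewise")
  # overwrite with known synthetic curves to test the interpolator in isolation
  lin <- res
  lin$entropy <- 0.1 + 0.02 * lin$tau
  out <- interpolate_scales(lin, 1:22)
  expect_equal(out$entropy, 0.1 + 0.02 * (1:22), tolerance = 1e-10)
  expect_true(all(out$interpolated[!(out$tau %in% lin$tau)]))
  quad <- res
  quad$entropy <- 1 + 0.05 * quad$tau - 0.001 * quad$tau^2
  out2 <- interpolate_scales(quad, 1:22)
  expect_equal(out2$entropy, 1 + 0.05 * (1:22) - 0.001 * (1:22)^2,
               tolerance = 1e-6)
  # dense input is the identity on the computed scales
  dense <- interpolate_scales(res, res$tau)
  expect_equal(dense$entropy, res$entropy)
  expect_error(interpolate_scales(res, 1:42), "xtrapolation")
})
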