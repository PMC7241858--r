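#' Band-limited 1/f^x background noise trials
#'
#' Generates epochs of Gaussian noise whose power spectrum follows
#' `1/f^x`, via spectral synthesis: white Gaussian noise is Fourier
#' transformed, its amplitudes scaled by `f^(-x/2)` (DC removed), and
#' transformed back. Each trial is then band-pass filtered with a two-pass
#' 4th-order Butterworth at `band` and (by default) rescaled to unit SD so
#' that rhythm amplitudes added later are in interpretable units.
#'
#' Defaults mirror the simulation conditions used throughout this package's
#' validation: 100 trials of 8 s at 250 Hz, pink (`x = 1`) background,
#' band-limited to 0.5--70 Hz.
#'
#' @param n_trials number of epochs.
#' @param duration epoch duration in seconds (`duration * fs` must be whole).
#' @param fs sampling rate in Hz.
#' @param exponent spectral exponent `x >= 0` (0 = white, 1 = pink).
#' @param band length-2 Hz band for the background band-pass filter;
#'   `NULL` disables band-limiting (used for very short segments where the
#'   band edges are unresolvable).
#' @param normalize_sd rescale every trial to SD 1 (default TRUE).
#' @param seed integer RNG seed; `NULL` uses the current RNG state.
#' @return a [segment_set()] of `n_trials` epochs.
#' @examples
#' ss <- gen_noise(n_trials = 3, duration = 1, fs = 250, exponent = 1, seed = 1)
#' @export
gen_noise <- function(n_trials = 100, duration = 8, fs = 250, exponent = 1,
                      band = c(0.5, 70), normalize_sd = TRUE, seed = NULL) {
  if (exponent < 0) stop("invalid config: `exponent` must be >= 0")
  n <- duration * fs
  if (abs(n - round(n)) > 1e-9) stop("invalid config: duration * fs must be integral")
  n <- as.integer(round(n))
  if (!is.null(band)) {
    if (band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2])
      stop("invalid config: `band` must lie strictly inside (0, fs/2)")
  }
  if (!is.null(seed)) set.seed(seed)
  segs <- lapply(seq_len(n_trials), function(i)
    one_noise_trial(n, fs, exponent, band, normalize_sd))
  segment_set(segs, fs)
}

one_noise_trial <- function(n, fs, exponent, band, normalize_sd) {
  white <- stats::rnorm(n)
  x <- shape_spectrum(white, fs, exponent)
  if (!is.null(band)) {
    ba <- signal::butter(4, band / (fs / 2), type = "pass")
    pad <- floor(n / 2)
    xp <- pad_symmetric_mean(x, pad)
    xp <- as.numeric(signal::filter(ba$b, ba$a, xp))
    xp <- rev(as.numeric(signal::filter(ba$b, ba$a, rev(xp))))
    x <- xp[(pad + 1):(pad + n)]
  }
  if (normalize_sd) x <- x / stats::sd(x)
  x
}

# scale the Fourier amplitudes of a real series by f^(-x/2)
shape_spectrum <- function(white, fs, exponent) {
  n <- length(white)
  if (exponent == 0) return(white)
  f <- fs * (0:(n - 1)) / n
  f <- pmin(f, fs - f) # two-sided spectrum, symmetric frequencies
  amp <- c(0, f[-1]^(-exponent / 2)) # kill DC
  Re(stats::fft(stats::fft(white) * amp, inverse = TRUE)) / n
}

#' Superimpose a phase-locked sinusoid on every trial
#'
#' @param data a [segment_set()].
#' @param freq rhythm frequency in Hz (< fs/2).
#' @param amplitude peak amplitude in signal units (>= 0).
#' @param phase starting phase in radians, identical across trials
#'   (phase-locked).
#' @return a [segment_set()] with `amplitude * sin(2*pi*freq*t + phase)`
#'   added to each segment; the background is untouched.
#' @export
add_rhythm <- function(data, freq, amplitude, phase = 0) {
  stopifnot(inherits(data, "segment_set"))
  if (freq >= data$fs / 2) stop("`freq` must be below Nyquist")
  if (amplitude < 0) stop("`amplitude` must be >= 0")
  if (amplitude == 0) return(data)
  map_segments(data, function(s) {
    t <- (seq_along(s) - 1) / data$fs
    s + amplitude * sin(2 * pi * freq * t + phase)
  })
}

#' Global signal-to-noise ratio of a rhythm-plus-noise set
#'
#' `SNR_global = (RMS_signal / RMS_noise)^2`, where the RMS is taken over all
#' samples of all trials; `signal` is the background plus rhythm and `noise`
#' the background alone. For independent components this equals
#' `1 + var_rhythm / var_noise`.
#'
#' @param with_rhythm [segment_set()] containing background + rhythm.
#' @param noise_only matching background-only [segment_set()].
#' @return a single ratio (1 when no rhythm was added).
#' @export
snr_global <- function(with_rhythm, noise_only) {
  stopifnot(inherits(with_rhythm, "segment_set"),
            inherits(noise_only, "segment_set"))
  s <- concat_segments(with_rhythm)
  n <- concat_segments(noise_only)
  if (length(s) != length(n)) stop("segment sets have mismatched shapes")
  rms_n <- sqrt(mean(n^2))
  if (rms_n == 0) stop("noise RMS is zero")
  (sqrt(mean(s^2)) / rms_n)^2
}

#' Noise sets across a sweep of spectral exponents
#'
#' Generates one [gen_noise()] set per exponent from a shared seed stream, so
#' sets are paired: the k-th trial of every set is built from the same white
#' noise, shaped by a different exponent.
#'
#' @param exponents numeric vector of spectral exponents.
#' @param seed integer seed for the shared stream.
#' @inheritParams gen_noise
#' @return a named list of [segment_set()]s (names `"x<exponent>"`).
#' @export
gen_slope_sweep <- function(exponents, n_trials = 100, duration = 8, fs = 250,
                            band = c(0.5, 70), normalize_sd = TRUE,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(round(duration * fs))
  whites <- lapply(seq_len(n_trials), function(i) stats::rnorm(n))
  out <- lapply(exponents, function(x) {
    segs <- lapply(whites, function(w) {
      y <- shape_spectrum(w, fs, x)
      if (!is.null(band)) {
        ba <- signal::butter(4, band / (fs / 2), type = "pass")
        pad <- floor(n / 2)
        yp <- pad_symmetric_mean(y, pad)
        yp <- as.numeric(signal::filter(ba$b, ba$a, yp))
        yp <- rev(as.numeric(signal::filter(ba$b, ba$a, rev(yp))))
        y <- yp[(pad + 1):(pad + n)]
      }
      if (normalize_sd) y <- y / stats::sd(y)
      y
    })
    segment_set(segs, fs)
  })
  names(out) <- paste0("x", exponents)
  out
}

#' Short 1/f segments with and without a superimposed alpha rhythm
#'
#' Builds the 2 x (slopes) factorial of short segments used to demonstrate the
#' circular relation between alpha rhythmicity and broadband sample entropy:
#' for every replicate one white-noise draw is shaped to each requested
#' spectral slope (paired across slopes), and an alpha-band sinusoid of the
#' given amplitude is either superimposed or not (paired across presence).
#' Segments are too short to band-limit at 0.5 Hz, so no background band-pass
#' is applied; each background is normalised to unit SD.
#'
#' @param slopes spectral exponents (default `c(1, 1.2)`).
#' @param n replicates per cell (default 100).
#' @param fs sampling rate in Hz (default 500, the empirical epoch rate,
#'   which makes a 250 ms window a whole number of samples).
#' @param duration segment duration in seconds (default 0.25).
#' @param alpha_freq rhythm frequency in Hz (default 10).
#' @param amplitude rhythm amplitude (default 1).
#' @param seed integer seed.
#' @return a named list of [segment_set()]s over the factorial cells, names
#'   `"x<slope>_alpha<0|1>"`.
#' @export
gen_alpha_segments <- function(slopes = c(1, 1.2), n = 100, fs = 500,
                               duration = 0.25, alpha_freq = 10,
                               amplitude = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ns <- as.integer(round(duration * fs))
  whites <- lapply(seq_len(n), function(i) stats::rnorm(ns))
  t <- (0:(ns - 1)) / fs
  alpha <- amplitude * sin(2 * pi * alpha_freq * t)
  out <- list()
  for (x in slopes) {
    bg <- lapply(whites, function(w) {
      y <- shape_spectrum(w, fs, x)
      y / stats::sd(y)
    })
    out[[sprintf("x%g_alpha0", x)]] <- segment_set(bg, fs)
    out[[sprintf("x%g_alpha1", x)]] <-
      segment_set(lapply(bg, function(s) s + alpha), fs)
  }
  out
}

#' Background noise with inserted rhythmic bursts and ground truth
#'
#' Inserts tapered sinusoidal bursts of known frequency, duration and
#' amplitude at random positions into 1/f background trials, for validating
#' episode detectors. Burst edges carry a half-cycle cosine taper to limit
#' spectral splatter; one burst per trial.
#'
#' @param freq burst frequency in Hz.
#' @param n_cycles burst duration in cycles.
#' @param amplitude burst peak amplitude (0 gives background only and an
#'   empty truth table).
#' @param n_trials number of trials.
#' @param duration trial duration in seconds.
#' @param fs sampling rate in Hz.
#' @param exponent background spectral exponent.
#' @param margin fraction of the trial kept burst-free at each edge
#'   (default 0.15, keeping bursts clear of wavelet edge effects).
#' @param seed integer seed.
#' @return a list with `data` (a [segment_set()]) and `truth` (data.frame:
#'   `trial`, `onset`, `offset` in samples, half-open `[onset, offset)`,
#'   `freq`, `amplitude`, `n_cycles`).
#' @export
gen_event_stream <- function(freq = 10, n_cycles = 5, amplitude = 4,
                             n_trials = 100, duration = 8, fs = 250,
                             exponent = 1, margin = 0.15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(round(duration * fs))
  burst_len <- as.integer(round(n_cycles / freq * fs))
  if (burst_len > n) stop("burst does not fit in the segment")
  bg <- gen_noise(n_trials, duration, fs, exponent, seed = NULL)
  if (amplitude == 0) {
    truth <- data.frame(trial = integer(0), onset = integer(0),
                        offset = integer(0), freq = numeric(0),
                        amplitude = numeric(0), n_cycles = numeric(0))
    return(list(data = bg, truth = truth))
  }
  lo <- as.integer(floor(margin * n)) + 1L
  hi <- n - burst_len - as.integer(floor(margin * n))
  if (hi < lo) stop("burst does not fit inside the margins")
  onsets <- sample(lo:hi, n_trials, replace = TRUE)
  tb <- (0:(burst_len - 1)) / fs
  burst <- amplitude * sin(2 * pi * freq * tb)
  taper_len <- max(1L, as.integer(round(fs / freq / 2))) # half cycle
  taper <- rep(1, burst_len)
  ramp <- 0.5 - 0.5 * cos(pi * seq(0, 1, length.out = taper_len))
  taper[seq_len(taper_len)] <- ramp
  taper[burst_len - taper_len + seq_len(taper_len)] <- rev(ramp)
  burst <- burst * taper
  segs <- bg$segments
  for (i in seq_len(n_trials)) {
    idx <- onsets[i] + 0:(burst_len - 1)
    segs[[i]][idx] <- segs[[i]][idx] + burst
  }
  truth <- data.frame(trial = seq_len(n_trials), onset = onsets,
                      offset = onsets + burst_len, freq = freq,
                      amplitude = amplitude, n_cycles = n_cycles)
  list(data = segment_set(segs, fs), truth = truth)
}
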