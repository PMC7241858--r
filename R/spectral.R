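#' Power spectral density at log-spaced frequencies
#'
#' Per segment: Hanning taper, zero-padding to `zero_pad_s` seconds, FFT,
#' power read off at the padded-grid bin nearest each requested frequency;
#' powers are averaged over segments and log10-transformed. The default grid
#' is 41 log-spaced (base-2) frequencies between 2 and 64 Hz.
#'
#' @param data a [segment_set()] (or vector/matrix/list plus `fs`).
#' @param freqs requested frequencies in Hz; default
#'   `2^seq(log2(2), log2(64), length.out = 41)`.
#' @param zero_pad_s total padded duration in seconds (default 10).
#' @param smooth_hz width (Hz) of a boxcar moving average applied to the
#'   linear power spectrum on the dense padded grid before frequencies are
#'   read off; 0 (default) disables smoothing.
#' @param fs sampling rate when `data` is not a segment_set.
#' @return an object of class `psd_result`: list with `freqs` (Hz),
#'   `log_power` (mean log10 power per frequency), `taper = "hanning"`,
#'   `zero_pad_s`, `fs`, `n_segments`.
#' @export
compute_psd <- function(data, freqs = NULL, zero_pad_s = 10, smooth_hz = 0,
                        fs = NULL) {
  ss <- as_segment_set(data, fs)
  if (is.null(freqs)) freqs <- 2^seq(log2(2), log2(64), length.out = 41)
  if (any(freqs <= 0) || any(freqs >= ss$fs / 2))
    stop("requested frequencies must lie strictly inside (0, Nyquist)")
  if (is.unsorted(freqs, strictly = TRUE)) stop("`freqs` must be strictly increasing")
  n_pad <- as.integer(round(zero_pad_s * ss$fs))
  grid <- ss$fs * (0:(n_pad - 1)) / n_pad
  idx <- vapply(freqs, function(f) which.min(abs(grid[1:(n_pad %/% 2)] - f)),
                integer(1))
  acc <- numeric(length(freqs))
  for (seg in ss$segments) {
    if (length(seg) < 2L) stop("segments must have >= 2 samples")
    if (length(seg) > n_pad)
      stop("segment longer than the zero-padded window")
    w <- hanning_taper(length(seg))
    x <- c(seg * w, rep(0, n_pad - length(seg)))
    p_raw <- Mod(stats::fft(x))^2
    p <- p_raw
    if (smooth_hz > 0) {
      k <- max(1L, as.integer(round(smooth_hz / (ss$fs / n_pad))))
      if (k %% 2L == 0L) k <- k + 1L
      p <- as.numeric(stats::filter(p_raw, rep(1 / k, k), sides = 2))
      # edge bins where the boxcar ran off the grid: fall back to raw power
      p[is.na(p)] <- p_raw[is.na(p)]
    }
    acc <- acc + p[idx]
  }
  structure(list(freqs = freqs,
                 log_power = log10(acc / length(ss$segments)),
                 taper = "hanning", zero_pad_s = zero_pad_s, fs = ss$fs,
                 n_segments = length(ss$segments)),
            class = "psd_result")
}

hanning_taper <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = n))

#' @export
print.psd_result <- function(x, ...) {
  cat(sprintf("<psd_result> %d frequencies %.3g-%.3g Hz, %d segment(s), %s taper\n",
              length(x$freqs), min(x$freqs), max(x$freqs), x$n_segments,
              x$taper))
  invisible(x)
}

#' Aperiodic (1/f) slope of a power spectrum
#'
#' Ordinary least-squares fit of log10 power on log10 frequency, excluding a
#' rhythm band (default 7--13 Hz, bracketing the alpha peak) so that a
#' narrowband peak does not bias the broadband fit. For `1/f^x` input the
#' slope estimates `-x`.
#'
#' @param psd a [compute_psd()] result.
#' @param exclude length-2 Hz interval excluded from the fit (closed);
#'   `NULL` uses all frequencies.
#' @return an object of class `slope_fit`: list with `slope`, `intercept`,
#'   `r2`, `excluded_band`, `n_points`.
#' @export
fit_slope <- function(psd, exclude = c(7, 13)) {
  stopifnot(inherits(psd, "psd_result"))
  keep <- rep(TRUE, length(psd$freqs))
  if (!is.null(exclude))
    keep <- psd$freqs < exclude[1] | psd$freqs > exclude[2]
  if (sum(keep) < 5L) stop("fewer than 5 frequencies remain after exclusion")
  lf <- log10(psd$freqs[keep])
  lp <- psd$log_power[keep]
  fit <- stats::lm(lp ~ lf)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = suppressWarnings(summary(fit)$r.squared),
                 excluded_band = exclude, n_points = sum(keep)),
            class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("<slope_fit> slope = %.3f (r2 = %.3f, %d points%s)\n",
              x$slope, x$r2, x$n_points,
              if (is.null(x$excluded_band)) "" else
                sprintf(", %g-%g Hz excluded", x$excluded_band[1],
                        x$excluded_band[2])))
  invisible(x)
}

#' Auto-sandwich a short segment
#'
#' Triples a short segment's duration while retaining its autocorrelative
#' properties, by appending time-reversed and amplitude-inverted copies at
#' both ends. Each copy is reflected about the endpoint value it attaches to,
#' so the sandwich is continuous at the joins.
#'
#' @param segment numeric vector.
#' @return numeric vector of length `3 * length(segment)`.
#' @export
auto_sandwich <- function(segment) {
  n <- length(segment)
  pre <- 2 * segment[1] - rev(segment)
  post <- 2 * segment[n] - rev(segment)
  c(pre, segment, post)
}

#' Spectral slope of a very short segment via auto-sandwiching
#'
#' For 250 ms windows a raw FFT has too little frequency resolution for a
#' stable aperiodic fit. The segment is first [auto_sandwich()]ed (tripling
#' its duration), then the PSD is computed at 45 log-spaced frequencies
#' between 2 and 90 Hz (Hanning taper, zero-padded to 10 s, 4 Hz boxcar
#' smoothing of the linear spectrum), and the slope is fit with the 5--20 Hz
#' range excluded to remove alpha-peak influence.
#'
#' @param segment numeric vector (one short window).
#' @param fs sampling rate in Hz.
#' @param exclude Hz interval excluded from the slope fit (default
#'   `c(5, 20)`).
#' @return a list with `psd` (the `psd_result`, carrying a `short_segment`
#'   warning flag when the sandwich is shorter than 3 cycles of the lowest
#'   requested frequency) and `fit` (the `slope_fit`).
#' @export
auto_sandwich_psd <- function(segment, fs, exclude = c(5, 20)) {
  sandwich <- auto_sandwich(segment)
  freqs <- 2^seq(log2(2), log2(90), length.out = 45)
  psd <- compute_psd(segment_set(sandwich, fs), freqs = freqs,
                     zero_pad_s = 10, smooth_hz = 4)
  if (length(sandwich) / fs < 3 / min(freqs))
    attr(psd, "warning") <- "short_segment"
  list(psd = psd, fit = fit_slope(psd, exclude = exclude))
}
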