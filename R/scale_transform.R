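#' Scale-wise filter cutoff frequencies
#'
#' For scale factor `tau` the scale-wise signal is bounded above by
#' `LP = (1/tau) * nyquist` and below by `HP = (1/(tau+1)) * nyquist`, with
#' nyquist = fs/2. The band-pass variant uses a narrow passband of
#' `LP +/- 0.05 * LP` centred on the low-pass bound.
#'
#' @param tau scale factor, integer >= 1.
#' @param fs sampling rate in Hz.
#' @param variant one of `"original_pointavg"`, `"lowpass"`, `"highpass"`,
#'   `"bandpass"`, `"bandstop"`.
#' @return a list with elements (as applicable) `lp_hz`, `hp_hz`, `band`
#'   (length-2 numeric, Hz) and `nyquist`.
#' @examples
#' cutoffs_for_scale(4, 250, "lowpass")$lp_hz   # 31.25
#' cutoffs_for_scale(4, 250, "highpass")$hp_hz  # 25
#' @export
cutoffs_for_scale <- function(tau, fs,
                              variant = c("lowpass", "highpass", "bandpass",
                                          "bandstop", "original_pointavg")) {
  variant <- match.arg(variant)
  tau <- as.integer(tau)
  if (is.na(tau) || tau < 1L) stop("`tau` must be an integer >= 1")
  if (fs <= 0) stop("`fs` must be > 0")
  nyq <- fs / 2
  out <- list(nyquist = nyq)
  lp <- nyq / tau
  hp <- nyq / (tau + 1)
  out$lp_hz <- switch(variant,
                      lowpass = , bandpass = , original_pointavg = lp, NULL)
  out$hp_hz <- switch(variant, highpass = hp, NULL)
  if (variant == "bandpass") out$band <- c(0.95, 1.05) * lp
  out
}

#' Design the coarse-graining filter for one scale
#'
#' Builds the zero-phase (two-pass) IIR filter used to derive the scale-`tau`
#' signal:
#' \itemize{
#'   \item lowpass: 6th-order Butterworth low-pass at `LP = nyquist/tau`
#'     (scale 1 is the identity -- the cutoff would sit at Nyquist);
#'   \item highpass: 6th-order Butterworth high-pass at `HP = nyquist/(tau+1)`;
#'   \item bandpass: sequential Chebyshev type-I low- and high-pass filters
#'     (order 4, 1 dB passband ripple) at `LP * 1.05` and `LP * 0.95`;
#'     10th-order Butterworth filters replace the Chebyshevs when the passband
#'     reaches above half the Nyquist frequency, and at scale 1 only a
#'     10th-order Butterworth high-pass is applied (the sampling rate itself
#'     sets the upper bound);
#'   \item bandstop: 6th-order Butterworth band-stop at a caller-supplied band.
#' }
#' Quoted orders are per pass; two-pass application squares the magnitude
#' response and cancels the phase delay.
#'
#' @inheritParams cutoffs_for_scale
#' @param bandstop_band length-2 numeric (Hz), required for `"bandstop"`.
#' @return an object of class `scale_filter`: a list with `stages` (each a
#'   list `b`, `a`, `family`, `order`, `type`, `cutoff_hz`), `tau`, `fs`,
#'   `variant`, `two_pass = TRUE`. The identity case has zero stages.
#' @export
design_scale_filter <- function(tau, fs,
                                variant = c("lowpass", "highpass", "bandpass",
                                            "bandstop", "original_pointavg"),
                                bandstop_band = NULL) {
  variant <- match.arg(variant)
  cf <- cutoffs_for_scale(tau, fs, variant)
  nyq <- cf$nyquist
  stages <- list()
  mk <- function(ba, family, order, type, cutoff)
    list(b = ba$b, a = ba$a, family = family, order = order, type = type,
         cutoff_hz = cutoff)
  chk_w <- function(w, what) {
    if (any(w <= 0) || any(w >= 1))
      stop(sprintf("unstable filter design at tau = %d: %s cutoff outside (0, Nyquist)",
                   tau, what))
    w
  }
  if (variant == "lowpass") {
    if (tau > 1L) {
      w <- chk_w(cf$lp_hz / nyq, "low-pass")
      stages <- list(mk(signal::butter(6, w, type = "low"),
                        "butterworth", 6L, "low", cf$lp_hz))
    }
  } else if (variant == "highpass") {
    w <- chk_w(cf$hp_hz / nyq, "high-pass")
    stages <- list(mk(signal::butter(6, w, type = "high"),
                      "butterworth", 6L, "high", cf$hp_hz))
  } else if (variant == "bandpass") {
    band <- cf$band
    if (tau == 1L) {
      w <- chk_w(band[1] / nyq, "high-pass")
      stages <- list(mk(signal::butter(10, w, type = "high"),
                        "butterworth", 10L, "high", band[1]))
    } else if (band[2] > 0.5 * nyq) {
      w_lo <- chk_w(band[2] / nyq, "low-pass")
      w_hi <- chk_w(band[1] / nyq, "high-pass")
      stages <- list(mk(signal::butter(10, w_lo, type = "low"),
                        "butterworth", 10L, "low", band[2]),
                     mk(signal::butter(10, w_hi, type = "high"),
                        "butterworth", 10L, "high", band[1]))
    } else {
      w_lo <- chk_w(band[2] / nyq, "low-pass")
      w_hi <- chk_w(band[1] / nyq, "high-pass")
      stages <- list(mk(signal::cheby1(4, 1, w_lo, type = "low"),
                        "chebyshev1", 4L, "low", band[2]),
                     mk(signal::cheby1(4, 1, w_hi, type = "high"),
                        "chebyshev1", 4L, "high", band[1]))
    }
  } else if (variant == "bandstop") {
    if (is.null(bandstop_band) || length(bandstop_band) != 2L)
      stop("`bandstop_band` (length-2, Hz) required for the bandstop variant")
    w <- chk_w(sort(bandstop_band) / nyq, "band-stop")
    stages <- list(mk(signal::butter(6, w, type = "stop"),
                      "butterworth", 6L, "stop", sort(bandstop_band)))
  } # original_pointavg: no filter stages
  structure(list(stages = stages, tau = as.integer(tau), fs = fs,
                 variant = variant, two_pass = TRUE, cutoffs = cf),
            class = "scale_filter")
}

#' Frequency response of a designed scale filter
#'
#' Effective (two-pass) amplitude response of all cascaded stages.
#'
#' @param filt a `scale_filter`.
#' @param f_hz frequencies at which to evaluate (Hz).
#' @return numeric vector of amplitude gains at `f_hz`.
#' @export
filter_gain <- function(filt, f_hz) {
  stopifnot(inherits(filt, "scale_filter"))
  w <- pi * f_hz / (filt$fs / 2)
  g <- rep(1, length(w))
  z <- exp(1i * w)
  for (st in filt$stages) {
    h <- vapply(z, function(zz)
      sum(st$b * zz^-(seq_along(st$b) - 1)) /
        sum(st$a * zz^-(seq_along(st$a) - 1)), complex(1))
    g <- g * Mod(h)^2 # two-pass squares the magnitude
  }
  g
}

#' Symmetric mean padding
#'
#' Prepends and appends `pad_samples` copies of the segment mean; used before
#' zero-phase filtering so that edge transients fall into the padding, which
#' is removed afterwards. The default padding is half the segment length.
#'
#' @param segment numeric vector.
#' @param pad_samples number of samples to add at each end (>= 0).
#' @return padded numeric vector of length `length(segment) + 2 * pad_samples`.
#' @examples
#' pad_symmetric_mean(c(1, 2, 3), 2) # 2 2 1 2 3 2 2
#' @export
pad_symmetric_mean <- function(segment, pad_samples = floor(length(segment) / 2)) {
  pad_samples <- as.integer(pad_samples)
  if (pad_samples < 0L) stop("`pad_samples` must be >= 0")
  if (pad_samples == 0L) return(segment)
  pad <- rep(mean(segment), pad_samples)
  c(pad, segment, pad)
}

#' Point averaging (classic coarse-graining)
#'
#' Averages samples within non-overlapping bins of `tau` samples; the trailing
#' partial bin is dropped. `tau = 1` is the identity.
#'
#' @param segment numeric vector.
#' @param tau bin width in samples (integer >= 1).
#' @return numeric vector of length `floor(length(segment)/tau)`.
#' @examples
#' point_average(1:9, 3) # 2 5 8
#' @export
point_average <- function(segment, tau) {
  tau <- as.integer(tau)
  if (tau < 1L) stop("`tau` must be >= 1")
  if (tau == 1L) return(as.numeric(segment))
  n_bins <- floor(length(segment) / tau)
  if (n_bins == 0L) stop("segment shorter than one bin")
  colMeans(matrix(segment[seq_len(n_bins * tau)], nrow = tau))
}

# two-pass (forward-backward) application of one biquad-cascade stage set
apply_scale_filter <- function(x, filt) {
  for (st in filt$stages) {
    x <- as.numeric(signal::filter(st$b, st$a, x))
    x <- rev(as.numeric(signal::filter(st$b, st$a, rev(x))))
  }
  x
}

#' Filter-then-skip coarse-graining of one segment
#'
#' Derives the scale-`tau` sub-series of a segment: symmetric mean padding,
#' two-pass scale filter, padding removal, then point skipping. For the
#' low-pass variant every `tau`-th sample is kept, once per starting offset
#' `k = 1..tau`, yielding `tau` sub-series whose match counts are later
#' pooled (refined-composite counting). The high-pass and band-stop variants
#' keep the full-rate filtered series (down-sampling would re-impose a
#' low-pass characteristic), as does the band-pass variant: its passband
#' reaches `1.05 * LP`, above the Nyquist frequency `LP` of the decimated
#' series, so skipping would alias the upper half of the band and scramble
#' the frequency-to-scale mapping the narrowband estimator exists for.
#' `original_pointavg` bin-averages instead of filtering.
#'
#' @param segment numeric vector.
#' @param scale_filter a [design_scale_filter()] result.
#' @param pad_samples padding per end; default half the segment length.
#' @return list of numeric sub-series (length `tau` for lowpass, length 1
#'   otherwise).
#' @export
filt_skip <- function(segment, scale_filter,
                      pad_samples = floor(length(segment) / 2)) {
  stopifnot(inherits(scale_filter, "scale_filter"))
  tau <- scale_filter$tau
  variant <- scale_filter$variant
  if (variant == "original_pointavg")
    return(list(point_average(segment, tau)))
  n <- length(segment)
  padded <- pad_symmetric_mean(segment, pad_samples)
  filtered <- apply_scale_filter(padded, scale_filter)
  filtered <- filtered[(pad_samples + 1):(pad_samples + n)]
  if (variant %in% c("highpass", "bandpass", "bandstop"))
    return(list(filtered))
  lapply(seq_len(tau), function(k) filtered[seq(k, n, by = tau)])
}
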