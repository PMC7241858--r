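#' Morlet wavelet time-frequency transform
#'
#' Complex Morlet convolution at log-spaced center frequencies; power is the
#' squared magnitude. The wavelet envelope SD is `cycles / (2 * pi * f)`, so
#' temporal smoothing spans a fixed number of cycles at every frequency.
#' Samples within three envelope SDs of either segment edge are flagged as
#' edge-contaminated per frequency.
#'
#' @param segment numeric vector.
#' @param fs sampling rate in Hz.
#' @param freqs center frequencies in Hz; default 49 log-spaced between 1 and
#'   64 Hz.
#' @param cycles wavelet width in cycles (default 5).
#' @return an object of class `tfr`: list with `power` (freq x time matrix),
#'   `freqs`, `fs`, `cycles`, `edge` (per-frequency number of
#'   edge-contaminated samples at each end), `valid` (logical freq x time
#'   matrix), `n_time`.
#' @export
wavelet_tfr <- function(segment, fs,
                        freqs = 2^seq(log2(1), log2(64), length.out = 49),
                        cycles = 5) {
  n <- length(segment)
  nf <- length(freqs)
  power <- matrix(NA_real_, nf, n)
  edge <- integer(nf)
  valid <- matrix(FALSE, nf, n)
  X <- stats::fft(c(segment, rep(0, n))) # zero-pad to 2n for linear conv
  n2 <- 2L * n
  t2 <- c(0:(n2 %/% 2), -((n2 - n2 %/% 2 - 1):1)) / fs
  for (i in seq_len(nf)) {
    f <- freqs[i]
    sigma_t <- cycles / (2 * pi * f)
    support <- 4 * sigma_t
    if (2 * support >= n / fs) next # too short at this frequency: row flagged
    w <- exp(-t2^2 / (2 * sigma_t^2)) * exp(2i * pi * f * t2)
    w <- w / sqrt(sum(Mod(w)^2)) # unit-energy wavelet
    conv <- stats::fft(X * stats::fft(w), inverse = TRUE) / n2
    power[i, ] <- Mod(conv[seq_len(n)])^2
    edge[i] <- min(n, as.integer(ceiling(3 * sigma_t * fs)))
    if (n > 2 * edge[i])
      valid[i, (edge[i] + 1):(n - edge[i])] <- TRUE
  }
  structure(list(power = power, freqs = freqs, fs = fs, cycles = cycles,
                 edge = edge, valid = valid, n_time = n), class = "tfr")
}

#' Fit the 1/f background of a wavelet spectrum and derive power thresholds
#'
#' Classic BOSC-style background estimate: the time-averaged wavelet power
#' (valid samples only, pooled over trials) is regressed on frequency in
#' log-log space across all frequencies; the detection threshold per
#' frequency is the 95th percentile of the chi-square (2 df) distribution
#' scaled to the fitted background mean -- the distribution wavelet power of
#' Gaussian noise follows, which fixes the false-alarm rate near 5%.
#'
#' @param tfrs a `tfr` or list of `tfr`s over the same frequencies.
#' @param percentile detection percentile (default 0.95).
#' @param exclude_peak optional Hz interval to exclude from the background
#'   fit (e.g. a known rhythmic peak); default `NULL` fits all frequencies.
#' @return list of class `bosc_background`: `freqs`, `background` (fitted
#'   mean power), `threshold`, `slope` (log10/log10), `percentile`.
#' @export
fit_background <- function(tfrs, percentile = 0.95, exclude_peak = NULL) {
  if (inherits(tfrs, "tfr")) tfrs <- list(tfrs)
  freqs <- tfrs[[1]]$freqs
  total_s <- sum(vapply(tfrs, function(x) x$n_time, integer(1))) / tfrs[[1]]$fs
  if (total_s < 30)
    warning("background fit on less than 30 s of data; estimate may be unstable")
  mean_pow <- rowMeans(vapply(tfrs, function(x) {
    p <- x$power
    p[!x$valid] <- NA
    rowMeans(p, na.rm = TRUE)
  }, numeric(length(freqs))), na.rm = TRUE)
  keep <- is.finite(mean_pow) & mean_pow > 0
  if (!is.null(exclude_peak))
    keep <- keep & (freqs < exclude_peak[1] | freqs > exclude_peak[2])
  if (sum(keep) < 3L) stop("degenerate background fit")
  fit <- stats::lm(log10(mean_pow[keep]) ~ log10(freqs[keep]))
  bg <- 10^(stats::coef(fit)[1] + stats::coef(fit)[2] * log10(freqs))
  structure(list(freqs = freqs, background = unname(bg),
                 threshold = unname(bg * stats::qchisq(percentile, df = 2) / 2),
                 slope = unname(stats::coef(fit)[2]), percentile = percentile),
            class = "bosc_background")
}

#' Detect rhythmic episodes in a wavelet transform
#'
#' Per frequency row, contiguous runs of supra-threshold power lasting at
#' least `min_cycles` cycles become candidate episodes; candidates that
#' overlap in time at adjacent center frequencies are grouped, and each group
#' is reduced to the candidate carrying maximal power (a simplified
#' merge -- the full episode-sparsification of extended BOSC is intentionally
#' not reproduced). The episode frequency is the power-weighted mean over the
#' group.
#'
#' @param tfr a [wavelet_tfr()] result.
#' @param background a [fit_background()] result on compatible frequencies.
#' @param min_cycles minimum episode duration in cycles (default 1).
#' @return data.frame (possibly empty) with columns `mean_freq`, `onset`,
#'   `offset` (sample indices, half-open), `duration_cycles`,
#'   `mean_amplitude` (mean wavelet amplitude, sqrt power).
#' @export
detect_episodes <- function(tfr, background, min_cycles = 1) {
  stopifnot(inherits(tfr, "tfr"), inherits(background, "bosc_background"))
  if (length(tfr$freqs) != length(background$freqs))
    stop("tfr and background have different frequency grids")
  cand <- list()
  for (i in seq_along(tfr$freqs)) {
    p <- tfr$power[i, ]
    if (all(is.na(p))) next
    above <- !is.na(p) & p > background$threshold[i]
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    min_len <- min_cycles / tfr$freqs[i] * tfr$fs
    for (k in which(r$values & r$lengths >= min_len)) {
      cand[[length(cand) + 1L]] <- list(
        fi = i, onset = starts[k], offset = ends[k] + 1L,
        mean_pow = mean(p[starts[k]:ends[k]]))
    }
  }
  empty <- data.frame(mean_freq = numeric(0), onset = integer(0),
                      offset = integer(0), duration_cycles = numeric(0),
                      mean_amplitude = numeric(0))
  if (length(cand) == 0L) return(empty)
  # group candidates overlapping in time at adjacent frequency rows
  nc <- length(cand)
  comp <- seq_len(nc)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (a in seq_len(nc - 1L)) for (b in (a + 1L):nc) {
    if (abs(cand[[a]]$fi - cand[[b]]$fi) > 1L) next
    if (cand[[a]]$onset < cand[[b]]$offset && cand[[b]]$onset < cand[[a]]$offset) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) comp[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(nc), find, integer(1))
  out <- lapply(unique(roots), function(r0) {
    members <- cand[roots == r0]
    pows <- vapply(members, `[[`, numeric(1), "mean_pow")
    best <- members[[which.max(pows)]]
    mean_freq <- sum(tfr$freqs[vapply(members, `[[`, integer(1), "fi")] * pows) /
      sum(pows)
    # refine the edges at half-maximal amplitude (quarter-maximal power): the
    # wavelet's temporal smoothing pushes the absolute-threshold crossings
    # outward by a sizable fraction of its support, while a smoothed step
    # edge passes through half its plateau amplitude at the true boundary
    p <- tfr$power[best$fi, best$onset:(best$offset - 1L)]
    core <- which(p >= 0.25 * max(p))
    onset <- best$onset + core[1] - 1L
    offset <- best$onset + core[length(core)]
    dur_cycles <- (offset - onset) / tfr$fs * mean_freq
    data.frame(mean_freq = mean_freq, onset = onset, offset = offset,
               duration_cycles = dur_cycles,
               mean_amplitude = sqrt(mean(p[core[1]:core[length(core)]])))
  })
  do.call(rbind, out)
}

#' Episode rate per center frequency
#'
#' Counts detected episodes of at least `min_cycles` cycles whose mean
#' frequency falls within a moving window of `width` adjacent center
#' frequencies, normalised per unit time.
#'
#' @param episodes an episode data.frame (possibly pooled over trials).
#' @param freqs the center-frequency grid.
#' @param total_time total analysed duration in seconds (for normalisation);
#'   use `NULL` for raw counts.
#' @param min_cycles duration criterion in cycles (default 3).
#' @param width window width in center frequencies (odd, default 3).
#' @return data.frame with `freq` and `rate` (episodes per second, or counts).
#' @export
episode_rate <- function(episodes, freqs, total_time = NULL, min_cycles = 3,
                         width = 3) {
  half <- (width - 1L) %/% 2L
  keep <- episodes[episodes$duration_cycles >= min_cycles, , drop = FALSE]
  rate <- vapply(seq_along(freqs), function(i) {
    lo <- freqs[max(1L, i - half)]
    hi <- freqs[min(length(freqs), i + half)]
    sum(keep$mean_freq >= lo & keep$mean_freq <= hi)
  }, numeric(1))
  if (!is.null(total_time)) rate <- rate / total_time
  data.frame(freq = freqs, rate = rate)
}

# Zero-phase band filtering with sandwich-extension padding: the signal is
# continued at both ends by time-reversed, amplitude-inverted copies (the
# same continuity-preserving extension as auto_sandwich), so that narrowband
# content crosses the edges smoothly and stop-band ringing at segment
# boundaries is minimal -- this matters for 250 ms windows.
band_filter_signal <- function(x, fs, band, type, order = 6) {
  nyq <- fs / 2
  ba <- switch(type,
               low = signal::butter(order, band / nyq, type = "low"),
               pass = signal::butter(order, band / nyq, type = "pass"),
               stop = signal::butter(order, band / nyq, type = "stop"))
  n <- length(x)
  xp <- auto_sandwich(x)
  xp <- as.numeric(signal::filter(ba$b, ba$a, xp))
  xp <- rev(as.numeric(signal::filter(ba$b, ba$a, rev(xp))))
  xp[(n + 1):(2 * n)]
}

#' Trough-locked average waveform of detected episodes
#'
#' For every qualifying episode, the trough is the local minimum of the
#' band-filtered signal nearest the episode's wavelet-power maximum; raw
#' signal snippets aligned on those troughs are averaged. Band filtering is
#' used only for trough localisation, never for the averaged waveform.
#'
#' @param segment raw numeric signal the episodes were detected on.
#' @param fs sampling rate in Hz.
#' @param episodes episode data.frame from [detect_episodes()].
#' @param band `"alpha"` (low-pass 25 Hz, min 3 cycles) or `"beta"`
#'   (band-pass 10--25 Hz, min 1 cycle).
#' @param snippet_s half-width of the averaged snippet in seconds.
#' @return list with `waveform` (average), `lag_s` (time axis, trough at 0),
#'   `n_events`, `trough_lags_s` (per-event trough offset from the power
#'   maximum, seconds); `NULL` waveform with `n_events = 0` when no episode
#'   qualifies.
#' @export
trough_lock_average <- function(segment, fs, episodes, band = c("alpha", "beta"),
                                snippet_s = 0.4) {
  band <- match.arg(band)
  min_cycles <- if (band == "alpha") 3 else 1
  filtered <- if (band == "alpha")
    band_filter_signal(segment, fs, 25, "low")
  else band_filter_signal(segment, fs, c(10, 25), "pass")
  eps <- episodes[episodes$duration_cycles >= min_cycles, , drop = FALSE]
  if (nrow(eps) == 0L)
    return(list(waveform = NULL, lag_s = NULL, n_events = 0L,
                trough_lags_s = numeric(0)))
  half <- as.integer(round(snippet_s * fs))
  snippets <- list(); lags <- numeric(0)
  for (e in seq_len(nrow(eps))) {
    on <- eps$onset[e]; off <- eps$offset[e] - 1L
    # wavelet power at the episode frequency, maximum inside the episode
    pw <- Mod(morlet_row(segment, fs, eps$mean_freq[e]))^2
    pk <- on - 1L + which.max(pw[on:off])
    idx <- on:off
    is_min <- filtered[idx] < c(Inf, filtered[idx[-length(idx)]]) &
      filtered[idx] < c(filtered[idx[-1]], Inf)
    mins <- idx[is_min]
    if (length(mins) == 0L) next
    trough <- mins[which.min(abs(mins - pk))]
    if (trough - half < 1L || trough + half > length(segment)) next
    snippets[[length(snippets) + 1L]] <- segment[(trough - half):(trough + half)]
    lags <- c(lags, (trough - pk) / fs)
  }
  if (length(snippets) == 0L)
    return(list(waveform = NULL, lag_s = NULL, n_events = 0L,
                trough_lags_s = numeric(0)))
  list(waveform = Reduce(`+`, snippets) / length(snippets),
       lag_s = seq(-half, half) / fs, n_events = length(snippets),
       trough_lags_s = lags)
}

morlet_row <- function(segment, fs, f, cycles = 5) {
  n <- length(segment)
  n2 <- 2L * n
  t2 <- c(0:(n2 %/% 2), -((n2 - n2 %/% 2 - 1):1)) / fs
  sigma_t <- cycles / (2 * pi * f)
  w <- exp(-t2^2 / (2 * sigma_t^2)) * exp(2i * pi * f * t2)
  w <- w / sqrt(sum(Mod(w)^2))
  conv <- stats::fft(stats::fft(c(segment, rep(0, n))) * stats::fft(w),
                     inverse = TRUE) / n2
  conv[seq_len(n)]
}

#' Sample entropy in 250 ms windows around episode on- and offsets
#'
#' For every episode of at least `min_cycles` cycles, four windows are cut:
#' `pre_onset` and `post_onset` around the onset, `pre_offset` and
#' `post_offset` around the offset (each `window` seconds, half-open at the
#' event boundary). Scale-1 sample entropy (scale-wise bound, m = 2, r = 0.5
#' by default) is computed per window, optionally after band-stop filtering
#' the whole signal first -- the circularity control that removes the
#' rhythm's own regularity from the broadband estimate. Events are labelled
#' high/low by a median split on episode amplitude.
#'
#' @param segment raw numeric signal.
#' @param fs sampling rate in Hz.
#' @param episodes episode data.frame from [detect_episodes()].
#' @param window window length in seconds (default 0.25).
#' @param bandstop optional length-2 Hz band (e.g. `c(8, 15)`) removed with a
#'   two-pass 6th-order Butterworth band-stop before entropy; `NULL` skips.
#' @param min_cycles episode duration criterion (default 3).
#' @param m,r sample entropy parameters.
#' @return data.frame with one row per usable event: `mean_freq`,
#'   `amplitude`, `amplitude_class` (`"high"`/`"low"` median split),
#'   `pre_onset`, `post_onset`, `pre_offset`, `post_offset` (nats),
#'   `within` (mean of the two inside-event windows), `outside` (mean of the
#'   two outside windows), `bandstop` (logical). Events whose windows leave
#'   the recording are skipped.
#' @export
event_window_entropy <- function(segment, fs, episodes, window = 0.25,
                                 bandstop = NULL, min_cycles = 3,
                                 m = 2L, r = 0.5) {
  w <- as.integer(round(window * fs))
  sig <- if (is.null(bandstop)) segment
  else band_filter_signal(segment, fs, sort(bandstop), "stop")
  eps <- episodes[episodes$duration_cycles >= min_cycles, , drop = FALSE]
  rows <- list()
  if (nrow(eps) > 0L) for (e in seq_len(nrow(eps))) {
    on <- eps$onset[e]; off <- eps$offset[e]
    if (on - w < 1L || off + w - 1L > length(sig)) next
    win <- list(pre_onset = sig[(on - w):(on - 1L)],
                post_onset = sig[on:(on + w - 1L)],
                pre_offset = sig[(off - w):(off - 1L)],
                post_offset = sig[off:(off + w - 1L)])
    ent <- vapply(win, function(x)
      as.numeric(sample_entropy(x, m = m, r = r, fs = fs)), numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      mean_freq = eps$mean_freq[e], amplitude = eps$mean_amplitude[e],
      pre_onset = ent[["pre_onset"]], post_onset = ent[["post_onset"]],
      pre_offset = ent[["pre_offset"]], post_offset = ent[["post_offset"]])
  }
  if (length(rows) == 0L)
    return(data.frame(mean_freq = numeric(0), amplitude = numeric(0),
                      amplitude_class = character(0), pre_onset = numeric(0),
                      post_onset = numeric(0), pre_offset = numeric(0),
                      post_offset = numeric(0), within = numeric(0),
                      outside = numeric(0), bandstop = logical(0)))
  out <- do.call(rbind, rows)
  out$amplitude_class <- ifelse(out$amplitude >= stats::median(out$amplitude),
                                "high", "low")
  out$within <- (out$post_onset + out$pre_offset) / 2
  out$outside <- (out$pre_onset + out$post_offset) / 2
  out$bandstop <- !is.null(bandstop)
  out[, c("mean_freq", "amplitude", "amplitude_class", "pre_onset",
          "post_onset", "pre_offset", "post_offset", "within", "outside",
          "bandstop")]
}
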