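#' Frequency labels for scale factors
#'
#' Entropy at a scale is interpretable only relative to the spectral content
#' of the scale-wise signal, so scales are labelled in Hz: the upper (Nyquist)
#' bound `LP = nyquist/tau` for the low-/band-pass (and point-averaging)
#' variants, and the lower bound `HP = nyquist/(tau+1)` for the high-pass
#' variant.
#'
#' @param taus integer vector of scale factors.
#' @param fs sampling rate in Hz.
#' @param variant coarse-graining variant (see [cutoffs_for_scale()]).
#' @return numeric vector of Hz labels, strictly decreasing in `tau`.
#' @examples
#' scale_frequency_labels(c(1, 12), 500, "lowpass") # 250, 250/12
#' @export
scale_frequency_labels <- function(taus, fs,
                                   variant = c("lowpass", "highpass",
                                               "bandpass", "bandstop",
                                               "original_pointavg")) {
  variant <- match.arg(variant)
  nyq <- fs / 2
  if (variant == "highpass") nyq / (taus + 1) else nyq / taus
}

#' Modified multiscale sample entropy
#'
#' Computes the multiscale entropy curve of a [segment_set()]: for every scale
#' factor the signal is coarse-grained by the chosen filter variant
#' ([filt_skip()]), the similarity bound is set by the chosen policy, template
#' matches are counted across all point-skipping offsets and all segments, and
#' sample entropy is taken on the summed counts (refined-composite counting
#' across discontinuous epochs).
#'
#' The two bound policies are the crux of the estimator:
#' \describe{
#'   \item{`"scalewise"`}{bound = `r` x SD of the scale-wise signal itself
#'     (concatenated over offsets and segments), normalising entropy for the
#'     variance that scale-wise filtering removes.}
#'   \item{`"global"`}{bound = `r` x SD of the original broadband signal,
#'     the classic convention; at coarse scales the bound becomes liberal
#'     relative to the shrinking scale-wise SD, biasing entropy downward and
#'     coupling it to spectral power.}
#' }
#'
#' @param data a [segment_set()], or matrix/list/vector plus `fs`.
#' @param taus integer vector of scale factors (default 1:42).
#' @param variant coarse-graining variant: `"lowpass"` (default),
#'   `"highpass"`, `"bandpass"`, `"bandstop"`, `"original_pointavg"`.
#' @param policy `"scalewise"` (default) or `"global"` similarity bound.
#' @param m template length (default 2).
#' @param r bound fraction of SD (default 0.5).
#' @param fs sampling rate (only when `data` is not a segment_set).
#' @param bandstop_band length-2 Hz band for the bandstop variant.
#' @param pad_samples padding per end for filtering; default half segment
#'   length.
#' @return an object of class `mmse_result`: a data.frame with columns
#'   `tau`, `entropy` (nats; NA where flagged), `bound`, `scale_sd`,
#'   `label_hz`, `flag` (`"ok"`, `"undefined"`, `"insufficient"`,
#'   `"degenerate"`), `interpolated`, plus attributes `params` (m, r),
#'   `variant`, `policy`, `fs`.
#' @examples
#' set.seed(7)
#' ss <- segment_set(matrix(rnorm(4 * 500), nrow = 4), fs = 250)
#' res <- compute_mmse(ss, taus = c(1, 2, 4), variant = "lowpass")
#' res$entropy
#' @export
compute_mmse <- function(data, taus = 1:42,
                         variant = c("lowpass", "highpass", "bandpass",
                                     "bandstop", "original_pointavg"),
                         policy = c("scalewise", "global"),
                         m = 2L, r = 0.5, fs = NULL,
                         bandstop_band = c(8, 15), pad_samples = NULL) {
  variant <- match.arg(variant)
  policy <- match.arg(policy)
  ss <- as_segment_set(data, fs)
  taus <- as.integer(taus)
  if (length(taus) == 0L || any(is.na(taus)) || any(taus < 1L))
    stop("`taus` must be a non-empty vector of integers >= 1")
  m <- as.integer(m)
  broadband_sd <- stats::sd(concat_segments(ss))
  n_scales <- length(taus)
  entropy <- bound <- scale_sd <- rep(NA_real_, n_scales)
  flag <- rep("ok", n_scales)
  for (i in seq_len(n_scales)) {
    tau <- taus[i]
    filt <- try(design_scale_filter(tau, ss$fs, variant, bandstop_band),
                silent = TRUE)
    if (inherits(filt, "try-error")) { flag[i] <- "insufficient"; next }
    subs <- list()
    for (seg in ss$segments) {
      ps <- if (is.null(pad_samples)) floor(length(seg) / 2) else pad_samples
      subs <- c(subs, filt_skip(seg, filt, pad_samples = ps))
    }
    subs <- subs[lengths(subs) > m + 1L]
    if (length(subs) == 0L) { flag[i] <- "insufficient"; next }
    scale_sd[i] <- stats::sd(unlist(subs, use.names = FALSE))
    if (!is.finite(scale_sd[i]) || scale_sd[i] == 0) {
      flag[i] <- "degenerate"; next
    }
    bound[i] <- similarity_bound(
      if (policy == "global") broadband_sd else scale_sd[i], r)
    pm <- 0; pm1 <- 0
    for (s in subs) {
      cnt <- count_matches_cpp(s, m, bound[i])
      pm <- pm + cnt$pm
      pm1 <- pm1 + cnt$pm1
    }
    e <- entropy_from_counts(pm, pm1)
    if (is.na(e)) flag[i] <- attr(e, "flag") else entropy[i] <- e
  }
  res <- data.frame(tau = taus, entropy = entropy, bound = bound,
                    scale_sd = scale_sd,
                    label_hz = scale_frequency_labels(taus, ss$fs, variant),
                    flag = flag, interpolated = FALSE,
                    stringsAsFactors = FALSE)
  structure(res, params = list(m = m, r = r), variant = variant,
            policy = policy, fs = ss$fs,
            class = c("mmse_result", "data.frame"))
}

#' @export
print.mmse_result <- function(x, ...) {
  cat(sprintf("<mmse_result> variant = %s, policy = %s, m = %d, r = %g, fs = %g Hz\n",
              attr(x, "variant"), attr(x, "policy"),
              attr(x, "params")$m, attr(x, "params")$r, attr(x, "fs")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Spline-interpolate an entropy curve onto a denser scale grid
#'
#' When scale factors are computed in coarse steps (e.g. every third scale)
#' the curve can be interpolated with a cubic spline over `tau`. Scales
#' flagged missing are excluded from the fit; interpolated rows are marked.
#'
#' @param result an [compute_mmse()] result with >= 4 valid scales.
#' @param target_taus integer scales to interpolate to; must lie inside the
#'   computed range (no extrapolation).
#' @return an `mmse_result` on `target_taus`; computed scales keep their
#'   exact values, new scales have `interpolated = TRUE` and NA bound/SD.
#' @export
interpolate_scales <- function(result, target_taus) {
  stopifnot(inherits(result, "mmse_result"))
  ok <- result$flag == "ok" & !is.na(result$entropy)
  if (sum(ok) < 4L) stop("need at least 4 valid scales for spline interpolation")
  target_taus <- as.integer(target_taus)
  rng <- range(result$tau[ok])
  if (any(target_taus < rng[1] | target_taus > rng[2]))
    stop("extrapolation outside the computed scale range is not supported")
  sf <- stats::splinefun(result$tau[ok], result$entropy[ok], method = "fmm")
  have <- match(target_taus, result$tau)
  out <- data.frame(
    tau = target_taus,
    entropy = ifelse(!is.na(have) & ok[pmax(have, 1L)], result$entropy[have],
                     sf(target_taus)),
    bound = ifelse(!is.na(have), result$bound[have], NA_real_),
    scale_sd = ifelse(!is.na(have), result$scale_sd[have], NA_real_),
    label_hz = scale_frequency_labels(target_taus, attr(result, "fs"),
                                      attr(result, "variant")),
    flag = ifelse(!is.na(have), result$flag[have], "ok"),
    interpolated = is.na(have) | !ok[ifelse(is.na(have), 1L, have)],
    stringsAsFactors = FALSE)
  # a flagged computed scale gets the spline value too, marked interpolated
  redo <- !is.na(have) & !ok[ifelse(is.na(have), 1L, have)]
  out$entropy[redo] <- sf(target_taus[redo])
  attributes(out)[c("params", "variant", "policy", "fs")] <-
    attributes(result)[c("params", "variant", "policy", "fs")]
  class(out) <- c("mmse_result", "data.frame")
  out
}
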