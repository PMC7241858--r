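#' Absolute similarity bound from a standard deviation
#'
#' Sample entropy discretises continuous amplitudes by treating two values as
#' equal when they differ by no more than an absolute tolerance, conventionally
#' expressed as a fraction `r` of the signal standard deviation.
#'
#' @param sd standard deviation of the reference signal (signal units, >= 0).
#' @param r bound fraction (unitless, > 0); 0.5 is the default used throughout
#'   this package.
#' @return the absolute similarity bound `r * sd` in signal units.
#' @examples
#' similarity_bound(2.4, 0.5) # 1.2
#' @export
similarity_bound <- function(sd, r = 0.5) {
  if (!is.numeric(sd) || length(sd) != 1L || is.na(sd) || sd < 0)
    stop("`sd` must be a single non-negative number")
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r <= 0)
    stop("`r` must be a single positive number")
  r * sd
}

#' Entropy parameters
#'
#' Bundles the embedding length `m`, the bound fraction `r` and the absolute
#' similarity bound. When `sd` is given the bound is derived as `r * sd`.
#'
#' @param m embedding (template) length in samples, integer >= 1. Default 2.
#' @param r bound fraction of SD, > 0. Default 0.5.
#' @param bound absolute similarity tolerance in signal units; computed from
#'   `sd` when omitted.
#' @param sd reference-signal standard deviation used to derive `bound`.
#' @return a list of class `entropy_params` with fields `m`, `r`, `bound`.
#' @export
entropy_params <- function(m = 2L, r = 0.5, bound = NULL, sd = NULL) {
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("`m` must be an integer >= 1")
  if (!is.numeric(r) || r <= 0) stop("`r` must be > 0")
  if (is.null(bound)) {
    if (is.null(sd)) stop("supply either `bound` or `sd`")
    bound <- similarity_bound(sd, r)
  }
  if (bound < 0) stop("`bound` must be >= 0")
  structure(list(m = m, r = r, bound = bound), class = "entropy_params")
}

#' Count template-pattern matches in one segment
#'
#' Counts ordered pairs of m-length amplitude patterns that match within an
#' absolute tolerance (Chebyshev / max-norm distance), and how many of those
#' pairs still match when extended by one sample. Only templates that admit an
#' (m+1)-th continuation enter either count, so `pm1 <= pm` always holds;
#' self-matches are excluded (Richman-Moorman convention).
#'
#' @param segment numeric vector, length > m + 1.
#' @param m template length (integer >= 1).
#' @param bound absolute similarity tolerance (>= 0).
#' @return a list with integer-valued counts `pm` (m-length matches) and
#'   `pm1` ((m+1)-length matches).
#' @examples
#' count_matches(rep(1, 6), m = 2, bound = 0.1) # pm = pm1 = 12
#' @export
count_matches <- function(segment, m = 2L, bound) {
  segment <- as.numeric(segment)
  m <- as.integer(m)
  if (m < 1L) stop("`m` must be >= 1")
  if (bound < 0) stop("`bound` must be >= 0")
  if (length(segment) <= m + 1L)
    stop(sprintf("insufficient data: segment of length %d cannot host m = %d templates with continuation",
                 length(segment), m))
  count_matches_cpp(segment, m, bound)
}

#' Sample entropy across (possibly discontinuous) segments
#'
#' Estimates sample entropy SampEn(m, r) = ln(pm / pm1), where pm and pm1 are
#' the match counts summed over all segments of a [segment_set()]. Summing
#' counts before taking the log ratio lets short epochs contribute jointly to
#' one estimate without any template spanning an epoch boundary.
#'
#' When `bound` is not supplied it defaults to `r` times the SD of the
#' concatenation of all segments. No demeaning or detrending is applied:
#' callers control preprocessing.
#'
#' @param data a [segment_set()], numeric vector, matrix (rows = segments) or
#'   list of numeric vectors.
#' @param m template length (default 2).
#' @param r bound fraction of SD (default 0.5); ignored when `bound` is given.
#' @param bound absolute similarity tolerance in signal units.
#' @param fs sampling rate, only needed to build a segment_set from raw input.
#' @return a single numeric value (nats). Degenerate inputs yield `NA` with an
#'   attribute `flag` (`"undefined"` when no (m+1)-length matches exist,
#'   `"degenerate"` for zero-variance input) rather than an error, so that
#'   multi-scale curves can contain gaps.
#' @examples
#' set.seed(1)
#' sample_entropy(rnorm(500), m = 2, r = 0.5, fs = 100)
#' @export
sample_entropy <- function(data, m = 2L, r = 0.5, bound = NULL, fs = 1) {
  ss <- as_segment_set(data, fs)
  pooled <- concat_segments(ss)
  if (is.null(bound)) {
    s <- stats::sd(pooled)
    if (s == 0) return(flagged_na("degenerate"))
    bound <- similarity_bound(s, r)
  }
  if (stats::sd(pooled) == 0 && bound == 0) return(flagged_na("degenerate"))
  usable <- lengths(ss$segments) > m + 1L
  if (!any(usable))
    stop("insufficient data: no segment longer than m + 1")
  pm <- 0; pm1 <- 0
  for (seg in ss$segments[usable]) {
    cnt <- count_matches_cpp(seg, as.integer(m), bound)
    pm <- pm + cnt$pm
    pm1 <- pm1 + cnt$pm1
  }
  entropy_from_counts(pm, pm1)
}

entropy_from_counts <- function(pm, pm1) {
  if (pm1 == 0) return(flagged_na("undefined"))
  log(pm / pm1)
}

flagged_na <- function(reason) structure(NA_real_, flag = reason)
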