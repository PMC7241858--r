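#' Construct a set of equal-rate signal segments
#'
#' A `segment_set` is the unit that entropy is estimated on: an ordered
#' collection of real-valued segments sharing one sampling rate. Segments are
#' treated as mutually discontinuous -- no template pattern ever spans a
#' segment boundary -- which is what makes estimation across epoched
#' ("pseudo-trial") recordings possible.
#'
#' @param x a numeric vector (one segment), a numeric matrix
#'   (rows = segments), or a list of numeric vectors.
#' @param fs sampling rate in Hz (> 0).
#' @return an object of class `segment_set`: a list with elements
#'   `segments` (list of numeric vectors) and `fs`.
#' @examples
#' ss <- segment_set(matrix(rnorm(200), nrow = 2), fs = 100)
#' length(ss$segments)
#' @export
segment_set <- function(x, fs) {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number (Hz)")
  segments <- if (is.matrix(x)) {
    lapply(seq_len(nrow(x)), function(i) as.numeric(x[i, ]))
  } else if (is.list(x)) {
    lapply(x, as.numeric)
  } else if (is.numeric(x)) {
    list(as.numeric(x))
  } else stop("`x` must be a numeric vector, matrix or list of vectors")
  if (length(segments) == 0L) stop("no segments supplied")
  bad <- vapply(segments, function(s) any(!is.finite(s)), logical(1))
  if (any(bad)) stop("segment(s) ", paste(which(bad), collapse = ", "),
                     " contain non-finite values")
  structure(list(segments = segments, fs = fs), class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  lens <- lengths(x$segments)
  cat(sprintf("<segment_set> %d segment(s) @ %g Hz, lengths %s\n",
              length(x$segments), x$fs,
              if (length(unique(lens)) == 1L) as.character(lens[1])
              else paste0(min(lens), "-", max(lens))))
  invisible(x)
}

as_segment_set <- function(x, fs = NULL) {
  if (inherits(x, "segment_set")) return(x)
  if (is.null(fs)) stop("`fs` required when input is not a segment_set")
  segment_set(x, fs)
}

#' Apply a function to every segment
#'
#' @param x a `segment_set`.
#' @param f function mapping a numeric vector to a numeric vector.
#' @param ... passed on to `f`.
#' @return a `segment_set` with transformed segments (same `fs`).
#' @export
map_segments <- function(x, f, ...) {
  stopifnot(inherits(x, "segment_set"))
  out <- x
  out$segments <- lapply(x$segments, f, ...)
  out
}

concat_segments <- function(x) unlist(x$segments, use.names = FALSE)
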