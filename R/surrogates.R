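#' Phase-randomised surrogate of one segment
#'
#' Replaces the Fourier phases of a real-valued segment with i.i.d. uniform
#' phases while keeping the amplitude spectrum, respecting conjugate symmetry
#' (DC and, for even lengths, the Nyquist bin stay real). The surrogate
#' preserves every linear property of the signal (power spectrum,
#' autocorrelation, variance) to machine precision and destroys nonlinear
#' structure, which is what makes original-vs-surrogate comparisons a test
#' for nonlinear contributions to entropy effects.
#'
#' @param segment numeric vector.
#' @param seed optional integer seed for the phase draw.
#' @return numeric vector of the same length.
#' @export
phase_randomize <- function(segment, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(segment)
  if (n < 3L) return(segment)
  X <- stats::fft(segment)
  half <- (n - 1) %/% 2 # bins 2..half+1 are free; DC (and Nyquist) fixed
  phases <- stats::runif(half, 0, 2 * pi)
  Y <- X
  Y[2:(half + 1)] <- Mod(X[2:(half + 1)]) * exp(1i * phases)
  Y[n:(n - half + 1)] <- Conj(Y[2:(half + 1)])
  if (n %% 2L == 0L) Y[n / 2 + 1] <- Mod(X[n / 2 + 1]) * sign(Re(X[n / 2 + 1]))
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Ensemble of phase-randomised surrogate sets
#'
#' Applies [phase_randomize()] independently to every segment, `n_surrogates`
#' times, with a reproducible seed stream.
#'
#' @param data a [segment_set()].
#' @param n_surrogates number of surrogate sets (>= 1).
#' @param seed integer seed for the ensemble stream.
#' @return a list of `n_surrogates` [segment_set()]s.
#' @export
surrogate_ensemble <- function(data, n_surrogates, seed = NULL) {
  stopifnot(inherits(data, "segment_set"), n_surrogates >= 1)
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_surrogates), function(i)
    map_segments(data, phase_randomize))
}
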