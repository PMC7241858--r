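#' Variance explained from a t-statistic
#'
#' `R^2 = t^2 / (t^2 + df)` for an unpaired t-test; its square root equals the
#' point-biserial correlation between the continuous measure and the binary
#' group.
#'
#' @param t t-statistic.
#' @param df degrees of freedom (> 0).
#' @return R-squared in `[0, 1]`.
#' @examples
#' effect_r2(2, 97) # 4/101
#' @export
effect_r2 <- function(t, df) {
  if (df <= 0) stop("`df` must be > 0")
  t^2 / (t^2 + df)
}

#' Compare two independent correlations via the r-to-z transform
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with a two-sided
#' p-value from the standard normal.
#'
#' @param r1,r2 correlations with `|r| < 1`.
#' @param n1,n2 sample sizes (> 3).
#' @return list with `z` and `p`.
#' @export
compare_corrs_z <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("correlations must satisfy |r| < 1")
  if (n1 <= 3 || n2 <= 3) stop("sample sizes must exceed 3")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Paired standardized difference (d')
#'
#' `mean(x - y) / sd(x - y)` for paired condition/baseline values.
#'
#' @param x condition values.
#' @param y baseline values (same length, >= 2 pairs).
#' @return d'; `NA` with attribute `flag = "zero_sd"` when the paired
#'   differences have zero spread.
#' @export
dprime_paired <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- x - y
  if (all(d == 0)) return(0)
  s <- stats::sd(d)
  if (s <= 1e-10 * mean(abs(d))) # constant offset up to rounding noise
    return(structure(NA_real_, flag = "zero_sd"))
  mean(d) / s
}

#' Within-subject centering of a subject-by-condition grid
#'
#' Removes between-subject offsets for within-subject error bars/statistics:
#' each value has its subject mean subtracted and the grand mean added back,
#' so condition means are preserved while subject means are equalized.
#'
#' @param values numeric matrix, rows = subjects, columns = conditions;
#'   complete (no missing cells).
#' @return matrix of the same shape.
#' @export
within_subject_center <- function(values) {
  values <- as.matrix(values)
  if (any(is.na(values))) stop("grid must be complete (no missing cells)")
  sweep(values, 1, rowMeans(values)) + mean(values)
}
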