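# Independent reference implementations used as oracles in tests.

# Naive template-pair counting via outer-product Chebyshev distances over all
# template pairs (self-pairs subtracted); deliberately a different construction
# from the package's counting loop.
oracle_counts <- function(x, m, bound) {
  nt <- length(x) - m
  stopifnot(nt >= 2)
  E <- stats::embed(x, m + 1)[, (m + 1):1, drop = FALSE] # row i = x[i..i+m]
  D <- abs(outer(E[, 1], E[, 1], "-"))
  if (m >= 2) for (k in 2:m) D <- pmax(D, abs(outer(E[, k], E[, k], "-")))
  Dm1 <- pmax(D, abs(outer(E[, m + 1], E[, m + 1], "-")))
  list(pm = sum(D <= bound) - nt, pm1 = sum(Dm1 <= bound) - nt)
}

oracle_sampen <- function(x, m, bound) {
  cnt <- oracle_counts(x, m, bound)
  log(cnt$pm / cnt$pm1)
}

# For i.i.d. N(0,1) data the probability that two independent samples lie
# within r*sigma is 2*Phi(r/sqrt(2)) - 1, and SampEn is -log of it.
analytic_iid_sampen <- function(r) -log(2 * stats::pnorm(r / sqrt(2)) - 1)

# two-sided exact sign test p-value on the non-zero paired differences
sign_test_p <- function(d) {
  nz <- d[d != 0]
  if (length(nz) == 0) return(1)
  stats::binom.test(sum(nz < 0), length(nz))$p.value
}
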