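# Truncated-normal draws and raw moments.
#
# The cohort generator draws age and TIV from normal distributions
# truncated to their physiological support, and the moment-matching
# calibration needs the raw moments E[X^k] of those truncated laws in
# closed form (up to order 4 for age, because the model contains age^2
# and TIV x age terms).

# Inverse-CDF sampler: exact, vectorized, and fully determined by the
# RNG stream (one uniform per draw), which keeps cohorts reproducible.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(sd > 0, lower < upper)
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}

# Raw moments E[X^k], k = 1..order, of N(mean, sd^2) truncated to
# [lower, upper], by the standard recursion
#   m_k = (k-1) sd^2 m_{k-2} + mean m_{k-1}
#         - sd * (upper^{k-1} phi(beta) - lower^{k-1} phi(alpha)) / Z
# with phi the standard normal density and Z the truncation mass.
truncnorm_moments <- function(mean, sd, lower = -Inf, upper = Inf, order = 4) {
  stopifnot(is_number(mean), is_number(sd), sd > 0, lower < upper, order >= 1)
  alpha <- (lower - mean) / sd
  beta <- (upper - mean) / sd
  z <- stats::pnorm(beta) - stats::pnorm(alpha)
  stopifnot(z > 0)
  bound_term <- function(bound, std, k) {
    if (!is.finite(bound)) return(0)  # density kills any polynomial factor
    bound^(k - 1) * stats::dnorm(std)
  }
  m <- numeric(order + 1)  # m[k + 1] = E[X^k]
  m[1] <- 1
  for (k in seq_len(order)) {
    prev2 <- if (k >= 2) m[k - 1] else 0
    m[k + 1] <- (k - 1) * sd^2 * prev2 + mean * m[k] -
      sd * (bound_term(upper, beta, k) - bound_term(lower, alpha, k)) / z
  }
  m[-1]
}
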