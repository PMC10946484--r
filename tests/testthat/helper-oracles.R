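# Independent oracles and fixture builders shared across the test files.

# Imhof-type numerical inversion of the characteristic function of
# sum(lambda_k z_k^2): an implementation-independent CDF oracle.
imhof_cdf <- function(lambda, x) {
  f <- function(u) sapply(u, function(ui) {
    th <- 0.5 * sum(atan(lambda * ui)) - 0.5 * x * ui
    rho <- exp(0.25 * sum(log1p(lambda^2 * ui^2)))
    sin(th) / (ui * rho)
  })
  v <- stats::integrate(f, 0, Inf, rel.tol = 1e-12, abs.tol = 1e-10,
                        subdivisions = 100000L, stop.on.error = FALSE)
  1 - (0.5 + v$value / pi)
}

# Monte-Carlo CDF oracle for the same quadratic form.
mc_cdf <- function(lambda, x, n = 1e6L) {
  z <- matrix(rnorm(length(lambda) * n), nrow = length(lambda))
  q <- colSums(lambda * z^2)
  est <- mean(q <= x)
  list(est = est, se = sqrt(est * (1 - est) / n))
}

# Heterogeneous synthetic meta-analysis: K studies of total size n,
# control probability pi_c, effects N(theta, tau2).
het_studies <- function(k = 12, n = 100, pi_c = 0.3, theta = 0.5,
                        tau2 = 0.3, seed = 5) {
  set.seed(seed)
  filter_studies(
    simulate_study(rep(n, k), 0.5, pi_c, rnorm(k, theta, sqrt(tau2)))
  )$kept
}

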