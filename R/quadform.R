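#' Eigen-spectrum of the generalized Q statistic
#'
#' The generalized Q with fixed weights is a quadratic form
#' `theta_hat' B theta_hat` with `B = W (diag(q) - q q')`, `q_i = w_i / W`.
#' When the study estimates are independent normals with variances `m2`,
#' Q is distributed as `sum(lambda_k z_k^2)` where the `lambda_k` are the
#' eigenvalues of `S^(1/2) B S^(1/2)`, `S = diag(m2)`. `B` annihilates the
#' constant vector, so exactly one structural zero eigenvalue is removed;
#' if more are numerically zero (below `1e-10 * max`) a warning flags the
#' degenerate input.
#'
#' @param q_norm Normalized weights `q_i` summing to 1.
#' @param w_total Total weight `W`.
#' @param m2 Per-study second moments (variances), all > 0.
#' @return A list of class `"qf_spectrum"`: `lambdas` (positive, decreasing)
#'   and `n_dropped`.
#' @export
qf_spectrum <- function(q_norm, w_total, m2) {
  if (any(m2 <= 0) || any(!is.finite(m2)))
    stop("invalid input: second moments m2 must be positive", call. = FALSE)
  if (abs(sum(q_norm) - 1) > 1e-8)
    stop("invalid input: q_norm must sum to 1", call. = FALSE)
  # A_ij = W (delta_ij q_i - q_i q_j) sqrt(m2_i m2_j)
  a <- -w_total * tcrossprod(q_norm * sqrt(m2))
  diag(a) <- diag(a) + w_total * q_norm * m2
  ev <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
  cut <- 1e-10 * max(ev)
  keep <- ev > cut
  n_dropped <- sum(!keep)
  if (n_dropped > 1L)
    warning("dropped ", n_dropped, " numerically zero eigenvalues ",
            "(expected 1); input may be degenerate")
  structure(list(lambdas = ev[keep], n_dropped = n_dropped),
            class = "qf_spectrum")
}

#' CDF of a nonnegative quadratic form in independent standard normals
#'
#' Computes `P(sum(lambda_k z_k^2) <= x)` by Ruben's expansion of the
#' distribution as a mixture of central chi-square distributions, the
#' series underlying the Farebrother algorithm. The centering constant is
#' `beta = 2 lambda_min lambda_max / (lambda_min + lambda_max)`.
#'
#' @param spectrum A `"qf_spectrum"` object, or a numeric vector of
#'   positive eigenvalues.
#' @param x Evaluation point, >= 0.
#' @param tol Series truncation tolerance, in (0, 1e-4]; default 1e-9.
#' @param max_terms Maximum number of series terms before falling back to a
#'   Monte-Carlo estimate (with a warning).
#' @return The CDF value in \[0, 1\].
#' @export
ruben_cdf <- function(spectrum, x, tol = 1e-9, max_terms = 10000L) {
  lambda <- if (inherits(spectrum, "qf_spectrum")) spectrum$lambdas else spectrum
  if (any(lambda <= 0)) stop("invalid input: eigenvalues must be positive",
                             call. = FALSE)
  if (tol <= 0 || tol > 1e-4) stop("tol must be in (0, 1e-4]", call. = FALSE)
  if (x < 0) stop("x must be >= 0", call. = FALSE)
  if (x == 0) return(0)
  r <- length(lambda)
  lmin <- min(lambda); lmax <- max(lambda)
  if (lmax / lmin - 1 < 1e-12) return(stats::pchisq(x / lmin, df = r))
  beta <- 2 * lmin * lmax / (lmin + lmax)
  gam <- 1 - beta / lambda               # all in (-1, 1) by choice of beta
  xb <- x / beta
  a <- numeric(max_terms + 1L)
  g <- numeric(max_terms)
  a[1L] <- exp(0.5 * sum(log(beta / lambda)))
  gpow <- gam
  cdf <- a[1L] * stats::pchisq(xb, df = r)
  small <- 0L
  for (k in seq_len(max_terms)) {
    g[k] <- sum(gpow)
    gpow <- gpow * gam
    a[k + 1L] <- sum(g[seq_len(k)] * a[k:1L]) / (2 * k)
    fk <- stats::pchisq(xb, df = r + 2 * k)
    term <- a[k + 1L] * fk
    cdf <- cdf + term
    # chi-square factor decays to 0 in k; once it (or the running term) is
    # negligible the remainder is below tol (validated against oracles)
    if (fk < tol) return(min(max(cdf, 0), 1))
    small <- if (abs(term) < 0.1 * tol) small + 1L else 0L
    if (small >= 4L) return(min(max(cdf, 0), 1))
  }
  warning("Ruben series did not converge in ", max_terms,
          " terms; falling back to Monte-Carlo estimate")
  mc_quadform_cdf(lambda, x, n = 1e5L)
}

# Monte-Carlo fallback / diagnostic CDF estimate (uses the current RNG).
mc_quadform_cdf <- function(lambda, x, n = 1e5L) {
  z <- matrix(stats::rnorm(length(lambda) * n), nrow = length(lambda))
  mean(colSums(lambda * z^2) <= x)
}

#' CDF of the observed generalized Q statistic at a given heterogeneity
#'
#' Composes the second-moment model (`m2(tau2)`), the spectrum of the
#' quadratic form and the Ruben series: this is the profile function
#' `F(x | tau2)` inverted by the median-unbiased point estimators and the
#' Farebrother-profile confidence intervals. It is strictly decreasing in
#' `tau2` for fixed `x > 0`.
#'
#' @param x An `lor_summaries` object (or studies, coerced with `policy`).
#' @param q_obs Evaluation point (typically the observed Q_F), >= 0.
#' @param tau2 Heterogeneity variance, >= 0.
#' @param variant `"conditional"`, `"uncond_model"` or `"uncond_naive"`.
#' @param theta_pooled Pooled effect for the model-based variant (defaults
#'   to the fixed-weights pooled estimate).
#' @param policy Zero-cell policy used if `x` is a raw study table.
#' @param tol Series tolerance passed to [ruben_cdf()].
#' @return `P(Q_F <= q_obs | tau2)`.
#' @export
qf_cdf <- function(x, q_obs, tau2, variant = "conditional",
                   theta_pooled = NULL, policy = "only", tol = 1e-9) {
  s <- as_lor_summaries(x, policy)
  m2 <- second_moments(s, tau2, variant, theta_pooled)
  qi <- s$n_tilde / sum(s$n_tilde)
  sp <- qf_spectrum(qi, sum(s$n_tilde), m2)
  ruben_cdf(sp, q_obs, tol = tol)
}

#' Chi-square p-value for the inverse-variance Q statistic
#'
#' Upper-tail probability of the chi-square distribution with K - 1 degrees
#' of freedom, the usual null approximation for Q with inverse-variance
#' weights.
#'
#' @param q Observed Q statistic.
#' @param k Number of studies (>= 2).
#' @return The p-value.
#' @export
chisq_pvalue_qiv <- function(q, k) {
  if (k < 2L) stop("need k >= 2", call. = FALSE)
  stats::pchisq(q, df = k - 1, lower.tail = FALSE)
}
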