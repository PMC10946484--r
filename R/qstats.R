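#' Weighted mean of study effects
#'
#' @param thetas Numeric vector of study-level estimates.
#' @param weights Positive weights of the same length.
#' @return The weighted mean `sum(w * theta) / sum(w)`.
#' @export
weighted_mean <- function(thetas, weights) {
  if (length(thetas) == 0L || length(thetas) != length(weights))
    stop("invalid input: need equally long, nonempty thetas and weights",
         call. = FALSE)
  if (any(weights <= 0) || any(!is.finite(weights)))
    stop("invalid input: weights must be positive and finite", call. = FALSE)
  sum(weights * thetas) / sum(weights)
}

#' Generalized Q statistic
#'
#' `Q = sum(w_i * (theta_i - theta_bar_w)^2)` for arbitrary positive weights
#' `w_i`, where `theta_bar_w` is the weighted mean of the `theta_i`.
#'
#' @inheritParams weighted_mean
#' @param flavor Label recorded in the result, `"IV"` or `"F"` (or any tag).
#' @return A list of class `"q_result"`: `q`, `weights`, `w_total`
#'   (`W = sum(w)`), `q_norm` (`q_i = w_i / W`), `theta_bar`, `k`, `flavor`.
#' @export
q_statistic <- function(thetas, weights, flavor = "generic") {
  if (length(thetas) < 2L)
    stop("insufficient studies: Q requires K >= 2", call. = FALSE)
  tb <- weighted_mean(thetas, weights)
  structure(
    list(q = sum(weights * (thetas - tb)^2),
         weights = weights,
         w_total = sum(weights),
         q_norm = weights / sum(weights),
         theta_bar = tb,
         k = length(thetas),
         flavor = flavor),
    class = "q_result"
  )
}

#' @export
print.q_result <- function(x, ...) {
  cat(sprintf("Q (%s weights) = %.4f on %d studies; weighted mean = %.4f\n",
              x$flavor, x$q, x$k, x$theta_bar))
  invisible(x)
}

#' Cochran's Q with inverse-variance weights
#'
#' @param x An `lor_summaries` object (or studies, coerced with `policy`).
#' @param policy Zero-cell policy used if `x` is a raw study table.
#' @return A `"q_result"` (flavor `"IV"`) with weights `1 / v2_cond`.
#' @export
q_iv <- function(x, policy = "only") {
  s <- as_lor_summaries(x, policy)
  q_statistic(s$theta_hat, 1 / s$v2_cond, flavor = "IV")
}

#' Generalized Q with effective-sample-size weights
#'
#' The weights are the studies' effective sample sizes
#' `n_tilde = n_c n_t / n`, fixed constants that do not involve any
#' variance estimate.
#'
#' @inheritParams q_iv
#' @return A `"q_result"` (flavor `"F"`) with weights `n_tilde`.
#' @export
q_f <- function(x, policy = "only") {
  s <- as_lor_summaries(x, policy)
  q_statistic(s$theta_hat, s$n_tilde, flavor = "F")
}

#' I-squared heterogeneity index
#'
#' `max(0, (Q - (K - 1)) / Q) * 100`, reported for the inverse-variance
#' flavor of Q.
#'
#' @param q Observed Q statistic (>= 0).
#' @param k Number of studies (>= 2).
#' @return Percentage in \[0, 100\].
#' @export
i_squared <- function(q, k) {
  if (k < 2L || q < 0) stop("need k >= 2 and q >= 0", call. = FALSE)
  max(0, (q - (k - 1)) / q) * 100
}

#' Fixed-weights (effective-sample-size) pooled log-odds-ratio
#'
#' @inheritParams q_iv
#' @return The weighted mean of the study estimates with weights `n_tilde`.
#' @export
pooled_ssw <- function(x, policy = "only") {
  s <- as_lor_summaries(x, policy)
  weighted_mean(s$theta_hat, s$n_tilde)
}

# Per-study second moments M2_i(tau2) of theta_hat_i about the overall mean:
#  conditional     v2_cond + tau2
#  uncond_model    Ev2(model p_t) + tau2 * C(model)
#  uncond_naive    Ev2(naive p_t) + tau2 * C(naive)
# For the model-based variant the pooled effect defaults to the
# effective-sample-size weighted mean of the summaries themselves.
second_moments <- function(summaries, tau2,
                           variant = c("conditional", "uncond_model", "uncond_naive"),
                           theta_pooled = NULL) {
  variant <- match.arg(variant)
  if (tau2 < 0) stop("tau2 must be >= 0", call. = FALSE)
  if (variant == "conditional") return(summaries$v2_cond + tau2)
  uvar <- sub("uncond_", "", variant)
  if (uvar == "model" && is.null(theta_pooled))
    theta_pooled <- weighted_mean(summaries$theta_hat, summaries$n_tilde)
  uc <- uncond_components(summaries[c("id", "x_t", "n_t", "x_c", "n_c")],
                          variant = uvar, theta_pooled = theta_pooled)
  uc$ev2 + tau2 * uc$c_i
}

#' Expected value of the generalized Q statistic under the random-effects model
#'
#' `E(Q_F) = W * sum(q_i (1 - q_i) * M2_i)`, where `M2_i` is the second
#' moment of study i's estimate about the overall effect: `v2_cond + tau2`
#' for the conditional variant, or `Ev2_i + tau2 * C_i` for the
#' unconditional (model-based / naive) variants.
#'
#' @param x An `lor_summaries` object (or studies, coerced with `policy`).
#' @param tau2 Heterogeneity variance, >= 0.
#' @param variant `"conditional"`, `"uncond_model"` or `"uncond_naive"`.
#' @param theta_pooled Pooled effect for the model-based variant; defaults
#'   to the fixed-weights pooled estimate of `x`.
#' @param policy Zero-cell policy used if `x` is a raw study table.
#' @return The expected value of `Q_F` at the given `tau2`.
#' @export
expected_qf <- function(x, tau2, variant = "conditional",
                        theta_pooled = NULL, policy = "only") {
  s <- as_lor_summaries(x, policy)
  m2 <- second_moments(s, tau2, variant, theta_pooled)
  qi <- s$n_tilde / sum(s$n_tilde)
  sum(s$n_tilde) * sum(qi * (1 - qi) * m2)
}
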