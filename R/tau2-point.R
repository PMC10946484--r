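new_tau2_est <- function(value, raw, method, policy = NA_character_,
                         variant = NA_character_, converged = TRUE,
                         iterations = 0L) {
  structure(list(value = value, raw = raw, method = method, policy = policy,
                 variant = variant, converged = converged,
                 iterations = iterations),
            class = "tau2_est")
}

#' @export
print.tau2_est <- function(x, ...) {
  lab <- x$method
  if (!is.na(x$variant)) lab <- paste(lab, x$variant)
  if (!is.na(x$policy)) lab <- paste0(lab, " ('", x$policy, "')")
  cat(sprintf("tau^2 [%s] = %.4f", lab, x$value))
  if (!is.na(x$raw) && x$raw < 0) cat(sprintf(" (raw %.4f, truncated)", x$raw))
  if (!x$converged) cat(" [did not converge]")
  cat("\n")
  invisible(x)
}

# Generalized Q with weights 1/(v2 + tau2); strictly decreasing in tau2.
qgen_iv <- function(summaries, tau2) {
  w <- 1 / (summaries$v2_cond + tau2)
  tb <- sum(w * summaries$theta_hat) / sum(w)
  sum(w * (summaries$theta_hat - tb)^2)
}

# Solve f(x) = target for strictly decreasing f on x >= 0, doubling the
# upper bracket from `upper` until f < target or `cap` is reached.
# Callers handle the f(0) <= target case.
root_decreasing <- function(f, target, upper = 5, cap = 1e4, tol = 1e-9) {
  f0 <- f(0)
  ub <- upper
  fu <- f(ub)
  while (fu >= target && ub < cap) {
    ub <- min(2 * ub, cap)
    fu <- f(ub)
  }
  if (fu >= target)
    return(list(root = cap, converged = FALSE))
  r <- stats::uniroot(function(x) f(x) - target, lower = 0, upper = ub,
                      f.lower = f0 - target, f.upper = fu - target,
                      tol = tol)
  list(root = r$root, converged = TRUE)
}

#' DerSimonian-Laird estimator of the heterogeneity variance
#'
#' Classical moment estimator
#' `max(0, (Q_IV - (K - 1)) / (S1 - S2 / S1))` with `S1 = sum(1/v2)`,
#' `S2 = sum(1/v2^2)`.
#'
#' @param x An `lor_studies` table or `lor_summaries` object.
#' @param policy Zero-cell policy (`"only"` or `"always"`) used to build
#'   the summaries when `x` is a raw study table.
#' @return A `"tau2_est"` object.
#' @export
tau2_dl <- function(x, policy = "only") {
  s <- as_lor_summaries(x, policy)
  need_k(s, 2L)
  w <- 1 / s$v2_cond
  q <- q_iv(s)$q
  raw <- (q - (nrow(s) - 1)) / (sum(w) - sum(w^2) / sum(w))
  new_tau2_est(max(0, raw), raw, "DL", attr(s, "policy"))
}

#' Restricted maximum-likelihood estimator of the heterogeneity variance
#'
#' Maximizes the restricted normal log-likelihood of the model
#' `theta_hat_i ~ N(theta, v2_i + tau2)` by the standard fixed-point
#' iteration, truncated at zero.
#'
#' @inheritParams tau2_dl
#' @param tol Relative convergence tolerance.
#' @param max_iter Iteration cap; on non-convergence the last iterate is
#'   returned with `converged = FALSE`.
#' @return A `"tau2_est"` object.
#' @export
tau2_reml <- function(x, policy = "only", tol = 1e-8, max_iter = 1000L) {
  s <- as_lor_summaries(x, policy)
  need_k(s, 2L)
  th <- s$theta_hat; v <- s$v2_cond
  t2 <- max(0, stats::var(th) - mean(v))
  conv <- FALSE; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    w <- 1 / (v + t2)
    tb <- sum(w * th) / sum(w)
    t2_new <- max(0, sum(w^2 * ((th - tb)^2 - v)) / sum(w^2) + 1 / sum(w))
    if (abs(t2_new - t2) <= tol * (1 + t2)) {
      t2 <- t2_new; conv <- TRUE; break
    }
    t2 <- t2_new
  }
  if (!conv) warning("REML iteration did not converge")
  new_tau2_est(t2, NA_real_, "REML", attr(s, "policy"),
               converged = conv, iterations = it)
}

#' Mandel-Paule estimator of the heterogeneity variance
#'
#' The value of tau2 >= 0 at which the generalized Q statistic with weights
#' `1 / (v2_i + tau2)` equals its null expectation K - 1; zero when even
#' `Qgen(0) <= K - 1`.
#'
#' @inheritParams tau2_dl
#' @return A `"tau2_est"` object.
#' @export
tau2_mp <- function(x, policy = "only") {
  s <- as_lor_summaries(x, policy)
  need_k(s, 2L)
  k <- nrow(s)
  if (qgen_iv(s, 0) <= k - 1)
    return(new_tau2_est(0, NA_real_, "MP", attr(s, "policy")))
  r <- root_decreasing(function(t2) qgen_iv(s, t2), k - 1)
  new_tau2_est(r$root, NA_real_, "MP", attr(s, "policy"), converged = r$converged)
}

# Moment estimators from the expected value of Q_F:
# raw = (Q_F / W - sum(q(1-q) ev2)) / sum(q(1-q) c), with ev2 the
# conditional variances and c = 1 (SSC), or the unconditional components
# (SSU model / naive).
tau2_qf_moment <- function(s, ev2, c_i, method, policy, variant = NA_character_) {
  qres <- q_f(s)
  qi <- qres$q_norm
  raw <- (qres$q / qres$w_total - sum(qi * (1 - qi) * ev2)) /
    sum(qi * (1 - qi) * c_i)
  new_tau2_est(max(0, raw), raw, method, policy, variant)
}

#' Sample-sizes conditional (SSC) moment estimator
#'
#' Moment estimator of tau2 obtained by equating the observed generalized Q
#' (effective-sample-size weights) to its expected value computed with the
#' conditional variance estimates.
#'
#' @inheritParams tau2_dl
#' @return A `"tau2_est"` object.
#' @export
tau2_ssc <- function(x, policy = "only") {
  s <- as_lor_summaries(x, policy)
  need_k(s, 2L)
  tau2_qf_moment(s, s$v2_cond, rep(1, nrow(s)), "SSC", attr(s, "policy"))
}

#' Sample-sizes unconditional (SSU) moment estimator
#'
#' As [tau2_ssc()], but with the unconditional second-moment decomposition
#' `Ev2_i + tau2 * C_i`: the expected within-study variance replaces the
#' conditional variance and the inflation factor `C_i` scales the tau2
#' term. The treatment-arm probability is model-based or naive. Adjusted
#' (add-0.5) proportions are used in every study, so the estimator is
#' defined for the `"always"` policy.
#'
#' @param x An `lor_studies` table or `lor_summaries` object (summaries are
#'   rebuilt under the `"always"` policy).
#' @param variant `"model"` or `"naive"`.
#' @param theta_pooled Pooled effect for the model-based variant; defaults
#'   to the fixed-weights pooled estimate.
#' @return A `"tau2_est"` object.
#' @export
tau2_ssu <- function(x, variant = c("model", "naive"), theta_pooled = NULL) {
  variant <- match.arg(variant)
  s <- summaries_always(x)
  need_k(s, 2L)
  if (variant == "model" && is.null(theta_pooled))
    theta_pooled <- pooled_ssw(s)
  uc <- uncond_components(s[c("id", "x_t", "n_t", "x_c", "n_c")],
                          variant, theta_pooled)
  tau2_qf_moment(s, uc$ev2, uc$c_i, "SSU", "always", variant)
}

# Median-unbiased inversion: largest tau2 >= 0 with F(Q_obs | tau2) = 0.5,
# where F is the Ruben-Farebrother CDF with second moments m2_fun(tau2).
tau2_median_core <- function(s, m2_fun, method, policy,
                             variant = NA_character_, tol = 1e-9) {
  qres <- q_f(s)
  qi <- qres$q_norm; w <- qres$w_total
  f <- function(t2) ruben_cdf(qf_spectrum(qi, w, m2_fun(t2)), qres$q)
  if (f(0) < 0.5)
    return(new_tau2_est(0, NA_real_, method, policy, variant))
  r <- root_decreasing(f, 0.5, tol = tol)
  new_tau2_est(r$root, NA_real_, method, policy, variant,
               converged = r$converged)
}

#' Sample-sizes median-unbiased conditional (SMC) estimator
#'
#' The tau2 at which the Ruben-Farebrother CDF of the observed generalized
#' Q (conditional second moments `v2_i + tau2`) equals one half; zero when
#' the observed Q falls below the median of its tau2 = 0 distribution.
#'
#' @inheritParams tau2_dl
#' @return A `"tau2_est"` object.
#' @export
tau2_smc <- function(x, policy = "only") {
  s <- as_lor_summaries(x, policy)
  need_k(s, 2L)
  tau2_median_core(s, function(t2) s$v2_cond + t2, "SMC", attr(s, "policy"))
}

#' Sample-sizes median-unbiased unconditional (SMU) estimator
#'
#' As [tau2_smc()], but with unconditional second moments
#' `Ev2_i + tau2 * C_i` (model-based or naive treatment-arm probability);
#' defined for the `"always"` policy.
#'
#' @inheritParams tau2_ssu
#' @return A `"tau2_est"` object.
#' @export
tau2_smu <- function(x, variant = c("model", "naive"), theta_pooled = NULL) {
  variant <- match.arg(variant)
  s <- summaries_always(x)
  need_k(s, 2L)
  if (variant == "model" && is.null(theta_pooled))
    theta_pooled <- pooled_ssw(s)
  uc <- uncond_components(s[c("id", "x_t", "n_t", "x_c", "n_c")],
                          variant, theta_pooled)
  tau2_median_core(s, function(t2) uc$ev2 + t2 * uc$c_i, "SMU", "always",
                   variant)
}

# SSU/SMU/FPU are defined with adjusted proportions in every study; rebuild
# the summaries under "always" unless already so.
summaries_always <- function(x) {
  if (inherits(x, "lor_summaries") && identical(attr(x, "policy"), "always"))
    return(x)
  if (inherits(x, "lor_summaries"))
    x <- x[c("id", "x_t", "n_t", "x_c", "n_c")]
  study_summaries(as_lor_studies(x), policy = "always")
}

need_k <- function(s, k_min) {
  if (nrow(s) < k_min)
    stop("insufficient studies: need K >= ", k_min, call. = FALSE)
  invisible(TRUE)
}

#' Estimate the heterogeneity variance by a named method
#'
#' Front-end dispatching on the method labels used throughout the package:
#' `"DL"`, `"REML"`, `"MP"`, `"SSC"`, `"SMC"` (each in `"only"` or
#' `"always"` versions) and `"SSU model"`, `"SSU naive"`, `"SMU model"`,
#' `"SMU naive"` (always-adjusted by construction).
#'
#' @param x An `lor_studies` table or `lor_summaries` object.
#' @param method Method label (see Details).
#' @param policy Zero-cell policy for the policy-paired methods.
#' @return A `"tau2_est"` object.
#' @export
tau2_estimate <- function(x, method, policy = "only") {
  parts <- strsplit(trimws(method), "\\s+")[[1]]
  m <- toupper(parts[1L])
  variant <- if (length(parts) > 1L) tolower(parts[2L]) else NULL
  switch(m,
    DL = tau2_dl(x, policy),
    REML = tau2_reml(x, policy),
    MP = tau2_mp(x, policy),
    SSC = tau2_ssc(x, policy),
    SMC = tau2_smc(x, policy),
    SSU = tau2_ssu(x, variant %||% "model"),
    SMU = tau2_smu(x, variant %||% "model"),
    stop("unknown method: ", method, call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
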