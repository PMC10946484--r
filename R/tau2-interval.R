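new_tau2_ci <- function(lower, upper, level, method, policy = NA_character_,
                        variant = NA_character_, status = "ok") {
  structure(list(lower = lower, upper = upper, level = level, method = method,
                 policy = policy, variant = variant, status = status),
            class = "tau2_ci")
}

#' @export
print.tau2_ci <- function(x, ...) {
  lab <- x$method
  if (!is.na(x$variant)) lab <- paste(lab, x$variant)
  if (!is.na(x$policy)) lab <- paste0(lab, " ('", x$policy, "')")
  cat(sprintf("%.0f%% CI for tau^2 [%s]: [%.4f, %.4f]",
              100 * x$level, lab, x$lower, x$upper))
  if (x$status != "ok") cat(sprintf(" (%s)", x$status))
  cat("\n")
  invisible(x)
}

# Invert a strictly decreasing profile function g(tau2) against lower/upper
# targets: the confidence set {tau2 >= 0 : lo_target <= g(tau2) <= hi_target}.
# If g(0) < lo_target the set is empty below any tau2 -> [0, 0] degenerate;
# if g(0) < hi_target only the lower constraint binds at 0 -> lower = 0.
invert_decreasing_profile <- function(g, lo_target, hi_target, level, method,
                                      policy = NA_character_,
                                      variant = NA_character_,
                                      cap = 1e4, tol = 1e-9) {
  g0 <- g(0)
  if (g0 < lo_target)
    return(new_tau2_ci(0, 0, level, method, policy, variant,
                       status = "degenerate_zero"))
  lower <- 0
  if (g0 >= hi_target) {
    r <- root_decreasing(g, hi_target, cap = cap, tol = tol)
    lower <- r$root
  }
  r <- root_decreasing(g, lo_target, cap = cap, tol = tol)
  status <- if (r$converged) "ok" else "upper_unbounded"
  new_tau2_ci(lower, r$root, level, method, policy, variant, status = status)
}

#' Q-profile confidence interval for the heterogeneity variance
#'
#' The set of tau2 >= 0 for which the generalized Q statistic with weights
#' `1 / (v2_i + tau2)` lies between the alpha/2 and 1 - alpha/2 quantiles
#' of the chi-square distribution with K - 1 degrees of freedom.
#'
#' @param x An `lor_studies` table or `lor_summaries` object.
#' @param policy Zero-cell policy used to build the summaries.
#' @param level Nominal coverage (default 0.95).
#' @return A `"tau2_ci"` object.
#' @export
ci_qprofile <- function(x, policy = "only", level = 0.95) {
  s <- as_lor_summaries(x, policy)
  need_k(s, 2L)
  alpha <- 1 - level
  df <- nrow(s) - 1
  invert_decreasing_profile(
    function(t2) qgen_iv(s, t2),
    lo_target = stats::qchisq(alpha / 2, df),
    hi_target = stats::qchisq(1 - alpha / 2, df),
    level, "QP", attr(s, "policy")
  )
}

# Profile log-likelihood of tau2 (theta profiled out in closed form).
profile_loglik <- function(summaries, tau2) {
  w <- 1 / (summaries$v2_cond + tau2)
  tb <- sum(w * summaries$theta_hat) / sum(w)
  -0.5 * sum(log(summaries$v2_cond + tau2) +
               w * (summaries$theta_hat - tb)^2)
}

#' Profile-likelihood confidence interval for the heterogeneity variance
#'
#' Inverts the likelihood-ratio statistic of the normal random-effects
#' model: the interval contains all tau2 >= 0 whose profile log-likelihood
#' lies within `qchisq(level, 1) / 2` of its maximum.
#'
#' @inheritParams ci_qprofile
#' @param cap Upper search cap for the bracket expansion; beyond it the
#'   interval is reported with status `"upper_unbounded"`.
#' @return A `"tau2_ci"` object.
#' @export
ci_pl <- function(x, policy = "only", level = 0.95, cap = 1e4) {
  s <- as_lor_summaries(x, policy)
  need_k(s, 2L)
  crit <- stats::qchisq(level, 1) / 2
  ll <- function(t2) profile_loglik(s, t2)
  # locate the ML point: expand the search interval until the profile
  # decreases at its right end
  ub <- 5
  while (ll(ub) >= ll(ub / 2) && ub < cap) ub <- 2 * ub
  opt <- stats::optimize(ll, c(0, ub), maximum = TRUE, tol = 1e-10)
  t2_ml <- if (ll(0) >= opt$objective) 0 else opt$maximum
  ll_max <- max(ll(0), opt$objective)
  drop <- function(t2) ll_max - ll(t2)
  lower <- 0
  if (t2_ml > 0 && drop(0) > crit) {
    r <- stats::uniroot(function(t2) drop(t2) - crit, c(0, t2_ml), tol = 1e-9)
    lower <- r$root
  }
  ub <- max(2 * t2_ml, 5)
  while (drop(ub) <= crit && ub < cap) ub <- min(2 * ub, cap)
  if (drop(ub) <= crit)
    return(new_tau2_ci(lower, cap, level, "PL", attr(s, "policy"),
                       status = "upper_unbounded"))
  r <- stats::uniroot(function(t2) drop(t2) - crit, c(t2_ml, ub), tol = 1e-9)
  new_tau2_ci(lower, r$root, level, "PL", attr(s, "policy"))
}

#' Farebrother-profile conditional (FPC) confidence interval
#'
#' The set of tau2 >= 0 for which the Ruben-Farebrother CDF of the observed
#' generalized Q (conditional second moments `v2_i + tau2`) lies between
#' alpha/2 and 1 - alpha/2. Since the CDF is strictly decreasing in tau2,
#' the lower limit solves `F = 1 - alpha/2` (zero if even `F(Q | 0)` is
#' below that) and the upper limit solves `F = alpha/2`.
#'
#' @inheritParams ci_qprofile
#' @return A `"tau2_ci"` object.
#' @export
ci_fpc <- function(x, policy = "only", level = 0.95) {
  s <- as_lor_summaries(x, policy)
  need_k(s, 2L)
  ci_farebrother_core(s, function(t2) s$v2_cond + t2, level, "FPC",
                      attr(s, "policy"))
}

#' Farebrother-profile unconditional (FPU) confidence interval
#'
#' As [ci_fpc()], with unconditional second moments `Ev2_i + tau2 * C_i`
#' (model-based or naive treatment-arm probability); defined for the
#' `"always"` policy.
#'
#' @inheritParams tau2_ssu
#' @param level Nominal coverage (default 0.95).
#' @return A `"tau2_ci"` object.
#' @export
ci_fpu <- function(x, variant = c("model", "naive"), level = 0.95,
                   theta_pooled = NULL) {
  variant <- match.arg(variant)
  s <- summaries_always(x)
  need_k(s, 2L)
  if (variant == "model" && is.null(theta_pooled))
    theta_pooled <- pooled_ssw(s)
  uc <- uncond_components(s[c("id", "x_t", "n_t", "x_c", "n_c")],
                          variant, theta_pooled)
  ci_farebrother_core(s, function(t2) uc$ev2 + t2 * uc$c_i, level, "FPU",
                      "always", variant)
}

ci_farebrother_core <- function(s, m2_fun, level, method, policy,
                                variant = NA_character_) {
  qres <- q_f(s)
  qi <- qres$q_norm; w <- qres$w_total
  alpha <- 1 - level
  f <- function(t2) ruben_cdf(qf_spectrum(qi, w, m2_fun(t2)), qres$q)
  invert_decreasing_profile(f, lo_target = alpha / 2,
                            hi_target = 1 - alpha / 2,
                            level, method, policy, variant)
}

#' Confidence interval for the heterogeneity variance by a named method
#'
#' Dispatches on the interval labels `"QP"`, `"PL"`, `"FPC"` (each paired
#' with a zero-cell policy) and `"FPU model"` / `"FPU naive"`.
#'
#' @inheritParams tau2_estimate
#' @param level Nominal coverage.
#' @return A `"tau2_ci"` object.
#' @export
tau2_interval <- function(x, method, policy = "only", level = 0.95) {
  parts <- strsplit(trimws(method), "\\s+")[[1]]
  m <- toupper(parts[1L])
  variant <- if (length(parts) > 1L) tolower(parts[2L]) else NULL
  switch(m,
    QP = ci_qprofile(x, policy, level),
    PL = ci_pl(x, policy, level),
    FPC = ci_fpc(x, policy, level),
    FPU = ci_fpu(x, variant %||% "model", level),
    stop("unknown interval method: ", method, call. = FALSE)
  )
}
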