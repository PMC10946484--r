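#' Full heterogeneity analysis of a set of 2x2 tables
#'
#' Filters degenerate studies, computes both Q statistics with their
#' heterogeneity tests (chi-square for the inverse-variance Q; the
#' Ruben-Farebrother tail of the effective-sample-size Q, in model-based
#' and naive versions), the pooled effects (common-effect inverse-variance,
#' random-effects inverse-variance, and fixed effective-sample-size
#' weights), and the requested point and interval estimators of tau2.
#'
#' @param studies An [lor_studies] table (e.g. from [read_studies()]).
#' @param policy Zero-cell policy for the policy-paired methods.
#' @param methods Point-estimator labels (see [tau2_estimate()]).
#' @param intervals Interval labels (see [tau2_interval()]).
#' @param level Nominal confidence level.
#' @return A list of class `"lor_analysis"` with components `k`, `dropped`,
#'   `policy`, `q` (both statistics, p-values, I-squared), `pooled`
#'   (estimates and standard errors), `estimates` (list of `tau2_est`),
#'   `cis` (list of `tau2_ci`) and `failures` (named error messages of
#'   methods that could not be computed).
#' @export
analyze <- function(studies, policy = c("only", "always"),
                    methods = c("DL", "REML", "MP", "SSC", "SSU model",
                                "SSU naive", "SMC", "SMU model", "SMU naive"),
                    intervals = c("QP", "PL", "FPC", "FPU model", "FPU naive"),
                    level = 0.95) {
  policy <- match.arg(policy)
  flt <- filter_studies(as_lor_studies(studies))
  if (flt$k < 2L)
    stop("insufficient studies: K = ", flt$k, " after filtering", call. = FALSE)
  s <- study_summaries(flt$kept, policy)
  qiv <- q_iv(s)
  qf <- q_f(s)
  q <- list(
    q_iv = qiv$q,
    p_chisq = chisq_pvalue_qiv(qiv$q, qiv$k),
    i2 = i_squared(qiv$q, qiv$k),
    q_f = qf$q,
    p_fssw_model = 1 - qf_cdf(s, qf$q, tau2 = 0, variant = "uncond_model"),
    p_fssw_naive = 1 - qf_cdf(s, qf$q, tau2 = 0, variant = "uncond_naive")
  )
  w <- 1 / s$v2_cond
  failures <- list()
  ests <- list()
  for (m in methods) {
    e <- tryCatch(tau2_estimate(s, m, policy), error = function(e) e)
    if (inherits(e, "error")) failures[[m]] <- conditionMessage(e)
    else ests[[m]] <- e
  }
  cis <- list()
  for (m in intervals) {
    ci <- tryCatch(tau2_interval(s, m, policy, level), error = function(e) e)
    if (inherits(ci, "error")) failures[[paste("CI", m)]] <- conditionMessage(ci)
    else cis[[m]] <- ci
  }
  # random-effects IV pooled estimate uses the Mandel-Paule tau2 when
  # available, otherwise DerSimonian-Laird
  t2_re <- if (!is.null(ests[["MP"]])) ests[["MP"]]$value else
    tau2_mp(s, policy)$value
  w_re <- 1 / (s$v2_cond + t2_re)
  pooled <- list(
    theta_iv = sum(w * s$theta_hat) / sum(w),
    se_iv = sqrt(1 / sum(w)),
    theta_iv_re = sum(w_re * s$theta_hat) / sum(w_re),
    se_iv_re = sqrt(1 / sum(w_re)),
    tau2_re = t2_re,
    theta_ssw = pooled_ssw(s),
    se_ssw = sqrt(sum(s$n_tilde^2 * (s$v2_cond + t2_re))) / sum(s$n_tilde)
  )
  structure(list(k = flt$k, dropped = flt$dropped, policy = policy,
                 level = level, q = q, pooled = pooled,
                 estimates = ests, cis = cis, failures = failures),
            class = "lor_analysis")
}

#' @export
print.lor_analysis <- function(x, ...) {
  cat(sprintf("Meta-analysis of log-odds-ratio: K = %d studies ('%s' policy)\n",
              x$k, x$policy))
  if (nrow(x$dropped))
    cat(sprintf("  (%d degenerate studies dropped: %s)\n", nrow(x$dropped),
                paste(x$dropped$id, collapse = ", ")))
  cat(sprintf("\nHeterogeneity tests:\n"))
  cat(sprintf("  Q (IV weights)  = %.4f, chi-square p = %.4f, I^2 = %.2f%%\n",
              x$q$q_iv, x$q$p_chisq, x$q$i2))
  cat(sprintf("  Q (ESS weights) = %.4f, F SSW p (model) = %.4f, (naive) = %.4f\n",
              x$q$q_f, x$q$p_fssw_model, x$q$p_fssw_naive))
  cat(sprintf("\nPooled log-odds-ratio:\n"))
  cat(sprintf("  IV common-effect:  %.4f (SE %.4f)\n",
              x$pooled$theta_iv, x$pooled$se_iv))
  cat(sprintf("  IV random-effects: %.4f (SE %.4f, tau^2 = %.4f)\n",
              x$pooled$theta_iv_re, x$pooled$se_iv_re, x$pooled$tau2_re))
  cat(sprintf("  ESS fixed-weights: %.4f (SE %.4f)\n",
              x$pooled$theta_ssw, x$pooled$se_ssw))
  if (length(x$estimates)) {
    cat("\nPoint estimates of tau^2:\n")
    for (e in x$estimates) { cat("  "); print(e) }
  }
  if (length(x$cis)) {
    cat(sprintf("\n%.0f%% confidence intervals for tau^2:\n", 100 * x$level))
    for (ci in x$cis) { cat("  "); print(ci) }
  }
  if (length(x$failures)) {
    cat("\nFailed methods:\n")
    for (nm in names(x$failures))
      cat(sprintf("  %s: %s\n", nm, x$failures[[nm]]))
  }
  invisible(x)
}

#' Serialize an analysis report to a tidy data frame
#'
#' One row per reported quantity, suitable for writing as TSV/CSV or
#' converting to JSON.
#'
#' @param x An `"lor_analysis"` object.
#' @return A data frame with columns `quantity`, `method`, `value`,
#'   `value2` (upper CI limit where relevant) and `status`.
#' @export
report_table <- function(x) {
  stopifnot(inherits(x, "lor_analysis"))
  rows <- list(
    data.frame(quantity = "k", method = "", value = x$k, value2 = NA_real_,
               status = "ok"),
    data.frame(quantity = c("q_iv", "p_chisq", "i2", "q_f", "p_fssw_model",
                            "p_fssw_naive"),
               method = "", value = unlist(x$q), value2 = NA_real_,
               status = "ok"),
    data.frame(quantity = c("theta_iv", "se_iv", "theta_iv_re", "se_iv_re",
                            "tau2_re", "theta_ssw", "se_ssw"),
               method = "", value = unlist(x$pooled), value2 = NA_real_,
               status = "ok")
  )
  for (nm in names(x$estimates)) {
    e <- x$estimates[[nm]]
    rows[[length(rows) + 1L]] <-
      data.frame(quantity = "tau2", method = nm, value = e$value,
                 value2 = NA_real_,
                 status = if (e$converged) "ok" else "no_convergence")
  }
  for (nm in names(x$cis)) {
    ci <- x$cis[[nm]]
    rows[[length(rows) + 1L]] <-
      data.frame(quantity = "ci", method = nm, value = ci$lower,
                 value2 = ci$upper, status = ci$status)
  }
  for (nm in names(x$failures))
    rows[[length(rows) + 1L]] <-
      data.frame(quantity = "failed", method = nm, value = NA_real_,
                 value2 = NA_real_, status = x$failures[[nm]])
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic benchmark dataset
#'
#' Deterministic (seeded) synthetic study sets for examples and tests:
#' \describe{
#'   \item{`stead_like`}{17 mostly balanced studies with total sizes between
#'     182 and 3128 and low event probabilities (around 0.04-0.06),
#'     emulating the shape of a large smoking-cessation review. Synthetic:
#'     the counts are generated, not taken from any published review.}
#'   \item{`sparse`}{10 small studies with rare events, so that zero cells
#'     occur.}
#'   \item{`balanced_small`}{8 medium studies with moderate probabilities
#'     and mild heterogeneity.}
#' }
#'
#' @param profile One of `"stead_like"`, `"sparse"`, `"balanced_small"`.
#' @param seed RNG seed.
#' @param path Optional output file; when given, the table is written as
#'   CSV (see [write_studies()]).
#' @return An [lor_studies] table (invisibly, if `path` is given).
#' @export
make_fixture <- function(profile = c("stead_like", "sparse", "balanced_small"),
                         seed = 20230628L, path = NULL) {
  profile <- match.arg(profile)
  set.seed(seed)
  studies <- switch(profile,
    stead_like = {
      k <- 17L
      # log-uniform sizes pinned to the target range, mostly balanced arms
      n <- round(exp(stats::runif(k - 2L, log(220), log(2400))))
      n <- c(182L, 3128L, as.integer(n))
      f <- rep(0.5, k)
      f[c(3L, 4L)] <- 0.33   # two studies with more subjects in treatment
      pi_c <- stats::runif(k, 0.030, 0.055)
      theta_i <- stats::rnorm(k, 0.5, sqrt(0.08))
      simulate_study(n, f, pi_c, theta_i)
    },
    sparse = simulate_study(rep(30L, 10L), 0.5, 0.04,
                            stats::rnorm(10L, 0.4, sqrt(0.1))),
    balanced_small = simulate_study(rep(40L, 8L), 0.5, 0.3,
                                    stats::rnorm(8L, 0.3, sqrt(0.05)))
  )
  if (!is.null(path)) {
    write_studies(studies, path)
    return(invisible(studies))
  }
  studies
}
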