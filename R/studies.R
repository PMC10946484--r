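#' Per-study 2x2 tables for a binary outcome
#'
#' Constructs a validated table of study-level counts for meta-analysis of
#' the log-odds-ratio. Each study contributes a 2x2 table: events and arm
#' size in the treatment arm (`x_t`, `n_t`) and in the control arm
#' (`x_c`, `n_c`).
#'
#' @param x_t Integer vector, event counts in the treatment arms (>= 0).
#' @param n_t Integer vector, treatment arm sizes (>= 1).
#' @param x_c Integer vector, event counts in the control arms (>= 0).
#' @param n_c Integer vector, control arm sizes (>= 1).
#' @param id Optional study labels; defaults to `"study_1"`, `"study_2"`, ...
#'
#' @return A data frame of class `"lor_studies"` with columns `id`, `x_t`,
#'   `n_t`, `x_c`, `n_c` and the derived logical columns `double_zero`
#'   (no events in either arm) and `double_n` (all events in both arms).
#' @examples
#' lor_studies(x_t = c(3, 0), n_t = c(10, 12), x_c = c(2, 1), n_c = c(10, 12))
#' @export
lor_studies <- function(x_t, n_t, x_c, n_c, id = NULL) {
  k <- length(x_t)
  if (!all(lengths(list(n_t, x_c, n_c)) == k))
    stop("x_t, n_t, x_c, n_c must have equal length", call. = FALSE)
  if (k == 0L) stop("at least one study is required", call. = FALSE)
  if (is.null(id)) id <- paste0("study_", seq_len(k))
  counts <- list(x_t = x_t, n_t = n_t, x_c = x_c, n_c = n_c)
  for (nm in names(counts)) {
    v <- counts[[nm]]
    if (any(!is.finite(v)) || any(v != round(v)))
      stop("column '", nm, "' must contain finite integers", call. = FALSE)
  }
  if (any(n_t < 1L) || any(n_c < 1L))
    stop("arm sizes n_t and n_c must be >= 1", call. = FALSE)
  bad <- which(x_t < 0 | x_c < 0 | x_t > n_t | x_c > n_c)
  if (length(bad))
    stop("invalid counts (need 0 <= x <= n) in row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  out <- data.frame(
    id = as.character(id),
    x_t = as.integer(x_t), n_t = as.integer(n_t),
    x_c = as.integer(x_c), n_c = as.integer(n_c),
    stringsAsFactors = FALSE
  )
  out$double_zero <- out$x_t == 0L & out$x_c == 0L
  out$double_n <- out$x_t == out$n_t & out$x_c == out$n_c
  class(out) <- c("lor_studies", "data.frame")
  out
}

as_lor_studies <- function(x) {
  if (inherits(x, "lor_studies")) return(x)
  need <- c("x_t", "n_t", "x_c", "n_c")
  if (!is.data.frame(x) || !all(need %in% names(x)))
    stop("expected an 'lor_studies' object or a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  lor_studies(x$x_t, x$n_t, x$x_c, x$n_c,
              id = if ("id" %in% names(x)) x$id else if ("study" %in% names(x)) x$study else NULL)
}

#' Read per-study 2x2 tables from a delimited text file
#'
#' Reads a comma- or tab-delimited file with header
#' `study,x_t,n_t,x_c,n_c` (delimiter auto-detected from the header line).
#' Blank lines are ignored; malformed rows are reported with their line
#' numbers.
#'
#' @param path Path to the file.
#' @param delim Delimiter; `NULL` (default) auto-detects comma vs tab.
#' @return A [lor_studies] data frame.
#' @export
read_studies <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) < 2L)
    stop("insufficient studies: '", path, "' has no data rows", call. = FALSE)
  if (is.null(delim))
    delim <- if (grepl("\t", lines[keep[1]])) "\t" else ","
  dat <- utils::read.table(text = lines[keep], header = TRUE, sep = delim,
                           quote = "\"", strip.white = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("study", "x_t", "n_t", "x_c", "n_c")
  miss <- setdiff(need, names(dat))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  line_of_row <- keep[-1L]  # file line numbers of the data rows
  for (nm in c("x_t", "n_t", "x_c", "n_c")) {
    v <- suppressWarnings(as.numeric(dat[[nm]]))
    bad <- which(!is.finite(v) | v != round(v))
    if (length(bad))
      stop("non-integer value in column '", nm, "' at file line(s): ",
           paste(line_of_row[bad], collapse = ", "), call. = FALSE)
    dat[[nm]] <- as.integer(round(v))
  }
  bad <- which(dat$x_t > dat$n_t | dat$x_c > dat$n_c | dat$x_t < 0 | dat$x_c < 0)
  if (length(bad))
    stop("event count exceeds arm size (or is negative) at file line(s): ",
         paste(line_of_row[bad], collapse = ", "), call. = FALSE)
  lor_studies(dat$x_t, dat$n_t, dat$x_c, dat$n_c, id = dat$study)
}

#' Write studies to a delimited file
#'
#' @param studies An [lor_studies] object.
#' @param path Output path.
#' @param delim Delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_studies <- function(studies, path, delim = ",") {
  studies <- as_lor_studies(studies)
  out <- data.frame(study = studies$id, x_t = studies$x_t, n_t = studies$n_t,
                    x_c = studies$x_c, n_c = studies$n_c)
  utils::write.table(out, path, sep = delim, quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Drop degenerate (double-zero / double-n) studies
#'
#' Removes studies in which both arms have zero events ("double-zero") or
#' both arms consist entirely of events ("double-n"); the log-odds-ratio
#' carries no information in either case and the prevalent practice is to
#' discard them, reducing the observed number of studies K accordingly.
#'
#' @param studies An [lor_studies] object.
#' @param quiet Suppress the message listing dropped studies?
#' @return A list with components `kept` (surviving studies, original
#'   order), `dropped` (excluded studies) and `k` (number kept).
#' @export
filter_studies <- function(studies, quiet = TRUE) {
  studies <- as_lor_studies(studies)
  drop <- studies$double_zero | studies$double_n
  kept <- studies[!drop, , drop = FALSE]
  dropped <- studies[drop, , drop = FALSE]
  if (!quiet && nrow(dropped))
    message("dropped ", nrow(dropped), " degenerate stud",
            if (nrow(dropped) == 1L) "y" else "ies", ": ",
            paste(dropped$id, collapse = ", "))
  list(kept = kept, dropped = dropped, k = nrow(kept))
}

#' Estimate an arm-level event probability
#'
#' Either the maximum-likelihood estimate `x/n` or the bias-adjusted
#' estimate `(x + 0.5)/(n + 1)`, which removes the order-1/n bias of the
#' estimated log-odds and is strictly inside (0, 1) for all legal counts.
#'
#' @param x Event count(s), `0 <= x <= n`.
#' @param n Arm size(s), `n >= 1`.
#' @param rule `"mle"` or `"adjusted"`.
#' @return Numeric vector of probabilities.
#' @examples
#' estimate_proportion(0, 10, "adjusted")  # 0.5/11
#' @export
estimate_proportion <- function(x, n, rule = c("mle", "adjusted")) {
  rule <- match.arg(rule)
  if (any(n < 1) || any(x < 0) || any(x > n))
    stop("invalid input: need 0 <= x <= n and n >= 1", call. = FALSE)
  if (rule == "mle") x / n else (x + 0.5) / (n + 1)
}

#' Decide which proportion rule each study uses under a zero-cell policy
#'
#' Under the `"always"` policy every study uses the adjusted (add-0.5)
#' proportions. Under the `"only"` policy a study is adjusted exactly when
#' any of its four cells `x_t`, `x_c`, `n_t - x_t`, `n_c - x_c` is zero
#' (the adjustment then applies to all four cells of that study), and uses
#' maximum likelihood otherwise.
#'
#' @param studies An [lor_studies] object.
#' @param policy `"only"` or `"always"`.
#' @return Character vector (`"mle"`/`"adjusted"`), one entry per study.
#' @export
resolve_rule <- function(studies, policy = c("only", "always")) {
  policy <- match.arg(policy)
  studies <- as_lor_studies(studies)
  if (policy == "always") return(rep("adjusted", nrow(studies)))
  zero <- with(studies, x_t == 0L | x_c == 0L | x_t == n_t | x_c == n_c)
  ifelse(zero, "adjusted", "mle")
}

# Arm-level proportions and effective denominators under a per-study rule.
# The n -> n + 1 substitution in variance denominators is tied to use of the
# adjusted proportions.
arm_quantities <- function(studies, rule) {
  adj <- rule == "adjusted"
  p_t <- ifelse(adj, (studies$x_t + 0.5) / (studies$n_t + 1), studies$x_t / studies$n_t)
  p_c <- ifelse(adj, (studies$x_c + 0.5) / (studies$n_c + 1), studies$x_c / studies$n_c)
  list(p_t = p_t, p_c = p_c,
       N_t = studies$n_t + adj, N_c = studies$n_c + adj)
}

#' Study-level log-odds-ratio
#'
#' @param studies An [lor_studies] object.
#' @param rule Proportion rule per study, `"mle"` or `"adjusted"` (recycled).
#'   Under `"mle"` all four cells of each study must be nonzero; apply
#'   [resolve_rule()] first to guarantee this.
#' @return Numeric vector of log-odds-ratio estimates.
#' @export
log_odds_ratio <- function(studies, rule = "mle") {
  studies <- as_lor_studies(studies)
  rule <- check_rule(rule, nrow(studies))
  a <- arm_quantities(studies, rule)
  bad <- rule == "mle" &
    (studies$x_t == 0L | studies$x_c == 0L |
       studies$x_t == studies$n_t | studies$x_c == studies$n_c)
  if (any(bad))
    stop("nonfinite estimate: zero cell under 'mle' rule in study(ies) ",
         paste(studies$id[bad], collapse = ", "),
         " (apply resolve_rule() first)", call. = FALSE)
  log(a$p_t * (1 - a$p_c) / (a$p_c * (1 - a$p_t)))
}

#' Conditional (within-study) variance of the log-odds-ratio
#'
#' Delta-method variance `1/(N_t p_t (1 - p_t)) + 1/(N_c p_c (1 - p_c))`,
#' with proportions from the study's rule and `N = n + 1` replacing
#' `N = n` when the adjusted proportions are used (the large-sample
#' unbiased variant).
#'
#' @inheritParams log_odds_ratio
#' @return Numeric vector of variance estimates.
#' @export
conditional_variance <- function(studies, rule = "mle") {
  studies <- as_lor_studies(studies)
  rule <- check_rule(rule, nrow(studies))
  a <- arm_quantities(studies, rule)
  bad <- rule == "mle" & (a$p_t %in% c(0, 1) | a$p_c %in% c(0, 1))
  if (any(bad))
    stop("nonfinite estimate: zero cell under 'mle' rule in study(ies) ",
         paste(studies$id[bad], collapse = ", "), call. = FALSE)
  1 / (a$N_t * a$p_t * (1 - a$p_t)) + 1 / (a$N_c * a$p_c * (1 - a$p_c))
}

check_rule <- function(rule, k) {
  if (!all(rule %in% c("mle", "adjusted")))
    stop("rule must be 'mle' or 'adjusted'", call. = FALSE)
  rep_len(rule, k)
}

#' Effective sample size of a study
#'
#' `n_tilde = n_c * n_t / (n_c + n_t)`, the effective sample size; these are
#' the fixed weights of the generalized Q statistic. For balanced arms it
#' equals n/4.
#'
#' @param studies An [lor_studies] object.
#' @return Numeric vector of effective sample sizes.
#' @export
effective_sample_size <- function(studies) {
  studies <- as_lor_studies(studies)
  with(studies, as.numeric(n_c) * n_t / (n_c + n_t))
}

#' Variance inflation factor of the random-effects term
#'
#' The coefficient `C = (1 + [2 n_t p_t (1 - p_t)]^(-1))^2` that multiplies
#' the heterogeneity variance in the unconditional variance of the estimated
#' log-odds-ratio under the fixed-intercept random-effects model. It
#' satisfies `C >= 1`, decreases in `n_t`, and tends to 1 as `n_t` grows.
#'
#' @param n_t Treatment-arm size(s) (the effective denominator; callers pass
#'   `n_t + 1` when the adjusted proportion is used).
#' @param p_t Treatment-arm probability estimate(s), strictly in (0, 1).
#' @return Numeric vector of inflation factors.
#' @export
inflation_factor <- function(n_t, p_t) {
  if (any(p_t <= 0 | p_t >= 1))
    stop("invalid input: p_t must be strictly inside (0, 1)", call. = FALSE)
  (1 + 1 / (2 * n_t * p_t * (1 - p_t)))^2
}

# Unconditional second-moment building blocks: the expected within-study
# variance Ev2 (treatment proportion model-based or naive, control
# proportion adjusted) and the inflation factor C for each study.
uncond_components <- function(studies, variant = c("model", "naive"),
                              theta_pooled = NULL) {
  variant <- match.arg(variant)
  studies <- as_lor_studies(studies)
  p_c <- (studies$x_c + 0.5) / (studies$n_c + 1)
  N_c <- studies$n_c + 1
  if (variant == "naive") {
    p_t <- (studies$x_t + 0.5) / (studies$n_t + 1)
    N_t <- studies$n_t + 1
  } else {
    if (is.null(theta_pooled))
      stop("invalid input: theta_pooled is required for the model-based variant",
           call. = FALSE)
    # model-based: p_t from the study's control arm and the pooled effect
    p_t <- stats::plogis(stats::qlogis(p_c) + theta_pooled)
    N_t <- studies$n_t
  }
  list(
    ev2 = 1 / (N_t * p_t * (1 - p_t)) + 1 / (N_c * p_c * (1 - p_c)),
    c_i = inflation_factor(N_t, p_t)
  )
}

#' Unconditional variance of the estimated log-odds-ratio
#'
#' Under the fixed-intercept random-effects model the variance of the
#' estimated log-odds-ratio decomposes as `Ev2 + tau2 * C`, where `Ev2` is
#' the expected within-study variance and `C` the inflation factor
#' ([inflation_factor()]). The treatment-arm probability in `Ev2` and `C`
#' is either model-based (`expit(logit(p_c_adj) + theta_pooled)`) or naive
#' (the study's own adjusted proportion); the control arm always uses the
#' adjusted proportion. Wherever an adjusted proportion is used, `n + 1`
#' replaces `n` in the denominators.
#'
#' @param studies An [lor_studies] object.
#' @param tau2 Heterogeneity variance, `>= 0`.
#' @param variant `"model"` or `"naive"`.
#' @param theta_pooled Pooled log-odds-ratio; required for `"model"`,
#'   ignored for `"naive"`.
#' @return Numeric vector of unconditional variance estimates.
#' @export
unconditional_variance <- function(studies, tau2,
                                   variant = c("model", "naive"),
                                   theta_pooled = NULL) {
  if (tau2 < 0) stop("tau2 must be >= 0", call. = FALSE)
  uc <- uncond_components(studies, variant, theta_pooled)
  uc$ev2 + tau2 * uc$c_i
}

#' Per-study summaries for meta-analysis of log-odds-ratio
#'
#' Resolves the zero-cell policy, then computes each study's log-odds-ratio,
#' conditional variance and effective sample size.
#'
#' @param studies An [lor_studies] object (pass through [filter_studies()]
#'   first if degenerate studies may be present).
#' @param policy `"only"` or `"always"`; see [resolve_rule()].
#' @return A data frame of class `"lor_summaries"` with columns `id`,
#'   the four counts, `rule`, `theta_hat`, `v2_cond` and `n_tilde`; the
#'   policy is stored as attribute `"policy"`.
#' @export
study_summaries <- function(studies, policy = c("only", "always")) {
  policy <- match.arg(policy)
  studies <- as_lor_studies(studies)
  if (any(studies$double_zero | studies$double_n))
    stop("degenerate (double-zero/double-n) studies present; ",
         "use filter_studies() first", call. = FALSE)
  rule <- resolve_rule(studies, policy)
  out <- data.frame(
    id = studies$id,
    x_t = studies$x_t, n_t = studies$n_t,
    x_c = studies$x_c, n_c = studies$n_c,
    rule = rule,
    theta_hat = log_odds_ratio(studies, rule),
    v2_cond = conditional_variance(studies, rule),
    n_tilde = effective_sample_size(studies),
    stringsAsFactors = FALSE
  )
  attr(out, "policy") <- policy
  class(out) <- c("lor_summaries", "data.frame")
  out
}

as_lor_summaries <- function(x, policy = c("only", "always")) {
  if (inherits(x, "lor_summaries")) return(x)
  study_summaries(as_lor_studies(x), policy = match.arg(policy))
}
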