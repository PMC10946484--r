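test_that("proportion estimation follows the mle and adjusted rules", {
  expect_equal(estimate_proportion(5, 10, "mle"), 0.5)
  expect_equal(estimate_proportion(0, 10, "adjusted"), 0.5 / 11)
  expect_equal(estimate_proportion(10, 10, "adjusted"), 10.5 / 11)
  # adjusted strictly inside (0,1) for all legal counts on a small grid
  for (n in c(1, 3, 17)) {
    p <- estimate_proportion(0:n, n, "adjusted")
    expect_true(all(p > 0 & p < 1))
  }
  expect_error(estimate_proportion(11, 10, "mle"), "invalid")
})

test_that("the zero-cell policy selects the rule per study", {
  st <- lor_studies(x_t = c(3, 0, 3, 10), n_t = c(10, 10, 10, 10),
                    x_c = c(2, 2, 2, 3), n_c = c(10, 10, 10, 10))
  expect_equal(resolve_rule(st, "only"),
               c("mle", "adjusted", "mle", "adjusted"))
  expect_equal(resolve_rule(st, "always"), rep("adjusted", 4))
})

test_that("log-odds-ratio matches hand arithmetic and is antisymmetric", {
  st <- lor_studies(3, 10, 1, 10)
  expect_equal(log_odds_ratio(st, "mle"), log(27 / 7))
  swapped <- lor_studies(1, 10, 3, 10)
  expect_equal(log_odds_ratio(swapped, "mle"), -log(27 / 7))
  expect_equal(log_odds_ratio(lor_studies(5, 10, 5, 10), "mle"), 0)
  expect_error(log_odds_ratio(lor_studies(0, 10, 2, 10), "mle"), "nonfinite")
})

test_that("conditional variance: hand value, 1/n scaling, symmetry", {
  expect_equal(conditional_variance(lor_studies(5, 10, 5, 10), "mle"), 0.8)
  # doubling arm sizes at fixed proportions halves the variance
  v1 <- conditional_variance(lor_studies(3, 10, 2, 10), "mle")
  v2 <- conditional_variance(lor_studies(6, 20, 4, 20), "mle")
  expect_equal(v2, v1 / 2)
  # adjusted variance is finite with zero cells and symmetric in
  # events/non-events
  st <- lor_studies(0, 10, 2, 10)
  va <- conditional_variance(st, "adjusted")
  expect_true(is.finite(va) && va > 0)
  flipped <- lor_studies(10, 10, 8, 10)
  expect_equal(conditional_variance(flipped, "adjusted"), va)
})

test_that("inflation factor matches its closed form and limits", {
  expect_equal(inflation_factor(50, 0.5), (1 + 1 / (2 * 50 * 0.25))^2,
               tolerance = 1e-12)
  # -> 1 as n grows; monotone non-increasing in n at fixed p
  ns <- c(10, 50, 200, 1e4, 1e8)
  ci <- inflation_factor(ns, 0.3)
  expect_true(all(diff(ci) < 0))
  expect_true(all(ci >= 1))
  expect_equal(ci[5], 1, tolerance = 1e-6)
  expect_error(inflation_factor(10, 1), "invalid")
})

test_that("unconditional variance decomposes as Ev2 + tau2 * C", {
  set.seed(11)
  st <- simulate_study(rep(60, 5), 0.5, 0.25, rnorm(5, 0.4, 0.3))
  v0 <- unconditional_variance(st, 0, "naive")
  # tau2 = 0 reduces to the Ev2 term, which for the naive variant is the
  # adjusted conditional variance (algebraic identity)
  expect_equal(v0, conditional_variance(st, "adjusted"), tolerance = 1e-12)
  # linear in tau2 with slope C_i
  p_t <- (st$x_t + 0.5) / (st$n_t + 1)
  ci <- inflation_factor(st$n_t + 1, p_t)
  expect_equal(unconditional_variance(st, 0.7, "naive"), v0 + 0.7 * ci,
               tolerance = 1e-12)
  # model variant requires a pooled effect
  expect_error(unconditional_variance(st, 0.1, "model"), "theta_pooled")
  vm <- unconditional_variance(st, 0.1, "model", theta_pooled = 0.4)
  expect_true(all(is.finite(vm) & vm > 0))
})

test_that("unconditional and conditional variances agree as n grows", {
  base <- c(x_t = 12, n_t = 40, x_c = 6, n_c = 40)
  gap <- sapply(c(1, 10, 100), function(sc) {
    st <- lor_studies(base["x_t"] * sc, base["n_t"] * sc,
                      base["x_c"] * sc, base["n_c"] * sc)
    abs(unconditional_variance(st, 0, "naive") -
          conditional_variance(st, "adjusted" ))
  })
  # identity holds exactly for the naive variant; model variant is O(1/n^2)
  gapm <- sapply(c(1, 10, 100), function(sc) {
    st <- lor_studies(base["x_t"] * sc, base["n_t"] * sc,
                      base["x_c"] * sc, base["n_c"] * sc)
    th <- log_odds_ratio(st, "adjusted")
    abs(unconditional_variance(st, 0, "model", theta_pooled = th) -
          conditional_variance(st, "adjusted"))
  })
  expect_true(all(diff(gapm) < 0))
  expect_lt(gapm[3], gapm[1] / 50)
  expect_true(all(gap < 1e-15))
})

test_that("effective sample size is n/4 for balanced arms and bounded", {
  expect_equal(effective_sample_size(lor_studies(1, 10, 1, 10)), 5)
  expect_equal(effective_sample_size(lor_studies(1, 84, 1, 84)), 42)
  st <- lor_studies(c(1, 2), c(10, 250), c(1, 2), c(30, 50))
  expect_true(all(effective_sample_size(st) <=
                    pmin(st$n_t, st$n_c)))
})

test_that("degenerate studies are dropped, order preserved", {
  st <- lor_studies(x_t = c(0, 3, 10, 5), n_t = c(10, 10, 10, 10),
                    x_c = c(0, 1, 12, 2), n_c = c(12, 10, 12, 10))
  flt <- filter_studies(st)
  expect_equal(flt$k, 2)
  expect_equal(flt$kept$id, c("study_2", "study_4"))
  expect_equal(flt$dropped$id, c("study_1", "study_3"))
  clean <- lor_studies(c(3, 5), c(10, 10), c(1, 2), c(10, 10))
  expect_equal(filter_studies(clean)$kept$x_t, clean$x_t)
})

test_that("summaries are finite for every policy and random legal study", {
  set.seed(99)
  for (i in 1:25) {
    n_t <- sample(2:40, 1); n_c <- sample(2:40, 1)
    st <- lor_studies(sample(0:n_t, 1), n_t, sample(0:n_c, 1), n_c)
    if (st$double_zero || st$double_n) next
    for (pol in c("only", "always")) {
      two <- rbind(st, lor_studies(3, 10, 2, 10))
      class(two) <- class(st)
      s <- study_summaries(two, pol)
      expect_true(all(is.finite(s$theta_hat)))
      expect_true(all(s$v2_cond > 0))
      expect_true(all(s$n_tilde > 0))
    }
  }
})

test_that("reader round-trips files, detects dialects and flags bad rows", {
  st <- het_studies(k = 6, seed = 21)
  path <- withr::local_tempfile(fileext = ".csv")
  write_studies(st, path)
  back <- read_studies(path)
  expect_equal(back$x_t, st$x_t)
  expect_equal(back$id, st$id)
  # tab dialect auto-detected
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_studies(st, path2, delim = "\t")
  expect_equal(read_studies(path2)$n_c, st$n_c)
  # malformed rows are reported with their file line numbers
  writeLines(c("study,x_t,n_t,x_c,n_c", "a,1,10,2,10", "b,11,10,2,10"), path)
  expect_error(read_studies(path), "line.*3")
  writeLines(c("study,x_t,n_t,x_c,n_c", "a,1.5,10,2,10"), path)
  expect_error(read_studies(path), "non-integer")
  writeLines("study,x_t,n_t,x_c,n_c", path)
  expect_error(read_studies(path), "insufficient")
})
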