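# A fixed heterogeneous dataset used for the cross-checks below.
st_het <- het_studies(k = 12, n = 100, pi_c = 0.3, theta = 0.5,
                      tau2 = 0.3, seed = 5)

test_that("DerSimonian-Laird: hand value, truncation and oracle agreement", {
  # two studies, v = (1,1), theta = (0,2): Q = 2, S1 = 2, S2 = 2 -> 1
  s2 <- structure(data.frame(id = c("a", "b"), x_t = 1, n_t = 10, x_c = 1,
                             n_c = 10, rule = "mle",
                             theta_hat = c(0, 2), v2_cond = c(1, 1),
                             n_tilde = 5),
                  class = c("lor_summaries", "data.frame"))
  expect_equal(tau2_dl(s2)$value, 1)
  # homogeneous: truncated to zero, raw retained
  hom <- study_summaries(lor_studies(c(10, 10), c(50, 50), c(10, 10),
                                     c(50, 50)), "only")
  dl0 <- tau2_dl(hom)
  expect_equal(dl0$value, 0)
  expect_lte(dl0$raw, 0)
  s <- study_summaries(st_het, "only")
  expect_equal(tau2_dl(s)$value,
               metafor::rma(s$theta_hat, s$v2_cond, method = "DL")$tau2,
               tolerance = 1e-8)
})

test_that("REML: balanced closed form and oracle agreement", {
  # equal variances v: REML = max(0, sum((th - mean)^2) / (K-1) - v)
  set.seed(9)
  th <- rnorm(10, 0, 0.8); v <- 0.2
  s <- structure(data.frame(id = letters[1:10], x_t = 1, n_t = 10, x_c = 1,
                            n_c = 10, rule = "mle", theta_hat = th,
                            v2_cond = v, n_tilde = 5),
                 class = c("lor_summaries", "data.frame"))
  closed <- max(0, sum((th - mean(th))^2) / 9 - v)
  expect_equal(tau2_reml(s)$value, closed, tolerance = 1e-6)
  sh <- study_summaries(st_het, "only")
  expect_equal(tau2_reml(sh)$value,
               metafor::rma(sh$theta_hat, sh$v2_cond, method = "REML",
                            control = list(tau2.min = 0))$tau2,
               tolerance = 1e-6)
})

test_that("Mandel-Paule: root contract, truncation and oracle agreement", {
  sh <- study_summaries(st_het, "only")
  mp <- tau2_mp(sh)
  expect_gt(mp$value, 0)
  # at the root the generalized Q equals K - 1
  w <- 1 / (sh$v2_cond + mp$value)
  tb <- sum(w * sh$theta_hat) / sum(w)
  expect_equal(sum(w * (sh$theta_hat - tb)^2), nrow(sh) - 1,
               tolerance = 1e-5)
  hom <- study_summaries(lor_studies(c(10, 11), c(50, 50), c(10, 10),
                                     c(50, 50)), "only")
  expect_equal(tau2_mp(hom)$value, 0)
  expect_equal(mp$value,
               metafor::rma(sh$theta_hat, sh$v2_cond, method = "PM")$tau2,
               tolerance = 1e-5)
})

test_that("SSC equals the generalized-Q moment estimator of the oracle", {
  for (pol in c("only", "always")) {
    s <- study_summaries(st_het, pol)
    expect_equal(tau2_ssc(s)$value,
                 metafor::rma(s$theta_hat, s$v2_cond, method = "GENQ",
                              weights = s$n_tilde)$tau2,
                 tolerance = 1e-8)
  }
})

test_that("SSU approaches SSC as sample sizes grow", {
  # the two moment estimators differ by O(1/n) in their variance inputs
  set.seed(12)
  th <- rnorm(8, 0.4, 0.5)
  rel_gap <- sapply(c(1, 10, 100), function(sc) {
    st <- simulate_study(rep(200 * sc, 8), 0.5, 0.3, th)
    st <- filter_studies(st)$kept
    a <- tau2_ssu(st, "naive")$raw
    b <- tau2_ssc(st, "always")$raw
    abs(a - b)
  })
  expect_true(all(diff(rel_gap) < 0))
})

test_that("median-unbiased estimators meet the CDF = 1/2 contract", {
  s <- study_summaries(st_het, "only")
  smc <- tau2_smc(s)
  expect_gt(smc$value, 0)
  expect_equal(qf_cdf(s, q_f(s)$q, smc$value), 0.5, tolerance = 1e-6)
  sa <- study_summaries(st_het, "always")
  for (variant in c("model", "naive")) {
    smu <- tau2_smu(st_het, variant)
    expect_equal(qf_cdf(sa, q_f(sa)$q, smu$value,
                        variant = paste0("uncond_", variant)),
                 0.5, tolerance = 1e-6)
  }
  # observed Q below the null median -> estimate 0
  hom <- study_summaries(lor_studies(c(10, 10, 11), c(50, 50, 50),
                                     c(10, 10, 10), c(50, 50, 50)), "only")
  expect_equal(tau2_smc(hom)$value, 0)
})

test_that("SMU collapses to SMC when its moments are forced conditional", {
  s <- study_summaries(st_het, "always")
  forced <- lorhet:::tau2_median_core(s, function(t2) s$v2_cond + t2,
                                      "SMU", "always", "forced")
  expect_equal(forced$value, tau2_smc(s)$value, tolerance = 1e-8)
})

test_that("all estimators are nonnegative and permutation invariant", {
  s <- study_summaries(st_het, "only")
  perm <- c(7, 1, 12, 4, 2, 9, 3, 11, 5, 10, 8, 6)
  for (m in c("DL", "MP", "SSC", "SMC")) {
    a <- tau2_estimate(s, m)
    b <- tau2_estimate(s[perm, ], m)
    expect_gte(a$value, 0)
    expect_equal(a$value, b$value, tolerance = 1e-7)
  }
  for (m in c("SSU model", "SSU naive", "SMU model", "SMU naive")) {
    a <- tau2_estimate(st_het, m)
    b <- tau2_estimate(st_het[perm, ], m)
    expect_gte(a$value, 0)
    expect_equal(a$value, b$value, tolerance = 1e-7)
  }
})

test_that("moment estimators recover tau2 on large balanced samples", {
  # K = 30 studies of n = 250, pi_c = 0.5, theta = 0.5, tau2 = 0.4:
  # SSC 'always' and SSU model should be nearly unbiased
  reps <- 2000
  tau2 <- 0.4
  ssc <- ssu <- numeric(reps)
  sc <- scenario(0.5, tau2, 30, 250, 0.5, reps = reps, seed = 424)
  for (r in seq_len(reps)) {
    st <- simulate_meta(sc, r)
    ssc[r] <- tau2_ssc(st, "always")$value
    ssu[r] <- tau2_ssu(st, "model")$value
  }
  se <- sd(ssc) / sqrt(reps)
  expect_lt(abs(mean(ssc) - tau2), 0.05 + 3 * se)
  expect_lt(abs(mean(ssu) - tau2), 0.05 + 3 * se)
})
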