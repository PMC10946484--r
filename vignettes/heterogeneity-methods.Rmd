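---
title: "Estimating the heterogeneity variance for log-odds-ratio meta-analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the heterogeneity variance for log-odds-ratio meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lorhet)
```

## The model

Each of $K$ studies compares a treatment and a control arm on a binary
outcome. Study $i$ contributes independent binomial counts
$X_{iT} \sim \mathrm{Bin}(n_{iT}, p_{iT})$ and
$X_{iC} \sim \mathrm{Bin}(n_{iC}, p_{iC})$, and the effect measure is the
log-odds-ratio
$\theta_i = \mathrm{logit}(p_{iT}) - \mathrm{logit}(p_{iC})$. The
random-effects model takes
$\mathrm{logit}(p_{iT}) = \mathrm{logit}(p_{iC}) + \theta_i$ with
$\theta_i \sim N(\theta, \tau^2)$ and fixed control-arm probabilities.
The target of this package is $\tau^2$, the between-study (heterogeneity)
variance.

Two estimators of the arm probabilities are supported: maximum likelihood
$\tilde p = x/n$ and the bias-adjusted $\hat p = (x + 0.5)/(n + 1)$, which
removes the $O(1/n)$ bias of the estimated log-odds and is always inside
$(0,1)$. The *zero-cell policy* decides which studies use $\hat p$:
`"only"` adjusts a study exactly when one of its four cells
($x_T$, $x_C$, $n_T - x_T$, $n_C - x_C$) is zero, `"always"` adjusts every
study. Whenever $\hat p$ is used, $n + 1$ replaces $n$ in the variance
denominators as well, giving the large-sample-unbiased delta-method
variance
$\hat v_i^2 = [N_T\,\hat p_T(1-\hat p_T)]^{-1} + [N_C\,\hat p_C(1-\hat p_C)]^{-1}$.
Studies with zero events in both arms ("double-zero") or all events in
both arms ("double-n") carry no information about the odds ratio and are
dropped by `filter_studies()`, the prevalent practice.

## Two Q statistics

Cochran's $Q = \sum_i w_i (\hat\theta_i - \bar\theta_w)^2$ underlies
moment estimation of $\tau^2$. The familiar version, $Q_{IV}$, uses
estimated inverse-variance weights $w_i = 1/\hat v_i^2$; because the
weights are themselves noisy functions of the data, its null distribution
is poorly approximated by $\chi^2_{K-1}$ in small samples, and estimators
built on it (DerSimonian-Laird in particular) inherit substantial bias.

The alternative studied here, $Q_F$, uses *fixed* effective-sample-size
weights $w_i = \tilde n_i = n_{iC} n_{iT} / n_i$ — constants that involve
no variance estimate. Writing $W = \sum w_i$ and $q_i = w_i / W$, the
first moment under the random-effects model is

$$E\,Q_F = W \sum_i q_i (1 - q_i) M_{2i},$$

where $M_{2i}$ is the second moment of $\hat\theta_i$ about $\theta$:
conditionally $M_{2i} = v_i^2 + \tau^2$, and unconditionally
$M_{2i} = E v_i^2 + \tau^2 C_i$ (next section). Equating observed and
expected $Q_F$ and solving for $\tau^2$ gives the moment estimators; using
the median of the distribution of $Q_F$ instead gives the median-unbiased
estimators.

## Unconditional variance and the inflation factor

With fixed control-arm probabilities, the variance of $\hat\theta_i$ under
the random-effects model decomposes as
$\mathrm{Var}(\hat\theta_i) = E v_i^2 + \tau^2 C_i$ with

$$C_i = \left(1 + \frac{1}{2\,n_{iT}\,p_{iT}(1 - p_{iT})}\right)^{2} \ge 1 ,$$

so the heterogeneity term is inflated relative to the conditional
decomposition $v_i^2 + \tau^2$. $C_i \to 1$ as $n_{iT}$ grows and
decreases monotonically in $n_{iT}$; `inflation_factor()` exposes it
directly. Two estimates of the treatment probability inside $Ev_i^2$ and
$C_i$ are available:

* **naive** — the study's own adjusted proportion $\hat p_{iT}$, with
  $n_{iT}+1$ in the denominators; at $\tau^2 = 0$ this makes the
  unconditional variance *identical* to the adjusted conditional variance,
  preserving the inflation structure;
* **model-based** — $\bar p_{iT} = \mathrm{expit}(\hat\alpha_i + \hat\theta)$
  with $\hat\alpha_i = \mathrm{logit}(\hat p_{iC})$ and $\hat\theta$ a
  pooled effect. Because $\bar p_{iT}$ is not itself an add-0.5
  proportion, the treatment denominator keeps $n_{iT}$ (the control arm,
  which always uses $\hat p_{iC}$, keeps $n_{iC}+1$).

Which pooled $\hat\theta$ enters $\bar p_{iT}$ is a genuinely open design
point; this package uses the fixed effective-sample-size weighted mean
(`pooled_ssw()`), consistent with the fixed-weights framework in which
these estimators live, and all model-variant functions accept an explicit
`theta_pooled` argument (e.g. an inverse-variance pooled value) for
sensitivity analysis.

## The distribution of $Q_F$ and the Ruben-Farebrother series

Conditionally on the weights, $Q_F = \hat\theta' B \hat\theta$ with
$B = W(\mathrm{diag}(q) - qq')$, a nonnegative quadratic form in
asymptotically normal variables. With
$S = \mathrm{diag}(M_{21}, \dots, M_{2K})$, $Q_F$ is distributed as
$\sum_k \lambda_k z_k^2$ where the $\lambda_k$ are the eigenvalues of
$S^{1/2} B S^{1/2}$ and $z_k$ are independent standard normals. $B$
annihilates the constant vector, so exactly one eigenvalue is a structural
zero; `qf_spectrum()` removes it (cutoff $10^{-10}\lambda_{\max}$) and
warns if more than one eigenvalue falls below the cutoff, which signals a
degenerate input.

`ruben_cdf()` evaluates $P(\sum_k \lambda_k z_k^2 \le x)$ by Ruben's
expansion into a mixture of central chi-square CDFs — the series that the
Farebrother algorithm implements. Numerical choices:

* centering constant
  $\beta = 2\lambda_{\min}\lambda_{\max} / (\lambda_{\min}+\lambda_{\max})$,
  which keeps every mixing ratio $1 - \beta/\lambda_k$ inside $(-1, 1)$;
* truncation tolerance `tol = 1e-9` (far below any statistical resolution
  used downstream), with the series stopped once the chi-square factor of
  the next terms is below `tol` or the running terms are negligible for
  four consecutive iterations;
* a cap of 10,000 terms; if it is ever hit, the function falls back to a
  100,000-draw Monte-Carlo estimate with a warning.

The test suite validates the series against the exact $\chi^2_1$ /
$\chi^2_2$ closed forms, an independent Imhof-type numerical inversion of
the characteristic function (agreement to $10^{-6}$ or better), and
million-draw Monte-Carlo estimates.

`qf_cdf()` composes the second-moment model with the spectrum and the
series to give $F(x \mid \tau^2)$, which is strictly decreasing in
$\tau^2$ for fixed $x > 0$ — the monotone profile that all root-finding
below relies on.

## The estimator battery

Point estimators (`tau2_estimate()` dispatches on the labels):

| Label | Construction | Policies |
|---|---|---|
| DL | moment, $Q_{IV}$ vs $\chi^2$ expectation | only / always |
| REML | restricted likelihood, fixed-point iteration | only / always |
| MP | $Q_{gen}(\tau^2) = K - 1$, weights $1/(\hat v_i^2+\tau^2)$ | only / always |
| SSC | moment, $Q_F$ with conditional variances | only / always |
| SSU model / naive | moment, $Q_F$ with unconditional variances | always |
| SMC | median-unbiased, $F(Q_F \mid \tau^2) = 1/2$, conditional | only / always |
| SMU model / naive | median-unbiased, unconditional | always |

The unconditional estimators are defined with adjusted proportions in
every study, hence they exist only in the `"always"` version — the
policy pairing mirrors how the estimators are defined. All moment
estimators are truncated at zero with the raw (possibly negative) value
retained for diagnostics; the median-type estimators are zero whenever the
observed $Q_F$ falls below the median of its $\tau^2 = 0$ distribution.

Interval estimators: Q-profile (QP) inverts
$Q_{gen}(\tau^2)$ against $\chi^2_{K-1}$ quantiles; profile likelihood
(PL) inverts the likelihood-ratio statistic with $\theta$ profiled out in
closed form; FPC and FPU (model/naive) invert $F(Q_F \mid \tau^2)$ against
$\alpha/2$ and $1-\alpha/2$, with miscoverage split equally between the
tails. Boundary conventions: when even $\tau^2 = 0$ lies above the
acceptance region the interval is reported as $[0, 0]$ with status
`degenerate_zero`; when only the lower constraint binds at zero, the lower
limit is 0 — this is what produces the $[0, U]$ intervals typical of
small meta-analyses. The upper search doubles an initial bracket of 5 up
to a cap of $10^4$; beyond the cap the status is `upper_unbounded`.

All scalar root-finding uses Brent's method (`stats::uniroot`) with
absolute tolerance $10^{-9}$ on $\tau^2$ inside the monotone brackets
described above: the profiles are strictly monotone, so bracketing is
guaranteed, and Brent needs roughly a third of the function evaluations of
plain bisection — which matters because each evaluation of
$F(Q_F \mid \tau^2)$ costs an eigen-decomposition plus a series
evaluation. The endpoint contracts ($|F - \text{target}| \le 10^{-6}$ at
interior endpoints, and the analogous conditions for QP and PL) are
asserted in the test suite. The REML fixed-point iteration uses relative
tolerance $10^{-8}$ with a 1,000-iteration cap and reports a `converged`
flag.

## Simulation harness

`scenario_grid()` reproduces the full factorial design under which these
estimators have been studied: $\theta \in \{0, 0.1, 0.5, 1, 1.5, 2\}$,
$\tau^2 \in \{0, 0.1, \dots, 1\}$, $K \in \{5, 10, 30\}$, equal total
sizes $n \in \{20, 40, 100, 250\}$ plus four skewed unequal-size sets with
averages $\{30, 60, 100, 160\}$ (skewness 1.464, each $K=5$ set reused
twice or six times for larger $K$), $p_{iC} \in \{0.1, 0.2, 0.5\}$, and a
control fraction of $1/2$ throughout — 4,752 scenarios, run at 10,000
repetitions by default. `run_scenario()` discards repetitions in which
fewer than 3 studies survive the degenerate-study filter and reports the
number actually used; failures of an individual estimator within a
repetition are excluded from that estimator's aggregate only.

Reported metrics are mean bias, median bias
$P(\hat\tau^2 \ge \tau^2) - P(\hat\tau^2 \le \tau^2)$ (ties count in both
tails, so the all-zero estimates arising at $\tau^2 = 0$ score 0), and for
intervals the coverage with its one-sided decomposition into *miss-left*
($\tau^2$ below the lower limit) and *miss-right* ($\tau^2$ above the
upper limit), which sum to one with coverage.

Randomness is organized as one documented seed per (scenario, repetition):
repetition $r$ of a scenario with seed $s$ uses Mersenne-Twister seeded
with $(s \bmod 100003)\cdot 10007 + r$, so results are independent of
execution order and reproducible rep-by-rep. The generator emulates the
design faithfully — binomial counts with a fixed control fraction, normal
random effects, fixed (not shuffled) assignment of the unequal sizes to
studies — but of course not every feature of real data: control-arm
probabilities in real reviews vary across studies and may correlate with
effects or arm sizes, events are not always independent binomials, and
selective publication is absent. Passing the simulation benchmarks
therefore validates the estimators under the stated model, not their
behavior on arbitrary real data.

Scale of the shipped checks: the test suite runs the two documented bias
benchmarks and the median-bias benchmark at the design's full 10,000
repetitions, the coverage check of FPC `"always"` at 2,000 repetitions,
and the large-sample recovery check (K = 30, n = 250) at 2,000
repetitions; these sizes keep Monte-Carlo error well below the effects
being checked. The full 4,752-scenario sweep is available as a batch job
via `scenario_grid()` + `run_scenario()` but is deliberately not a test.

## The worked-example machinery

`analyze()` produces the quantities a practitioner reports: both Q
statistics with their tests (chi-square for $Q_{IV}$; the upper
Ruben-Farebrother tail at $\tau^2 = 0$, in model-based and naive versions,
for $Q_F$), $I^2 = \max(0, (Q_{IV} - (K-1))/Q_{IV})$, pooled effects
(common-effect and random-effects inverse variance, and the fixed
effective-sample-size weighted mean), and any subset of the estimator
battery. Note that some published analyses report $I^2$ computed from a
fitted $\tau^2$ and a typical within-study variance rather than from the
$(Q - df)/Q$ formula; the two disagree in general, and this package uses
the $Q$-based definition.

`make_fixture()` generates deterministic synthetic datasets, including a
`"stead_like"` profile shaped like a large smoking-cessation review (17
mostly balanced studies, total sizes 182-3128, event probabilities around
0.04-0.06) for examples and reader tests. These counts are synthetic; the
original review's per-study counts are distributed in its supplementary
material and can be supplied to `read_studies()` directly.

## Known limitations

* The Farebrother approximation to $Q_F$ (and the chi-square approximation
  to $Q_{IV}$) is accurate for moderate-to-large samples but degrades for
  small $n$ combined with small event probabilities; the package reports,
  and does not attempt to repair, this — it is visible in the simulation
  harness as unbalanced miss-left/miss-right rates.
* The profile-likelihood interval relies on the normal within-study
  approximation and is known to over-cover; it is included as a
  comparator.
* Estimators based on an improved gamma approximation to $Q_{IV}$ (the
  Kulinskaya-Dollinger family) and one-stage GLMM methods are out of
  scope, as are relative-risk and risk-difference effect measures.

## Session info

```{r}
sessionInfo()
```
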