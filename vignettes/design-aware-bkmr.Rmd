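---
title: "Design-aware Bayesian kernel machine regression: models, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design-aware Bayesian kernel machine regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svybkmr)
```

## The problem

National biomonitoring surveys (NHANES being the canonical example) are
collected under stratified, multi-stage cluster designs with unequal
inclusion probabilities. Bayesian kernel machine regression (BKMR), the
workhorse for nonlinear exposure-mixture analysis in environmental
epidemiology, has no native notion of sampling weights, primary sampling
units (PSUs), or strata. Analysts therefore usually fit BKMR unweighted and
hope the design does not matter. `svybkmr` is a simulation laboratory for
asking, quantitatively, when it does matter and how much of the damage a
practical workaround repairs.

Two workflows are compared on identical survey samples:

* **naive**: BKMR fit directly to the sample; uncertainty from posterior
  credible intervals of a single fit;
* **design-aware**: the analysis dataset is redrawn B times by a
  weight-proportional, PSU-preserving bootstrap, BKMR is refit on every
  resample, and uncertainty comes from percentiles of the replicate
  estimates (replication-based intervals, deliberately *not* called
  posterior credible intervals).

## The data-generating mechanism

A finite population of `N_pop` (default 20,000) units carries M exposures
drawn from a mean-zero multivariate normal with exchangeable correlation
`rho` (unit variances, constant off-diagonal). The known response surface is

$$h(z_1,z_2,z_3) = 1.0\,z_1 z_2 + 0.5\,z_1^2 - 0.6\,z_2^2 + 0.30\,z_3 +
0.25\,z_3^2,$$

extended in the ten-exposure setting by $0.1 z_k$ for $k = 4,\dots,10$.
Outcomes are $Y_i = h(Z_i) + u_{c(i)} + \varepsilon_i$ with
$\varepsilon_i \sim N(0, \sigma^2_\varepsilon)$
($\sigma^2_\varepsilon = 1$) and a cluster effect
$u_c \sim N(0, \sigma^2_u)$ constant within each PSU. The intraclass
correlation is calibrated through
$\mathrm{ICC} = \sigma^2_u/(\sigma^2_u + \sigma^2_\varepsilon)$, so
ICC = 0.15 gives $\sigma^2_u = 0.1765$.

The population is split into C = 120 contiguous PSU blocks (the first
`N_pop mod C` PSUs take one extra unit — cluster sizes are a package choice,
since only their number is prescribed) assigned cyclically to H = 6 strata
(`stratum(c) = ((c - 1) mod H) + 1`).

**What the generator does not emulate**: non-normal or skewed exposure
marginals (real biomonitoring data are heavily right-skewed), measurement
error, covariate structure beyond an intercept, nonresponse, and
non-exchangeable correlation. Passing tests therefore demonstrate the
behavior of the workflows under a clean, favorable mechanism; they do not
certify performance on real survey data.

## Survey design and weights

Stage one selects `k_h = 4` PSUs per stratum by simple random sampling
without replacement. Stage two is either

* `srs`: `m_c` units per selected PSU, simple-randomly; or
* `pps`: units drawn without replacement with probabilities proportional to
  the shifted positive function
  $p_{ic} \propto \max(Z_{1i} - \min_{j \in c} Z_{1j} + 10^{-6},\, 0)$,
  normalized within the cluster. Because $Z_1$ drives the outcome through
  $h$, this selection is informative.

Within-PSU takes allocate `floor(n / (H k_h))` per PSU with the remainder
spread one unit each over the first selected PSUs in label order, so the
realized sample size is exactly `n`. Approximate inclusion probabilities
follow the two-stage product
$\pi_i \approx (k_h / C_h) \times \Pr(i \mid c)$ with
$\Pr(i \mid c) = m_c/N_c$ (SRS) or $\min(1, m_c\, p_{ic})$ (PPS); they are
approximations by construction, not exact without-replacement inclusion
probabilities. Base weights $w_i = 1/\pi_i$ are rescaled to mean one within
the sample; no trimming is applied. The without-replacement PPS draws use
successive sampling (R's `sample(prob = )`), which is distributionally the
exponential-key method.

## The kernel machine model and its sampler

The model is $Y \sim N(X\beta,\ \sigma^2 (I + \lambda K))$, the marginal
form of $Y = X\beta + h + \varepsilon$ with
$h \sim \mathrm{GP}(0, \tau K)$, $\lambda = \tau/\sigma^2$, and the
component-scaled Gaussian RBF kernel

$$K(z, z') = \exp\Big\{-\sum_m r_m (z_m - z'_m)^2\Big\}, \qquad r_m \ge 0.$$

Variable selection works through the scales: $r_m = 0$ removes exposure m,
and a spike-and-slab prior puts mass on exactly that event. Priors (all
exposed in `bkmr_config()`): flat on $\beta$; inverse-gamma(0.001, 0.001)
on $\sigma^2$; gamma(1, 0.1) on $\lambda$ with a log-random-walk proposal
of step 0.5; inclusion indicators Bernoulli(0.5); slab uniform(0, 100) on
each $r_m$ with birth proposals uniform(0, 10) and a within-model
log-random-walk of step 0.3. Exposures are standardized internally and the
transform stored, so pre-standardized input is equivalent.

Each MCMC iteration applies **one** Metropolis move to a uniformly chosen
component of $(\lambda, r_1, \dots, r_M)$ — birth/death/within-model for an
$r_m$ under variable selection — followed by conjugate Gibbs updates of
$\beta$ and $\sigma^2$ against the marginalized likelihood. The
one-component-per-iteration scan keeps the per-iteration cost at a single
Cholesky factorization, which is what makes hundreds of bootstrap refits
tractable; with the default chain lengths each scale parameter still
receives on the order of a thousand proposals. Chain defaults are
4000/2000/2 (iterations/burn-in/thinning, 1000 retained draws) for main
fits and 2500/1000/2 for bootstrap replicates. Acceptance rates are logged
per move type, and `compute_rhat()` provides a split-chain potential scale
reduction factor; convergence diagnostics beyond that are deliberately out
of scope.

### Numerical choices

* All factorizations are symmetric positive-definite Cholesky
  decompositions with a diagonal jitter of $10^{-8}$; nothing is ever
  explicitly inverted.
* Bootstrap resamples repeat exposure rows bit-identically, and the
  likelihood factors exactly through the unique rows: with
  $K = P K_u P^\top$, $C = P^\top P$, $W = C^{1/2}$, every log-determinant
  and quadratic form reduces to the $u \times u$ matrix
  $B = I_u + \lambda W K_u W$ (a Woodbury/determinant-lemma identity,
  verified against dense algebra in the test suite). With no duplicates the
  reduction is the standard dense computation. This cuts replicate-fit cost
  roughly in proportion to $(u/n)^3$.
* Posterior draws of $h$ at requested points are accumulated during the
  chain, reusing each iteration's factorization, whenever the points are
  known before fitting.
* All randomness flows through R's RNG, so L'Ecuyer-CMRG streams make
  parallel replicate runs bit-reproducible and independent of worker count.

## Estimands and summaries

The primary estimand is the overall mixture effect
$\Delta = h(q_{0.75}) - h(q_{0.25})$, all exposures moved jointly between
their marginal quartiles. Because the simulated marginals are standard
normal, the true value uses theoretical quantiles by default
($\Delta^* = 0.6\,\Phi^{-1}(0.75) \approx 0.4047$ for the three-exposure
surface); an option recomputes it from each population's empirical
quantiles. In the analysis workflows the contrast is evaluated at the
*analysis dataset's* quantiles — the field's standard convention — which is
itself one of the channels through which informative sampling biases the
naive workflow (selection shifts the sample quantiles of $Z_1$). The
design-aware replicates use their own resampled dataset's quantiles, which
approximate the population's. The analytic quadratic reference fitter (next
section) instead targets the estimand's known quantile points, because its
role is checking harness calibration, not reproducing analyst practice.

Secondary summaries (univariate curves, bivariate conditional-quantile
families, single-variable 25th-to-75th risk contrasts, and the overall
effect curve across joint quantiles) all evaluate $h$ at finite point sets.
The GP surface is identified only up to a constant traded against the
intercept, so every curve is reported relative to the all-median reference
point (the overall curve is pinned to zero at q = 0.50, per draw); contrasts
are unaffected. Naive, design-aware and oracle variants share grids and
centering so they are directly comparable, and every interval carries an
explicit `interval_kind` label ("posterior-credible", "replication-based",
or "oracle").

`h_spec()` coefficients are stored as data, which gives an *oracle mode*:
every summary can be evaluated on the true polynomial surface exactly,
letting the test suite pin down the summary plumbing independently of MCMC.

## The design-aware workflow

Per replicate, within each stratum the sample's PSUs are redrawn with
replacement (as many draws as the stratum had PSUs) with probabilities
proportional to each PSU's **sum** of weights; within each drawn PSU, units
are redrawn with replacement proportional to their weights. The stratum's
original multiset of within-PSU takes is retained as the takes of the
redrawn slots — when takes are equal this is the same as giving each drawn
PSU its own original take, and when they are not (sample sizes that do not
divide evenly over 24 PSUs) it is the only rule that keeps the per-stratum
and total sizes exact in every resample. The mean-weight rule is also
implemented (`psu_prob_rule = "mean_weights"`) since both conventions
circulate; they coincide under equal takes. A PSU
drawn twice contributes two independent unit resamples under distinct
labels — the standard with-replacement cluster bootstrap. Scalars aggregate
across replicates by the empirical mean with 2.5th/97.5th percentile
intervals (linear interpolation between order statistics, R quantile type
7); functional summaries aggregate pointwise. Replicate fits that fail are
skipped with a warning; a run aborts below 80% success.

## The Monte-Carlo harness

`run_scenario()` crosses sample size, exposure correlation, ICC, and
sampling regime; for each of R replicates it generates a fresh population,
draws a fresh sample, and applies both workflows to that identical sample,
then `compute_metrics()` reports bias, mean 95%-interval width, empirical
coverage (closed intervals), and RMSE against $\Delta^*$. The full
factorial grid (3 sample sizes x 2 correlations x 2 ICCs x 2 regimes)
yields 24 scenarios per mixture size.

Besides the kernel machine fitter, the harness exposes
`fitter = "quadratic"`: a conjugate Bayesian regression on the basis
$\{1, z_m, z_m^2, z_j z_k\}$ whose posterior contrasts are closed-form
Student-t. The basis contains the true surface, so with known quantile
points its 95% intervals are exactly calibrated — a fast, analytic
reference for validating the Monte-Carlo and resampling plumbing (it is
*not* a substitute analysis model, and the headline comparisons all use the
kernel machine fitter).

## Problem sizes used by the shipped checks

The test suite and the acceptance script run reduced versions of the study
conditions, chosen as the package's own test sizes: the informative-sampling
comparison uses n = 300, rho = 0.8, ICC = 0.15 with R = 20-30 Monte-Carlo
replicates, B = 10-20 bootstrap replicates, and chains of 1500-2000
iterations; the calibration benchmark uses the quadratic reference model at
n = 800 with R = 100; PIP saturation uses the full 4000-iteration default
chain at n = 300 under SRS with rho = 0. Full-scale settings (R = 100,
B = 50, default chains) remain the package defaults.

## Design choices where the design was open

* **Quantile source for $\Delta^*$**: theoretical normal quantiles by
  default (the inferential target is the superpopulation mean);
  population-empirical offered as a flag.
* **PSU resampling probabilities**: the sum-of-weights rule is the default,
  the mean-weight rule a documented alternative.
* **Sampler scan order**: one random component per iteration rather than a
  full sweep, for the cost reasons above.
* **PIP aggregation across replicates**: the design-aware PIP for an
  exposure is the mean of its per-replicate PIPs.
* **Replicate failure policy** (skip, 80% floor) and the percentile
  definition (type 7) are package conventions.
* **Interval for the naive workflow**: equal-tailed 95% posterior credible
  interval of the $\Delta$ draws.

## Known limitations

The design-aware workflow is a design-based approximation, not a weighted
likelihood or pseudo-posterior: its intervals are replication-based and,
as the simulations themselves show, improve but do not fully restore
nominal coverage under informative sampling. The simulator's clean normal
world understates real-data difficulties (skewness, measurement error,
nonresponse). Replicate-weight schemes (BRR, jackknife), weight trimming,
multiple-imputation combination, and binary outcomes are out of scope.
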