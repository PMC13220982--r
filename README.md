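# svybkmr — design-aware Bayesian kernel machine regression for complex surveys

Bayesian kernel machine regression (BKMR) is the standard tool for
estimating nonlinear, interactive exposure–response surfaces
h(z<sub>1</sub>, …, z<sub>M</sub>) for environmental chemical mixtures. The
population surveys those mixtures are measured in (stratified, two-stage
cluster designs with unequal inclusion probabilities) are exactly the kind
of data BKMR has no native support for: no weights, no PSUs, no replicate
variance estimation. `svybkmr` is a simulation laboratory plus analysis
toolkit for quantifying what that omission costs and how much a practical,
software-compatible workaround recovers.

It provides, end to end:

* a **finite-population simulator** with exchangeably correlated exposures,
  a known polynomial response surface, and ICC-calibrated cluster random
  effects — so the true overall mixture effect
  Δ\* = h(q<sub>0.75</sub>) − h(q<sub>0.25</sub>) is known exactly
  (0.4047 for the three-exposure surface);
* a **stratified two-stage sampler** with non-informative (SRS) and
  informative (PPS-like, selection proportional to a shifted function of
  Z<sub>1</sub>) within-PSU selection, approximate inclusion probabilities
  π<sub>i</sub> ≈ (k<sub>h</sub>/C<sub>h</sub>)·Pr(i|c), and mean-one
  rescaled weights w<sub>i</sub> = 1/π<sub>i</sub>;
* a **BKMR core**: Y ~ N(Xβ, σ²(I + λK)) with a component-scaled Gaussian
  RBF kernel and spike-and-slab variable selection (PIPs, group PIPs,
  conditional PIPs), fit by an RcppArmadillo Metropolis-within-Gibbs
  sampler;
* the **design-aware workflow**: B-fold weight-proportional, PSU-preserving
  bootstrap resampling with a BKMR refit per replicate and
  replication-based (percentile) intervals;
* **mixture summaries** (overall effect and its quantile curve, univariate
  and bivariate response functions, single-variable risk contrasts) with
  explicit interval-kind labels, plus an exact oracle mode on the true
  surface;
* a **Monte-Carlo harness** measuring bias, interval width, empirical 95%
  coverage, and RMSE against Δ\* over a full factorial of sample size,
  exposure correlation, ICC, and sampling regime.

## A worked example

Informative sampling, correlated exposures, clustered outcomes — the
setting where the naive analysis breaks:

```r
library(svybkmr)

pop  <- generate_population(population_config(N_pop = 20000, M = 3,
                                              rho = 0.8, icc = 0.15, seed = 1))
samp <- draw_sample(pop, sampling_design(n_total = 300, regime = "pps", seed = 2))

fit <- mcmc_fit(samp$y, as.matrix(as.data.frame(samp)[, c("z1","z2","z3")]),
                config = bkmr_config(seed = 3))
estimate_delta(fit)
#> 1.4747 [1.1206, 1.8256] (95% posterior-credible interval, 1000 values)

daf <- run_design_aware(samp, resample_plan(B = 20, seed = 4),
                        summaries = list(summarize_delta()))
estimate_delta(daf)
#> 0.2863 [-1.3612, 2.4566] (95% replication-based interval, 20 values)

true_overall_effect(h_spec("h3"), estimand_spec())$delta_star
#> [1] 0.4046939
```

The naive fit reports an overall mixture effect of 1.47 with a tight
credible interval that misses the true value (0.405) by a wide margin —
informative selection over-represents high-Z₁ units, and the analysis
inherits that distortion. The design-aware workflow re-expresses the sample
as a weighted empirical distribution before refitting: its point estimate
(0.29) moves back near the truth and its wider, honest replication-based
interval covers it. The same fits show PIP attenuation under the naive
analysis (z₂ PIP 0.01 versus 0.94 design-aware, mean over replicates).

Scenario-level operating characteristics come from the harness:

```r
m <- scenario_metrics(run_scenario(scenario_spec(
  n_total = 300, rho = 0.8, icc = 0.15, regime = "pps",
  R = 20, B = 20, seed = 7)))
m[, c("workflow", "bias", "width", "coverage", "rmse")]
```

which reports, per workflow, the bias and RMSE of Δ̂, the mean 95%-interval
width, and the empirical coverage over R Monte-Carlo replicates.

There is also a thin command-line wrapper (`inst/cli/svybkmr`) with
`simulate`, `sample`, `fit`, and `evaluate` subcommands driven by YAML/JSON
configs; every output is paired with a config echo that reproduces it.

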