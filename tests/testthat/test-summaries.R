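# Closed-form values for the oracle surface checks below come from direct
# evaluation of the polynomial surface.

test_that("oracle overall effect reproduces the closed-form contrast", {
  hs <- h_spec("h3")
  a <- qnorm(0.75)
  d <- estimate_delta(hs)
  expect_equal(d$point, 0.6 * a, tolerance = 1e-12)
  expect_equal(d$lo, d$point)
  expect_equal(d$interval_kind, "oracle")
  # identical quantile pair gives exactly zero
  expect_equal(estimate_delta(hs, lower_q = 0.4999999,
                              upper_q = 0.5000001)$point, 0,
               tolerance = 1e-5)
  # a flat surface has zero contrast everywhere
  flat <- h_spec("h3", base = rep(0, 5))
  expect_equal(estimate_delta(flat)$point, 0)
})

test_that("oracle overall curve is zero at the median and matches h on the grid", {
  hs <- h_spec("h3")
  cur <- overall_effect_curve(hs, quantiles = seq(0.25, 0.75, 0.05))
  ref <- which(abs(cur$q - 0.5) < 1e-12)
  expect_equal(cur$point[ref], 0)
  expect_equal(cur$hi - cur$lo, rep(0, nrow(cur)))
  for (i in seq_len(nrow(cur))) {
    z <- rep(qnorm(cur$q[i]), 3)
    expect_equal(cur$point[i], h_true(z, hs) - h_true(rep(0, 3), hs))
  }
  expect_error(overall_effect_curve(hs, quantiles = c(0.25, 0.75)),
               "include the reference")
  expect_error(overall_effect_curve(hs, quantiles = c(0, 0.5)), "inside")
})

test_that("oracle univariate responses restrict the polynomial correctly", {
  hs <- h_spec("h3")
  g <- seq(-2, 2, length.out = 9)
  # exposure 3, others at 0: 0.3 z + 0.25 z^2
  u3 <- univariate_response(hs, j = 3, grid = g)
  expect_equal(u3$point, 0.3 * g + 0.25 * g^2)
  # exposure 1, others at 0: cross term vanishes, leaving 0.5 z^2
  u1 <- univariate_response(hs, j = 1, grid = g)
  expect_equal(u1$point, 0.5 * g^2)
  expect_error(univariate_response(hs, j = 4), "out of range")
})

test_that("oracle bivariate curves expose the interaction structure", {
  hs <- h_spec("h3")
  g <- seq(-1, 1, length.out = 5)
  bv <- bivariate_response(hs, j = 1, k = 2, grid = g)
  # slope in z1 depends on the z2 level through the z1 z2 term:
  # h(z1, z2, 0) = z1 z2 + 0.5 z1^2 - 0.6 z2^2
  for (cq in unique(bv$cond_quantile)) {
    z2 <- qnorm(cq)
    i <- bv$cond_quantile == cq
    expect_equal(bv$point[i], g * z2 + 0.5 * g^2 - 0.6 * z2^2)
  }
  # an additive surface yields parallel curves (vertical shifts only)
  add <- h_spec("h3", base = c(z1z2 = 0, z1sq = 0.5, z2sq = -0.6,
                               z3 = 0.3, z3sq = 0.25))
  bv2 <- bivariate_response(add, j = 1, k = 2, grid = g)
  curves <- split(bv2$point, bv2$cond_quantile)
  gaps <- vapply(curves, function(cu) cu - curves[[1]], numeric(length(g)))
  expect_true(all(abs(sweep(gaps, 2, gaps[1, ])) < 1e-12))
  # conditioning at the median reproduces the univariate curve
  u <- univariate_response(hs, j = 1, grid = g)
  expect_equal(bv$point[bv$cond_quantile == 0.5], u$point)
  expect_error(bivariate_response(hs, j = 2, k = 2), "differ")
})

test_that("oracle single-variable risks follow the polynomial arithmetic", {
  hs <- h_spec("h3")
  a <- qnorm(0.75)
  for (qf in c(0.25, 0.5, 0.75)) {
    rk <- single_variable_risks(hs, q_fixed = qf)
    # exposure 3: 0.3(a - (-a)) + 0.25(a^2 - a^2) = 0.6a at any q_fixed
    expect_equal(rk$point[3], 0.6 * a, tolerance = 1e-12)
  }
  # exposure 1 at the median background: even term cancels and z2 = 0
  rk50 <- single_variable_risks(hs, q_fixed = 0.5)
  expect_equal(rk50$point[1], 0)
  # flat surface: all contrasts zero
  flat <- h_spec("h3", base = rep(0, 5))
  expect_equal(single_variable_risks(flat, q_fixed = 0.5)$point, rep(0, 3))
  expect_equal(round(single_variable_risks(hs, q_fixed = 0.5)$point[3], 4),
               0.4047)
})

test_that("empirical quantiles are monotone and feed the joint quantile point", {
  set.seed(71)
  dat <- data.frame(z1 = rnorm(500), z2 = rnorm(500), z3 = rnorm(500))
  q <- exposure_quantiles(dat, c(0.1, 0.5, 0.9))
  expect_true(all(diff(q[, 1]) > 0))
  expect_equal(dim(q), c(3L, 3L))
  expect_equal(as.numeric(q["0.5", ]),
               apply(as.matrix(dat), 2, median), ignore_attr = TRUE)
  expect_error(exposure_quantiles(dat, c(0, 0.5)), "probs > 0")
})

test_that("fitted summaries converge to the oracle on low-noise data", {
  dat <- surface_data(500, sigma_eps = 0.1, seed = 72)
  colnames(dat$Z) <- paste0("z", 1:3)
  fit <- mcmc_fit(dat$y, dat$Z,
                  config = bkmr_config(iters = 1500, burnin = 750, thin = 2,
                                       seed = 73))
  hs <- h_spec("h3")
  # overall effect at the data's own quantiles
  d_fit <- estimate_delta(fit)
  d_orc <- estimate_delta(hs, data = dat$Z)
  expect_equal(d_fit$point, d_orc$point, tolerance = 0.1)
  expect_equal(d_fit$interval_kind, "posterior-credible")
  # univariate response for z3 on a central grid
  g <- seq(-1, 1, length.out = 7)
  u_fit <- univariate_response(fit, j = 3, grid = g, ndraws = 200)
  u_orc <- univariate_response(hs, j = 3, grid = g, data = dat$Z)
  expect_lt(max(abs(u_fit$point - u_orc$point)), 0.12)
  # single-variable risks at the median background
  r_fit <- single_variable_risks(fit, q_fixed = 0.5, ndraws = 200)
  r_orc <- single_variable_risks(hs, q_fixed = 0.5, data = dat$Z)
  expect_lt(max(abs(r_fit$point - r_orc$point)), 0.12)
})

test_that("the fitted overall curve is pinned to zero at the median in every draw", {
  dat <- surface_data(80, seed = 74)
  fit <- mcmc_fit(dat$y, dat$Z, config = test_config(iters = 100,
                                                     burnin = 50, seed = 75))
  cur <- overall_effect_curve(fit, quantiles = c(0.3, 0.5, 0.7),
                              ndraws = 30)
  i <- which(cur$q == 0.5)
  expect_equal(cur$point[i], 0)
  expect_equal(cur$lo[i], 0)
  expect_equal(cur$hi[i], 0)
})

test_that("every summary carries an interval-kind label", {
  hs <- h_spec("h3")
  expect_equal(attr(univariate_response(hs, 1), "interval_kind"), "oracle")
  expect_equal(attr(overall_effect_curve(hs), "interval_kind"), "oracle")
  dat <- surface_data(40, seed = 76)
  fit <- mcmc_fit(dat$y, dat$Z, config = test_config(iters = 40, burnin = 20,
                                                     seed = 77))
  expect_equal(estimate_delta(fit, ndraws = 10)$interval_kind,
               "posterior-credible")
  expect_equal(attr(univariate_response(fit, 1, ngrid = 5, ndraws = 10),
                    "interval_kind"), "posterior-credible")
})

test_that("design-aware summary methods read the matching replicate summaries", {
  pop <- tiny_population(N = 2400L, seed = 78)
  samp <- draw_sample(pop, sampling_design(120, "pps", seed = 79))
  g <- seq(-1, 1, length.out = 5)
  plan <- resample_plan(B = 3, replicate_config = test_config(iters = 60,
                                                              burnin = 30),
                        seed = 80)
  daf <- run_design_aware(
    samp, plan,
    summaries = list(summarize_delta(), summarize_overall_curve(),
                     summarize_univariate(1, g),
                     summarize_bivariate(1, 2, g), summarize_risks(0.5)))
  expect_equal(estimate_delta(daf)$interval_kind, "replication-based")
  cur <- overall_effect_curve(daf)
  expect_equal(cur$point[cur$q == 0.5], 0)
  expect_equal(attr(cur, "interval_kind"), "replication-based")
  u <- univariate_response(daf, 1)
  expect_equal(u$z, g)
  bv <- bivariate_response(daf, 1, 2)
  expect_equal(nrow(bv), 15)
  rk <- single_variable_risks(daf, q_fixed = 0.5)
  expect_equal(nrow(rk), 3)
  # requesting a summary that was not computed fails with guidance
  expect_error(single_variable_risks(daf, q_fixed = 0.25), "rerun")
})
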