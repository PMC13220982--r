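test_that("exchangeable covariance has unit diagonal, constant off-diagonal", {
  expect_equal(make_exchangeable_cov(3, 0), diag(3))
  S <- make_exchangeable_cov(2, 0.8)
  expect_equal(S, matrix(c(1, 0.8, 0.8, 1), 2))
  S10 <- make_exchangeable_cov(10, 0.5)
  expect_true(all(diag(S10) == 1))
  expect_true(all(S10[upper.tri(S10)] == 0.5))
  expect_true(min(eigen(S10, only.values = TRUE)$values) > 0)
})

test_that("non-positive-definite correlations are rejected with the eigenvalue condition", {
  # smallest eigenvalue 1 + 2*rho = -0.2 at rho = -0.6, M = 3
  expect_error(make_exchangeable_cov(3, -0.6), "eigenvalue")
  expect_error(make_exchangeable_cov(3, 1), "eigenvalue")
  expect_error(make_exchangeable_cov(5, -0.3), "eigenvalue")
  # boundary inside the admissible range is fine
  expect_silent(make_exchangeable_cov(3, -0.49))
})

test_that("the exposure-response surface evaluates term by term", {
  expect_equal(h_true(c(0, 0, 0)), 0)
  expect_equal(h_true(c(1, 1, 1)), 1.45)  # 1 + 0.5 - 0.6 + 0.3 + 0.25
  expect_equal(h_true(rep(1, 10), h_spec("h10")), 1.45 + 7 * 0.1)
  # matrix evaluation matches rowwise evaluation
  Z <- matrix(rnorm(15), 5, 3)
  expect_equal(h_true(Z), apply(Z, 1, function(z) h_true(z)))
  expect_error(h_true(c(1, 2), h_spec("h3")), "3 exposures")
  expect_error(h_true(rep(1, 3), h_spec("h10")), "10 exposures")
})

test_that("the ten-exposure surface restricted to zero tail equals the three-exposure surface", {
  set.seed(42)
  for (i in 1:20) {
    z3 <- rnorm(3)
    expect_equal(h_true(c(z3, rep(0, 7)), h_spec("h10")),
                 h_true(z3, h_spec("h3")))
  }
})

test_that("ICC calibration matches the variance-ratio formula and inverts", {
  expect_equal(round(icc_to_sigma_u2(0.15, 1), 4), 0.1765)
  expect_equal(icc_to_sigma_u2(0, 1), 0)
  expect_equal(icc_to_sigma_u2(0.5, 1), 1.0)
  expect_error(icc_to_sigma_u2(1, 1), "< 1")
  for (icc in c(0, 0.15, 0.5, 0.9)) {
    expect_equal(sigma_u2_to_icc(icc_to_sigma_u2(icc, 2.3), 2.3), icc,
                 tolerance = 1e-12)
  }
})

test_that("PSU blocks are contiguous, near-equal, and cyclically stratified", {
  # N = C: every PSU has one unit, strata all equal
  pop1 <- generate_population(population_config(N_pop = 120, C = 120, H = 6,
                                                seed = 1))
  expect_true(all(table(pop1$data$psu) == 1))
  expect_true(all(table(pop1$data$stratum) == 20))

  # 20000 = 120*166 + 80: first 80 PSUs get 167
  sizes <- svybkmr:::psu_block_sizes(20000L, 120L)
  expect_equal(sum(sizes == 167), 80)
  expect_equal(sum(sizes == 166), 40)
  expect_equal(which(sizes == 167), 1:80)

  pop <- tiny_population(N = 1201L)
  tab <- table(pop$data$psu)
  expect_true(max(tab) - min(tab) <= 1)
  # stratum of PSU c is ((c-1) mod H) + 1, and each PSU is in one stratum
  map <- unique(pop$data[, c("psu", "stratum")])
  expect_equal(nrow(map), pop$config$C)
  expect_equal(map$stratum, ((map$psu - 1) %% pop$config$H) + 1)
  # contiguity: psu labels are nondecreasing in unit order
  expect_true(all(diff(pop$data$psu) >= 0))
})

test_that("outcome decomposes exactly and the cluster effect is constant within PSU", {
  pop <- tiny_population(icc = 0.15, seed = 7)
  d <- pop$data
  expect_equal(d$y, d$h_true + d$u + d$eps)
  expect_true(all(tapply(d$u, d$psu, function(x) diff(range(x))) == 0))
  # icc = 0 silences the cluster effect entirely
  pop0 <- tiny_population(icc = 0, seed = 8)
  expect_true(all(pop0$data$u == 0))
})

test_that("generated exposures match the requested correlation and variance structure", {
  pop <- generate_population(population_config(N_pop = 20000, M = 3,
                                               rho = 0.8, icc = 0.15,
                                               seed = 3))
  Z <- as.matrix(pop$data[, c("z1", "z2", "z3")])
  cors <- cor(Z)[upper.tri(diag(3))]
  expect_true(all(abs(cors - 0.8) < 0.02))
  # exchangeability: off-diagonal correlations agree with each other
  expect_lt(diff(range(cors)), 0.03)
  # variance decomposition: Var(Y) ~ Var(h) + sigma_u2 + sigma_eps2 within 5%
  vy <- var(pop$data$y)
  expect_equal(vy, var(pop$data$h_true) + pop$sigma_u2 + 1,
               tolerance = 0.05)
})

test_that("the same seed reproduces the population exactly", {
  cfg <- population_config(N_pop = 500, M = 3, rho = 0.3, icc = 0.15,
                           C = 24, H = 6, seed = 99)
  expect_identical(generate_population(cfg), generate_population(cfg))
})

test_that("the true overall effect follows the joint quantile contrast", {
  es <- estimand_spec(0.3, 0.7)
  es$lower_q <- es$upper_q <- 0.5
  expect_equal(true_overall_effect(h_spec("h3"), es)$delta_star, 0)
  # even terms cancel at +/- qnorm(0.75), leaving 0.6 * 0.6745
  a <- qnorm(0.75)
  expect_equal(true_overall_effect(h_spec("h3"), estimand_spec())$delta_star,
               0.6 * a, tolerance = 1e-12)
  expect_equal(round(true_overall_effect(h_spec("h3"),
                                         estimand_spec())$delta_star, 4),
               0.4047)
  # each tail exposure adds 0.1 * 2a
  expect_equal(true_overall_effect(h_spec("h10"),
                                   estimand_spec())$delta_star,
               0.6 * a + 7 * 0.1 * 2 * a, tolerance = 1e-12)
  # empirical source needs a population
  expect_error(true_overall_effect(
    h_spec("h3"), estimand_spec(quantile_source = "population-empirical")),
    "population")
  pop <- tiny_population(N = 5000L)
  d_emp <- true_overall_effect(
    h_spec("h3"), estimand_spec(quantile_source = "population-empirical"),
    pop)$delta_star
  expect_equal(d_emp, 0.6 * a, tolerance = 0.2)
})

test_that("population CSV + sidecar round trip preserves data and truth metadata", {
  pop <- tiny_population(N = 300L, icc = 0.15, seed = 5)
  path <- file.path(withr::local_tempdir(), "pop.csv")
  write_population(pop, path)
  back <- read_population(path)
  expect_equal(back$data$y, pop$data$y)
  expect_equal(back$data$z1, pop$data$z1)
  expect_equal(back$sigma_u2, pop$sigma_u2)
  expect_equal(back$config$rho, pop$config$rho)
  expect_equal(back$spec$base, pop$spec$base)
})
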