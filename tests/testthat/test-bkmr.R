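test_that("the RBF kernel has unit diagonal, r-weighted distances, and null limits", {
  z <- matrix(rnorm(9), 3, 3)
  K <- rbf_kernel(z, z, c(0.5, 1, 2))
  expect_equal(diag(K), rep(1, 3))
  expect_equal(K, t(K))
  expect_true(all(K > 0 & K <= 1))
  # r = 0 removes every exposure: all entries 1
  expect_equal(rbf_kernel(z, z, c(0, 0, 0)), matrix(1, 3, 3))
  # single pair at unit scale
  expect_equal(rbf_kernel(matrix(0), matrix(1), 1)[1, 1], exp(-1))
  # direct formula on a random pair
  a <- rnorm(3); b <- rnorm(3); r <- runif(3)
  expect_equal(rbf_kernel(rbind(a), rbind(b), r)[1, 1],
               exp(-sum(r * (a - b)^2)))
  expect_error(rbf_kernel(z, z, c(-1, 0, 0)), "nonnegative")
})

test_that("the marginal log-likelihood matches a dense multivariate-normal oracle", {
  set.seed(11)
  for (n in c(1, 5, 10)) {
    Z <- matrix(rnorm(n * 3), n, 3)
    X <- cbind(1, rnorm(n))
    y <- rnorm(n)
    beta <- c(0.5, -0.2)
    sigma2 <- 1.3; lambda <- 2; r <- c(0.7, 0, 1.1)
    jit <- 1e-8
    ll <- marginal_loglik(y, X, Z, beta, sigma2, lambda, r, jitter = jit)
    Sigma <- sigma2 * ((1 + jit) * diag(n) + lambda * rbf_kernel(Z, Z, r))
    expect_equal(ll, dense_mvn_loglik(y, X %*% beta, Sigma),
                 tolerance = 1e-8)
  }
  # n = 1 collapses to a univariate normal with variance sigma2 (1 + lambda)
  ll1 <- marginal_loglik(0.4, matrix(1), matrix(0.3), 0.1, 2, 3, 1,
                         jitter = 0)
  expect_equal(ll1, dnorm(0.4, 0.1, sqrt(2 * (1 + 3)), log = TRUE))
  # lambda -> 0 recovers the ordinary linear-model log-likelihood
  set.seed(12)
  y <- rnorm(8); X <- matrix(1, 8, 1); Z <- matrix(rnorm(24), 8, 3)
  ll0 <- marginal_loglik(y, X, Z, 0.2, 1.5, 0, c(1, 1, 1), jitter = 0)
  expect_equal(ll0, sum(dnorm(y, 0.2, sqrt(1.5), log = TRUE)))
})

test_that("the duplicate-row reduction reproduces dense algebra exactly", {
  set.seed(13)
  n <- 30
  Z <- matrix(rnorm(n * 3), n, 3)
  Z[21:30, ] <- Z[sample(10, 10, replace = TRUE), ]  # repeated rows
  y <- rnorm(n); X <- matrix(1, n, 1); beta <- 0.4
  lambda <- 1.7; r <- c(0.6, 0.2, 0); jit <- 1e-8
  red <- svybkmr:::unique_rows(Z)
  expect_lt(nrow(red$Zu), n)
  out <- svybkmr:::reduced_quad_logdet_cpp(y, X, beta, red$Zu, red$grp0,
                                           red$counts, r, lambda, jit)
  A <- (1 + jit) * diag(n) + lambda * rbf_kernel(Z, Z, r)
  resid <- y - X %*% beta
  expect_equal(out$logdet, as.numeric(determinant(A)$modulus),
               tolerance = 1e-10)
  expect_equal(out$quad, drop(t(resid) %*% solve(A) %*% resid),
               tolerance = 1e-8)
})

test_that("the GP conditional mean matches a dense-algebra oracle", {
  set.seed(14)
  n <- 5; M <- 3
  dat <- surface_data(n, M, sigma_eps = 0.5, seed = 14)
  fit <- mcmc_fit(dat$y, dat$Z, config = test_config(iters = 40, burnin = 20,
                                                     thin = 1, seed = 2))
  Znew <- matrix(rnorm(2 * M), 2, M)
  H <- posterior_h(fit, Znew, draw_noise = FALSE)
  Zs <- scale(fit$Z, fit$z_center, fit$z_scale)
  Zns <- scale(Znew, fit$z_center, fit$z_scale)
  for (t in c(1, 10, 20)) {
    r <- fit$draws$r[t, ]; lam <- fit$draws$lambda[t]
    beta <- fit$draws$beta[t, ]
    K <- rbf_kernel(Zs, Zs, r)
    Kx <- rbf_kernel(Zns, Zs, r)
    A <- (1 + fit$config$jitter) * diag(n) + lam * K
    oracle <- lam * Kx %*% solve(A, fit$y - fit$X %*% beta)
    expect_equal(unname(H[t, ]), drop(oracle), tolerance = 1e-8)
  }
})

test_that("a null kernel scale makes the surface flat across query points", {
  dat <- surface_data(20, seed = 15)
  fit <- mcmc_fit(dat$y, dat$Z, config = test_config(iters = 20, burnin = 10,
                                                     seed = 3))
  fit$draws$r[] <- 0
  H <- posterior_h(fit, matrix(rnorm(12), 4, 3), draw_noise = FALSE)
  expect_true(all(abs(H - H[, 1]) < 1e-10))
})

test_that("a fixed seed yields a bit-identical draw sequence", {
  dat <- surface_data(40, seed = 16)
  cfg <- test_config(iters = 200, burnin = 100, seed = 7)
  f1 <- mcmc_fit(dat$y, dat$Z, config = cfg)
  f2 <- mcmc_fit(dat$y, dat$Z, config = cfg)
  expect_identical(f1$draws, f2$draws)
})

test_that("fitting pre-standardized exposures is equivalent up to the stored transform", {
  dat <- surface_data(40, seed = 17)
  cfg <- test_config(iters = 100, burnin = 50, seed = 9)
  f_raw <- mcmc_fit(dat$y, dat$Z, config = cfg)
  Zs <- scale(dat$Z)
  f_std <- mcmc_fit(dat$y, Zs, config = cfg)
  expect_equal(f_raw$draws$r, f_std$draws$r)
  expect_equal(f_raw$draws$lambda, f_std$draws$lambda)
  # surface queries map through each fit's own transform to the same draws
  znew <- dat$Z[1:2, ]
  znew_s <- scale(znew, attr(Zs, "scaled:center"), attr(Zs, "scaled:scale"))
  expect_equal(posterior_h(f_raw, znew, draw_noise = FALSE),
               posterior_h(f_std, znew_s, draw_noise = FALSE),
               tolerance = 1e-10)
})

test_that("chain settings validate and T retained draws are produced", {
  expect_error(bkmr_config(iters = 100, burnin = 100, thin = 2),
               "positive integer")
  expect_error(bkmr_config(iters = 103, burnin = 100, thin = 2),
               "positive integer")
  cfg <- bkmr_config(iters = 110, burnin = 100, thin = 2, seed = 1)
  expect_equal(cfg$T, 5L)
  dat <- surface_data(15, seed = 18)
  fit <- mcmc_fit(dat$y, dat$Z, config = cfg)
  expect_equal(nrow(fit$draws$r), 5L)
  expect_error(mcmc_fit(c(dat$y[-1], NA), dat$Z, config = cfg), "missing")
})

test_that("noise-free signal data switch exposures on; pure-noise data leave them off", {
  # strong signal: all three exposures included essentially always
  dat <- surface_data(150, sigma_eps = 0.3, seed = 19)
  fit <- mcmc_fit(dat$y, dat$Z,
                  config = test_config(iters = 800, burnin = 400, seed = 20))
  expect_true(all(compute_pips(fit) > 0.9))
  # no signal: inclusion stays below one half for most seeds
  hits <- 0L
  for (s in 1:5) {
    set.seed(300 + s)
    Zn <- matrix(rnorm(100 * 3), 100, 3)
    yn <- rnorm(100)
    fitn <- mcmc_fit(yn, Zn, config = test_config(iters = 800, burnin = 400,
                                                  seed = s))
    if (all(compute_pips(fitn) < 0.5)) hits <- hits + 1L
  }
  expect_gte(hits, 3L)
})

test_that("the residual variance is recovered on data simulated from the model", {
  # sigma2 = 1 truth; the 95% interval should contain it in most short chains
  hits <- 0L
  nseeds <- 10L
  for (s in seq_len(nseeds)) {
    dat <- surface_data(120, sigma_eps = 1, seed = 400 + s)
    fit <- mcmc_fit(dat$y, dat$Z,
                    config = test_config(iters = 700, burnin = 350,
                                         seed = s))
    ci <- quantile(fit$draws$sigma2, c(0.025, 0.975))
    if (ci[1] <= 1 && 1 <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits, 0.8 * nseeds)
})
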