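# Shared fixtures, built in code at test time.

# small population for structural tests
tiny_population <- function(N = 1200L, M = 3L, rho = 0, icc = 0,
                            C = 24L, H = 6L, seed = 101L) {
  generate_population(population_config(N_pop = N, M = M, rho = rho,
                                        icc = icc, C = C, H = H,
                                        seed = seed))
}

# i.i.d. data straight from the surface (no survey structure), for fit tests
surface_data <- function(n, M = 3L, sigma_eps = 1, seed = 1L,
                         spec = h_spec("h3")) {
  set.seed(seed)
  Z <- matrix(rnorm(n * M), n, M)
  y <- h_true(Z, spec) + rnorm(n, 0, sigma_eps)
  list(y = y, Z = Z)
}

# fast chain settings for unit tests
test_config <- function(iters = 600L, burnin = 300L, thin = 1L, ...) {
  bkmr_config(iters = iters, burnin = burnin, thin = thin, ...)
}

# dense multivariate-normal log-density, independent of the package's
# factorization path
dense_mvn_loglik <- function(y, mu, Sigma) {
  n <- length(y)
  ld <- as.numeric(determinant(Sigma, logarithm = TRUE)$modulus)
  q <- drop(t(y - mu) %*% solve(Sigma) %*% (y - mu))
  -0.5 * (n * log(2 * pi) + ld + q)
}
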