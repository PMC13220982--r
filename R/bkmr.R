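#' Gaussian RBF kernel with per-exposure scales
#'
#' \deqn{K(z, z') = \exp\{-\sum_m r_m (z_m - z'_m)^2\}.}
#' Component scales implement variable selection: \code{r_m = 0} removes
#' exposure m from the surface entirely.
#'
#' @param Z_a,Z_b matrices of points (rows), same column count as
#'   \code{length(r)}.
#' @param r nonnegative per-exposure kernel scales.
#' @return the \code{nrow(Z_a)} x \code{nrow(Z_b)} kernel matrix.
#' @export
rbf_kernel <- function(Z_a, Z_b, r) {
  Z_a <- as.matrix(Z_a); Z_b <- as.matrix(Z_b)
  stopifnot(ncol(Z_a) == length(r), ncol(Z_b) == length(r))
  if (any(r < 0)) stop("kernel scales r must be nonnegative")
  rbf_kernel_cpp(Z_a, Z_b, as.numeric(r))
}

#' Marginal log-likelihood of the kernel machine model
#'
#' Log density of \code{Y ~ N(X beta, sigma2 * (I + lambda K))} with
#' \code{K = rbf_kernel(Z, Z, r)}, the marginalized representation in which
#' the nonparametric surface h has been integrated out of the Gaussian
#' process prior. Factorizations use the symmetric positive-definite
#' Cholesky decomposition with a small diagonal jitter; the matrix is never
#' inverted explicitly.
#'
#' @param y outcome vector.
#' @param X design matrix of adjustment covariates (intercept-only in the
#'   simulations).
#' @param Z exposure matrix.
#' @param beta,sigma2,lambda,r model parameters (see [bkmr_config()]).
#' @param jitter diagonal stabilizer, default 1e-8.
#' @return the log-likelihood (finite scalar).
#' @export
marginal_loglik <- function(y, X, Z, beta, sigma2, lambda, r,
                            jitter = 1e-8) {
  y <- as.numeric(y); X <- as.matrix(X); Z <- as.matrix(Z)
  stopifnot(nrow(X) == length(y), nrow(Z) == length(y),
            length(beta) == ncol(X), sigma2 > 0, lambda >= 0, all(r >= 0))
  K <- rbf_kernel_cpp(Z, Z, as.numeric(r))
  ll <- marginal_loglik_cpp(y, X, as.numeric(beta), sigma2, lambda, K, jitter)
  if (!is.finite(ll)) stop("non-finite marginal log-likelihood")
  ll
}

#' MCMC configuration for the kernel machine sampler
#'
#' Chain-length defaults follow the main-analysis settings (4000 iterations,
#' burn-in 2000, thinning 2, i.e. 1000 retained draws); bootstrap replicates
#' use [bkmr_config_replicate()] (2500/1000/2). Priors: flat on beta,
#' inverse-gamma(0.001, 0.001) on sigma2, gamma(1, 0.1) on lambda with a
#' log-random-walk proposal (step 0.5), Bernoulli(0.5) inclusion, uniform
#' (0, 100) slab on each kernel scale with birth proposals from uniform
#' (0, 10) and a within-model log random walk (step 0.3).
#'
#' @param iters,burnin,thin chain settings; (iters - burnin)/thin must be a
#'   positive integer.
#' @param varsel enable spike-and-slab variable selection.
#' @param a_sig,b_sig inverse-gamma prior on the residual variance.
#' @param a_lam,b_lam gamma(shape, rate) prior on the GP-to-noise ratio
#'   lambda.
#' @param lam_step,r_step log-random-walk proposal steps.
#' @param r_slab_max,r_birth_max slab upper bound and birth-proposal bound.
#' @param delta_prior prior inclusion probability for each exposure.
#' @param jitter diagonal stabilizer added before factorization.
#' @param lambda_init,r_init initial values.
#' @param seed integer RNG seed for [mcmc_fit()].
#' @return an object of class \code{bkmr_config}.
#' @export
bkmr_config <- function(iters = 4000L, burnin = 2000L, thin = 2L,
                        varsel = TRUE,
                        a_sig = 0.001, b_sig = 0.001,
                        a_lam = 1, b_lam = 0.1, lam_step = 0.5,
                        r_step = 0.3, r_slab_max = 100, r_birth_max = 10,
                        delta_prior = 0.5, jitter = 1e-8,
                        lambda_init = 1, r_init = 0.1, seed = 1L) {
  iters <- as.integer(iters); burnin <- as.integer(burnin)
  thin <- as.integer(thin)
  T_keep <- (iters - burnin) / thin
  if (T_keep <= 0 || T_keep != round(T_keep)) {
    stop("(iters - burnin)/thin must be a positive integer")
  }
  stopifnot(delta_prior > 0, delta_prior < 1, jitter >= 0,
            r_slab_max > 0, r_birth_max > 0, r_birth_max <= r_slab_max)
  structure(list(iters = iters, burnin = burnin, thin = thin,
                 varsel = isTRUE(varsel), a_sig = a_sig, b_sig = b_sig,
                 a_lam = a_lam, b_lam = b_lam, lam_step = lam_step,
                 r_step = r_step, r_slab_max = r_slab_max,
                 r_birth_max = r_birth_max, delta_prior = delta_prior,
                 jitter = jitter, lambda_init = lambda_init,
                 r_init = r_init, seed = as.integer(seed),
                 T = as.integer(T_keep)),
            class = "bkmr_config")
}

#' @rdname bkmr_config
#' @param ... further overrides passed to [bkmr_config()].
#' @export
bkmr_config_replicate <- function(iters = 2500L, burnin = 1000L, thin = 2L,
                                  ...) {
  bkmr_config(iters = iters, burnin = burnin, thin = thin, ...)
}

#' Fit Bayesian kernel machine regression by MCMC
#'
#' Exposures are standardized (centered and scaled) internally; the stored
#' transform maps query points into the fitted space, so fitting on
#' pre-standardized exposures is equivalent up to that transform. Each MCMC
#' iteration applies one Metropolis move to a randomly chosen component of
#' (lambda, r_1, ..., r_M) — a log random walk for lambda, a mixed
#' birth/death/within-model move for each kernel scale under variable
#' selection — followed by conjugate Gibbs updates of beta and sigma2
#' against the marginalized likelihood.
#'
#' @param y outcome vector (no missing values).
#' @param Z exposure matrix.
#' @param X covariate matrix; default intercept-only.
#' @param config a [bkmr_config()].
#' @param h_points optional matrix of points (original exposure scale) at
#'   which h draws are accumulated during sampling; cheaper than post-hoc
#'   [posterior_h()] because the current factorization is reused.
#' @param h_draw_noise draw from the full GP conditional (TRUE) or store
#'   conditional means only.
#' @return an object of class \code{bkmr_fit} with elements \code{draws}
#'   (r, delta, lambda, sigma2, beta, h), \code{accept} (acceptance rates by
#'   move type), the standardization transform, data, and config.
#' @export
mcmc_fit <- function(y, Z, X = NULL, config = bkmr_config(),
                     h_points = NULL, h_draw_noise = TRUE) {
  y <- as.numeric(y)
  Z <- as.matrix(Z)
  n <- length(y)
  stopifnot(nrow(Z) == n, inherits(config, "bkmr_config"))
  if (anyNA(y) || anyNA(Z)) stop("missing values are not supported")
  if (is.null(X)) X <- matrix(1, n, 1L)
  X <- as.matrix(X)
  stopifnot(nrow(X) == n)

  z_center <- colMeans(Z)
  z_scale <- apply(Z, 2L, stats::sd)
  z_scale[z_scale == 0 | !is.finite(z_scale)] <- 1
  Zs <- scale(Z, center = z_center, scale = z_scale)
  Znew <- if (is.null(h_points)) {
    matrix(0, 0L, ncol(Z))
  } else {
    scale(matrix(h_points, ncol = ncol(Z)), center = z_center,
          scale = z_scale)
  }

  red <- unique_rows(Zs)
  set.seed(config$seed)
  res <- bkmr_mcmc_cpp(y, Zs, X, Znew,
                       red$grp0, red$counts, red$Zu,
                       config$iters, config$burnin, config$thin,
                       config$varsel,
                       config$a_sig, config$b_sig,
                       config$a_lam, config$b_lam, config$lam_step,
                       config$r_step, config$r_slab_max, config$r_birth_max,
                       config$delta_prior, config$jitter,
                       config$lambda_init, config$r_init,
                       isTRUE(h_draw_noise))
  zn <- colnames(Z)
  if (is.null(zn)) zn <- paste0("z", seq_len(ncol(Z)))
  colnames(res$r) <- colnames(res$delta) <- zn

  structure(list(draws = res[c("r", "delta", "lambda", "sigma2", "beta", "h")],
                 accept = res$accept,
                 z_center = z_center, z_scale = z_scale,
                 y = y, Z = Z, X = X,
                 h_points = h_points, config = config),
            class = "bkmr_fit")
}

#' @export
print.bkmr_fit <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Kernel machine regression fit: n = %d, M = %d exposures\n",
    length(x$y), ncol(x$Z)))
  cat(sprintf("  %d iterations (burn-in %d, thin %d) -> %d retained draws\n",
              cfg$iters, cfg$burnin, cfg$thin, cfg$T))
  if (cfg$varsel) {
    pips <- compute_pips(x)
    cat("  PIPs:", paste(sprintf("%s = %.2f", names(pips), pips),
                         collapse = ", "), "\n")
  }
  acc <- x$accept
  cat("  acceptance:", paste(sprintf("%s %.2f", names(acc), acc),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Posterior draws of the exposure-response surface at new points
#'
#' For each retained draw, h(Z_new) is sampled from (or, with
#' \code{draw_noise = FALSE}, set to the mean of) the Gaussian conditional of
#' the GP given the data and that draw's parameters:
#' mean \code{lambda K* (I + lambda K)^-1 (y - X beta)}.
#'
#' @param fit a [mcmc_fit()] result.
#' @param Z_new matrix of query points on the original exposure scale.
#' @param draw_noise include the conditional GP variance.
#' @param ndraws optionally thin to this many retained draws (evenly spaced)
#'   to bound the per-draw factorization cost.
#' @return a T x nrow(Z_new) matrix of h draws.
#' @export
posterior_h <- function(fit, Z_new, draw_noise = TRUE, ndraws = NULL) {
  stopifnot(inherits(fit, "bkmr_fit"))
  Z_new <- matrix(as.matrix(Z_new), ncol = ncol(fit$Z))
  Zs <- scale(fit$Z, center = fit$z_center, scale = fit$z_scale)
  Zns <- scale(Z_new, center = fit$z_center, scale = fit$z_scale)
  dr <- fit$draws
  keep <- seq_len(nrow(dr$r))
  if (!is.null(ndraws) && ndraws < length(keep)) {
    keep <- unique(round(seq(1L, length(keep), length.out = ndraws)))
  }
  red <- unique_rows(Zs)
  posterior_h_cpp(fit$y, fit$X, Zns, red$grp0, red$counts, red$Zu,
                  dr$r[keep, , drop = FALSE], dr$lambda[keep],
                  dr$sigma2[keep], dr$beta[keep, , drop = FALSE],
                  fit$config$jitter, isTRUE(draw_noise))
}

# Exact duplicate-row reduction: bootstrap resamples repeat exposure rows
# bit-identically, and the marginalized likelihood factors through the
# unique rows (see the kernel machine sampler). Hex formatting makes the
# row keys exact.
unique_rows <- function(Z) {
  keys <- do.call(paste, lapply(seq_len(ncol(Z)), function(j) {
    sprintf("%a", Z[, j])
  }))
  first <- !duplicated(keys)
  grp <- match(keys, keys[first])
  list(Zu = Z[first, , drop = FALSE],
       grp0 = as.integer(grp - 1L),
       counts = as.numeric(tabulate(grp, nbins = sum(first))))
}

#' Serialize a fit to a directory archive of columnar text
#'
#' Draws are written as CSV tables (one per parameter block) and the chain
#' configuration plus standardization transform as a JSON echo, so a fit can
#' be archived and reloaded without binary formats.
#'
#' @param fit a [mcmc_fit()] result.
#' @param dir directory to create/populate.
#' @export
write_fit_archive <- function(fit, dir) {
  stopifnot(inherits(fit, "bkmr_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cbind(as.data.frame(fit$draws$r),
                         stats::setNames(as.data.frame(fit$draws$delta),
                                         paste0("delta_",
                                                colnames(fit$draws$delta))),
                         lambda = fit$draws$lambda,
                         sigma2 = fit$draws$sigma2,
                         as.data.frame(fit$draws$beta)),
                   file.path(dir, "draws.csv"), row.names = FALSE)
  if (length(fit$draws$h) > 0) {
    utils::write.csv(as.data.frame(fit$draws$h),
                     file.path(dir, "h_draws.csv"), row.names = FALSE)
  }
  meta <- list(config = unclass(fit$config),
               z_center = fit$z_center, z_scale = fit$z_scale,
               accept = as.list(fit$accept))
  jsonlite::write_json(meta, file.path(dir, "fit.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

# ---- inclusion-probability summaries ---------------------------------------

delta_draws <- function(x) {
  if (inherits(x, "bkmr_fit")) x$draws$delta else as.matrix(x)
}

#' Posterior inclusion probabilities
#'
#' The PIP of exposure j is the posterior probability that it was included
#' in the kernel, estimated by the mean of its inclusion indicator over
#' retained draws.
#'
#' @param x a [mcmc_fit()] result, or a T x M 0/1 matrix of inclusion
#'   indicator draws.
#' @return named vector of PIPs in [0, 1].
#' @export
compute_pips <- function(x) {
  if (inherits(x, "bkmr_fit") && !x$config$varsel) {
    warning("variable selection was off; PIPs are 1 by definition")
    return(stats::setNames(rep(1, ncol(x$draws$delta)),
                           colnames(x$draws$delta)))
  }
  colMeans(delta_draws(x))
}

#' Group-level posterior inclusion probabilities
#'
#' The group PIP is the posterior probability that at least one exposure in
#' the group was included; it is always >= the largest member PIP, and a
#' singleton group reproduces its member's PIP.
#'
#' @param x a fit or indicator matrix, as in [compute_pips()].
#' @param groups named list of disjoint exposure index (or name) vectors.
#' @return named vector of group PIPs.
#' @export
group_pips <- function(x, groups) {
  d <- delta_draws(x)
  if (any(lengths(groups) == 0)) stop("empty group")
  idx <- lapply(groups, function(g) {
    if (is.character(g)) match(g, colnames(d)) else as.integer(g)
  })
  all_idx <- unlist(idx)
  if (anyNA(all_idx) || any(all_idx < 1) || any(all_idx > ncol(d))) {
    stop("group members outside the exposure set")
  }
  if (anyDuplicated(all_idx)) stop("groups must be disjoint")
  out <- vapply(idx, function(g) {
    mean(rowSums(d[, g, drop = FALSE]) > 0)
  }, numeric(1))
  if (is.null(names(out))) names(out) <- paste0("g", seq_along(out))
  out
}

#' Conditional posterior inclusion probabilities
#'
#' \code{cPIP[i, j] = P(delta_i = 1 | delta_j = 1)}, estimated as the
#' proportion of retained draws with exposure i included among those with
#' exposure j included. Columns whose conditioning exposure is never
#' included are reported as NA (undefined), not 0.
#'
#' @param x a fit or indicator matrix, as in [compute_pips()].
#' @return M x M matrix with \code{[i, j] = cPIP(i | j)}.
#' @export
conditional_pips <- function(x) {
  d <- delta_draws(x)
  M <- ncol(d)
  out <- matrix(NA_real_, M, M, dimnames = list(colnames(d), colnames(d)))
  for (j in seq_len(M)) {
    on <- d[, j] == 1
    if (any(on)) out[, j] <- colMeans(d[on, , drop = FALSE])
  }
  out
}

#' Split-chain potential scale reduction factor
#'
#' Gelman-Rubin R-hat computed after splitting each chain in half, so a
#' single non-stationary chain is also flagged. Values near 1 indicate
#' convergence.
#'
#' @param chains a list of (or matrix with columns as) equal-length scalar
#'   draw sequences; lengths must be >= 4.
#' @return R-hat (>= 1 up to floating error), or NA if the within-chain
#'   variance is zero.
#' @export
compute_rhat <- function(chains) {
  if (is.matrix(chains)) chains <- asplit(chains, 2L)
  if (is.numeric(chains)) chains <- list(chains)
  lens <- lengths(chains)
  if (length(unique(lens)) != 1L || lens[1L] < 4L) {
    stop("chains must have equal length >= 4")
  }
  half <- lens[1L] %/% 2L
  split_chains <- unlist(lapply(chains, function(ch) {
    ch <- ch[seq_len(2L * half)]
    list(ch[seq_len(half)], ch[half + seq_len(half)])
  }), recursive = FALSE)
  m <- length(split_chains)
  n <- half
  means <- vapply(split_chains, mean, numeric(1))
  vars <- vapply(split_chains, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || W == 0) {
    # degenerate split chains: divergent if their means differ, else no
    # information
    return(if (is.finite(B) && B > 0) Inf else NA_real_)
  }
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}
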