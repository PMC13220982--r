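#' Exchangeable covariance matrix
#'
#' Builds the M x M covariance matrix with unit diagonal and constant
#' off-diagonal correlation \code{rho}, the structure used for the simulated
#' exposure vectors. The matrix is positive definite iff its two distinct
#' eigenvalues, \code{1 + (M-1)*rho} (multiplicity 1) and \code{1 - rho}
#' (multiplicity M-1), are both positive.
#'
#' @param M number of exposures (>= 1).
#' @param rho common pairwise correlation, in (-1/(M-1), 1).
#' @return an M x M numeric matrix.
#' @export
#' @examples
#' make_exchangeable_cov(3, 0.8)
make_exchangeable_cov <- function(M, rho) {
  stopifnot(is.numeric(M), length(M) == 1L, M >= 1, M == round(M))
  stopifnot(is.numeric(rho), length(rho) == 1L, is.finite(rho))
  if (M > 1) {
    ev1 <- 1 + (M - 1) * rho
    ev2 <- 1 - rho
    if (ev1 <= 0 || ev2 <= 0) {
      stop(sprintf(
        paste0("exchangeable correlation rho = %g is not positive definite ",
               "for M = %d: eigenvalues 1+(M-1)*rho = %g and 1-rho = %g ",
               "must both be positive"),
        rho, M, ev1, ev2))
    }
  }
  S <- matrix(rho, M, M)
  diag(S) <- 1
  S
}

#' Exposure-response surface specification
#'
#' The known nonlinear surface used by the simulator. The three-exposure
#' surface is
#' \deqn{h(z_1,z_2,z_3) = 1.0 z_1 z_2 + 0.5 z_1^2 - 0.6 z_2^2 + 0.30 z_3 +
#'   0.25 z_3^2,}
#' and the ten-exposure surface adds a small linear effect \code{0.1 z_k} for
#' each of \code{z_4, ..., z_10}. Coefficients are stored as data so tests can
#' inject degenerate surfaces (e.g. a flat one).
#'
#' @param id "h3" or "h10".
#' @param base named coefficients of the three-exposure terms, in the order
#'   z1*z2, z1^2, z2^2, z3, z3^2.
#' @param tail linear coefficient shared by exposures 4..M (ignored for "h3").
#' @return an object of class \code{h_spec}.
#' @export
h_spec <- function(id = c("h3", "h10"),
                   base = c(z1z2 = 1.0, z1sq = 0.5, z2sq = -0.6,
                            z3 = 0.30, z3sq = 0.25),
                   tail = 0.1) {
  id <- match.arg(id)
  stopifnot(length(base) == 5L, is.numeric(base), is.numeric(tail))
  structure(list(id = id, base = base, tail = tail,
                 M = if (id == "h3") 3L else 10L),
            class = "h_spec")
}

#' Evaluate the true exposure-response surface
#'
#' @param z numeric vector of length M, or an n x M matrix of points.
#' @param spec an [h_spec()].
#' @return numeric vector of surface values.
#' @export
#' @examples
#' h_true(c(1, 1, 1), h_spec("h3"))  # 1 + 0.5 - 0.6 + 0.3 + 0.25 = 1.45
h_true <- function(z, spec = h_spec("h3")) {
  stopifnot(inherits(spec, "h_spec"))
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  if (ncol(z) != spec$M) {
    stop(sprintf("surface '%s' expects %d exposures, got %d columns",
                 spec$id, spec$M, ncol(z)))
  }
  b <- spec$base
  out <- b[[1L]] * z[, 1L] * z[, 2L] + b[[2L]] * z[, 1L]^2 +
    b[[3L]] * z[, 2L]^2 + b[[4L]] * z[, 3L] + b[[5L]] * z[, 3L]^2
  if (spec$M > 3L) {
    out <- out + spec$tail * rowSums(z[, 4:spec$M, drop = FALSE])
  }
  unname(out)
}

#' ICC calibration of the cluster variance
#'
#' Converts an intraclass correlation to the cluster-level variance via
#' \code{ICC = sigma_u2 / (sigma_u2 + sigma_eps2)}, i.e.
#' \code{sigma_u2 = icc/(1-icc) * sigma_eps2}. At ICC = 0.15 and unit residual
#' variance this gives sigma_u2 = 0.1765 (to 4 decimals).
#'
#' @param icc intraclass correlation in [0, 1).
#' @param sigma_eps2 residual variance (> 0), default 1.
#' @return cluster-level variance sigma_u2.
#' @seealso [sigma_u2_to_icc()] for the inverse map.
#' @export
icc_to_sigma_u2 <- function(icc, sigma_eps2 = 1) {
  stopifnot(is.numeric(icc), length(icc) == 1L, icc >= 0,
            is.numeric(sigma_eps2), sigma_eps2 > 0)
  if (icc >= 1) stop("icc must be < 1")
  icc / (1 - icc) * sigma_eps2
}

#' @rdname icc_to_sigma_u2
#' @param sigma_u2 cluster-level variance (>= 0).
#' @export
sigma_u2_to_icc <- function(sigma_u2, sigma_eps2 = 1) {
  stopifnot(sigma_u2 >= 0, sigma_eps2 > 0)
  sigma_u2 / (sigma_u2 + sigma_eps2)
}

#' Population configuration
#'
#' @param N_pop population size.
#' @param M number of exposures (3 or 10 in the shipped study designs, any
#'   positive integer accepted).
#' @param rho exchangeable exposure correlation.
#' @param icc intraclass correlation of the outcome, in [0, 1).
#' @param sigma_eps2 residual variance, default 1.
#' @param C number of PSUs (clusters).
#' @param H number of strata; PSU c belongs to stratum ((c-1) mod H) + 1.
#' @param seed integer RNG seed.
#' @return an object of class \code{population_config}.
#' @export
population_config <- function(N_pop = 20000L, M = 3L, rho = 0, icc = 0,
                              sigma_eps2 = 1, C = 120L, H = 6L, seed = 1L) {
  stopifnot(N_pop >= 1, C >= 1, H >= 1, C >= H, N_pop >= C)
  stopifnot(icc >= 0, icc < 1, sigma_eps2 > 0)
  make_exchangeable_cov(M, rho)  # validates rho for this M
  structure(list(N_pop = as.integer(N_pop), M = as.integer(M), rho = rho,
                 icc = icc, sigma_eps2 = sigma_eps2, C = as.integer(C),
                 H = as.integer(H), seed = as.integer(seed)),
            class = "population_config")
}

# Contiguous block sizes: first (N mod C) PSUs get one extra unit.
psu_block_sizes <- function(N_pop, C) {
  base <- N_pop %/% C
  extra <- N_pop %% C
  sizes <- rep.int(base, C)
  if (extra > 0) sizes[seq_len(extra)] <- base + 1L
  sizes
}

#' Generate a finite population with known truth
#'
#' Draws \code{N_pop} exposure vectors from a mean-zero multivariate normal
#' with exchangeable correlation \code{rho}, partitions units into \code{C}
#' contiguous PSU blocks assigned cyclically to \code{H} strata, adds a
#' cluster random effect with ICC-calibrated variance, and forms the outcome
#' \code{Y = h(Z) + u + eps}. All truth components are stored so the outcome
#' is exactly reconstructible.
#'
#' @param config a [population_config()].
#' @param spec an [h_spec()]; its dimension must equal \code{config$M}.
#' @return an object of class \code{true_population}: a list with a data frame
#'   \code{data} (unit_id, stratum, psu, z1..zM, u, eps, h_true, y), the
#'   config, the surface spec, and \code{sigma_u2}.
#' @export
generate_population <- function(config, spec = NULL) {
  stopifnot(inherits(config, "population_config"))
  if (is.null(spec)) spec <- h_spec(if (config$M == 10L) "h10" else "h3")
  stopifnot(inherits(spec, "h_spec"))
  if (spec$M != config$M) {
    stop(sprintf("surface dimension %d does not match config M = %d",
                 spec$M, config$M))
  }
  set.seed(config$seed)
  N <- config$N_pop
  Sigma <- make_exchangeable_cov(config$M, config$rho)
  Z <- MASS::mvrnorm(N, mu = rep(0, config$M), Sigma = Sigma)
  Z <- matrix(Z, nrow = N)

  sizes <- psu_block_sizes(N, config$C)
  psu <- rep.int(seq_len(config$C), times = sizes)
  stratum <- ((psu - 1L) %% config$H) + 1L

  sigma_u2 <- icc_to_sigma_u2(config$icc, config$sigma_eps2)
  u_c <- if (sigma_u2 > 0) stats::rnorm(config$C, 0, sqrt(sigma_u2)) else
    numeric(config$C)
  u <- u_c[psu]
  eps <- stats::rnorm(N, 0, sqrt(config$sigma_eps2))
  h <- h_true(Z, spec)
  y <- h + u + eps

  dat <- data.frame(unit_id = seq_len(N), stratum = stratum, psu = psu)
  zcols <- as.data.frame(Z)
  names(zcols) <- paste0("z", seq_len(config$M))
  dat <- cbind(dat, zcols)
  dat$u <- u
  dat$eps <- eps
  dat$h_true <- h
  dat$y <- y

  structure(list(data = dat, config = config, spec = spec,
                 sigma_u2 = sigma_u2, psu_sizes = sizes),
            class = "true_population")
}

#' @export
print.true_population <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Finite population: N = %d, M = %d exposures (rho = %g),\n", cfg$N_pop,
    cfg$M, cfg$rho))
  cat(sprintf("  %d PSUs in %d strata; ICC = %g (sigma_u2 = %.4f)\n",
              cfg$C, cfg$H, cfg$icc, x$sigma_u2))
  cat(sprintf("  surface: %s; Var(Y) = %.3f\n", x$spec$id, stats::var(x$data$y)))
  invisible(x)
}

#' Estimand specification and the true overall mixture effect
#'
#' The overall mixture effect contrasts the surface at the joint upper and
#' lower quantile points of the exposures:
#' \deqn{\Delta^* = h(q_{0.75}) - h(q_{0.25}),}
#' with each exposure set to its own marginal p-th quantile. Marginals are
#' standard normal by construction, so the default uses theoretical N(0,1)
#' quantiles; \code{quantile_source = "population-empirical"} instead uses the
#' generated population's empirical quantiles.
#'
#' @param lower_q,upper_q quantile pair in (0,1), defaults 0.25 and 0.75.
#' @param quantile_source "theoretical-normal" or "population-empirical".
#' @return an object of class \code{estimand_spec}.
#' @export
estimand_spec <- function(lower_q = 0.25, upper_q = 0.75,
                          quantile_source = c("theoretical-normal",
                                              "population-empirical")) {
  quantile_source <- match.arg(quantile_source)
  stopifnot(lower_q > 0, upper_q < 1, lower_q < upper_q)
  structure(list(lower_q = lower_q, upper_q = upper_q,
                 quantile_source = quantile_source, delta_star = NULL),
            class = "estimand_spec")
}

#' @rdname estimand_spec
#' @param spec an [h_spec()].
#' @param estimand an \code{estimand_spec}.
#' @param population a [generate_population()] result; required when
#'   \code{quantile_source = "population-empirical"}.
#' @return \code{true_overall_effect} returns the \code{estimand_spec} with
#'   \code{delta_star} filled in.
#' @export
#' @examples
#' true_overall_effect(h_spec("h3"), estimand_spec())$delta_star  # 0.4047
true_overall_effect <- function(spec, estimand = estimand_spec(),
                                population = NULL) {
  stopifnot(inherits(spec, "h_spec"), inherits(estimand, "estimand_spec"))
  M <- spec$M
  if (estimand$quantile_source == "theoretical-normal") {
    q_lo <- rep(stats::qnorm(estimand$lower_q), M)
    q_hi <- rep(stats::qnorm(estimand$upper_q), M)
  } else {
    if (is.null(population)) {
      stop("population-empirical quantiles requested but no population given")
    }
    Z <- as.matrix(population$data[, paste0("z", seq_len(M))])
    q_lo <- apply(Z, 2L, stats::quantile, probs = estimand$lower_q,
                  names = FALSE)
    q_hi <- apply(Z, 2L, stats::quantile, probs = estimand$upper_q,
                  names = FALSE)
  }
  estimand$delta_star <- h_true(q_hi, spec) - h_true(q_lo, spec)
  estimand
}

#' Write / read a population as CSV plus JSON sidecar
#'
#' The CSV holds the unit-level columns; the sidecar records the config,
#' sigma_u2 and surface coefficients so runs can be reproduced bit-for-bit.
#'
#' @param population a [generate_population()] result.
#' @param path CSV path; the sidecar is written to \code{<path>.json}.
#' @export
write_population <- function(population, path) {
  stopifnot(inherits(population, "true_population"))
  utils::write.csv(population$data, path, row.names = FALSE)
  meta <- list(config = unclass(population$config),
               sigma_u2 = population$sigma_u2,
               h_spec = list(id = population$spec$id,
                             base = as.list(population$spec$base),
                             tail = population$spec$tail))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  dat <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- do.call(population_config, as.list(meta$config))
  spec <- h_spec(meta$h_spec$id, base = unlist(meta$h_spec$base),
                 tail = meta$h_spec$tail)
  structure(list(data = dat, config = cfg, spec = spec,
                 sigma_u2 = meta$sigma_u2,
                 psu_sizes = as.integer(table(dat$psu))),
            class = "true_population")
}
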