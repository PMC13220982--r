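#' Conjugate Bayesian quadratic regression (analytic reference model)
#'
#' Fits the outcome on the basis {1, z_m, z_m^2, z_j z_k (j < k)} under the
#' noninformative prior p(beta, sigma2) proportional to 1/sigma2, so every
#' posterior functional of the surface has a closed form (Student-t). The
#' basis contains the true simulated surface, which makes this fitter a fast
#' analytic reference for exercising the Monte-Carlo harness and the
#' resampling plumbing without MCMC; it is not the kernel machine model.
#'
#' @param y outcome vector.
#' @param Z exposure matrix.
#' @return an object of class \code{quad_fit}.
#' @export
quadratic_fit <- function(y, Z) {
  Z <- as.matrix(Z)
  Phi <- quad_basis(Z)
  qr_fit <- stats::lm.fit(Phi, y)
  p <- ncol(Phi)
  n <- length(y)
  if (n <= p) stop("quadratic reference model needs n > basis size")
  rss <- sum(qr_fit$residuals^2)
  XtXinv <- chol2inv(chol(crossprod(Phi)))
  structure(list(coef = qr_fit$coefficients, XtXinv = XtXinv,
                 s2 = rss / (n - p), df = n - p, Z = Z),
            class = "quad_fit")
}

quad_basis <- function(Z) {
  M <- ncol(Z)
  parts <- list(matrix(1, nrow(Z), 1L), Z, Z^2)
  if (M >= 2L) {
    cross <- do.call(cbind, lapply(seq_len(M - 1L), function(j) {
      Z[, j] * Z[, (j + 1L):M, drop = FALSE]
    }))
    parts <- c(parts, list(cross))
  }
  do.call(cbind, parts)
}

# posterior of c'beta is t_df(c'betahat, s2 * c' (X'X)^-1 c)
quad_contrast <- function(fit, z_hi, z_lo, level = 0.95) {
  cvec <- as.numeric(quad_basis(matrix(z_hi, 1L)) -
                       quad_basis(matrix(z_lo, 1L)))
  point <- sum(cvec * fit$coef)
  se <- sqrt(fit$s2 * drop(cvec %*% fit$XtXinv %*% cvec))
  tq <- stats::qt(1 - (1 - level) / 2, fit$df)
  structure(list(point = point, lo = point - tq * se, hi = point + tq * se,
                 interval_kind = "posterior-credible", level = level, B = 1L),
            class = "aggregated_estimate")
}

#' @rdname estimate_delta
#' @export
estimate_delta.quad_fit <- function(object, data = NULL, lower_q = 0.25,
                                    upper_q = 0.75, ...) {
  data <- if (is.null(data)) object$Z else data
  quad_contrast(object,
                joint_quantile_point(data, upper_q),
                joint_quantile_point(data, lower_q))
}

#' Simulation scenario specification
#'
#' One cell of the factorial experiment: population and design factors plus
#' Monte-Carlo and workflow settings.
#'
#' @param n_total sample size (study designs use 300, 800, 1200).
#' @param rho exchangeable exposure correlation (0 or 0.8).
#' @param icc intraclass correlation (0 or 0.15).
#' @param regime "srs" or "pps".
#' @param M exposures (3 or 10).
#' @param R Monte-Carlo replicates, default 100.
#' @param B bootstrap replicates for the design-aware workflow, default 50.
#' @param seed master seed; replicate RNG streams are spawned from it.
#' @param fitter "bkmr" (the kernel machine sampler) or "quadratic" (the
#'   analytic reference model, used for fast harness checks).
#' @param workflows which workflows to run.
#' @param naive_config,replicate_config chain settings for the naive fit and
#'   the per-replicate short chains.
#' @param N_pop,C,H,k_h population and first-stage design sizes.
#' @param quantile_source passed to [estimand_spec()]; "theoretical-normal"
#'   fixes the truth per scenario, "population-empirical" recomputes it from
#'   each replicate's population.
#' @return an object of class \code{scenario_spec}.
#' @export
scenario_spec <- function(n_total = 300L, rho = 0, icc = 0,
                          regime = c("srs", "pps"), M = 3L,
                          R = 100L, B = 50L, seed = 1L,
                          fitter = c("bkmr", "quadratic"),
                          workflows = c("naive", "design_aware"),
                          naive_config = bkmr_config(),
                          replicate_config = bkmr_config_replicate(),
                          N_pop = 20000L, C = 120L, H = 6L, k_h = 4L,
                          quantile_source = "theoretical-normal") {
  regime <- match.arg(regime)
  fitter <- match.arg(fitter)
  workflows <- match.arg(workflows, several.ok = TRUE)
  structure(list(n_total = as.integer(n_total), rho = rho, icc = icc,
                 regime = regime, M = as.integer(M), R = as.integer(R),
                 B = as.integer(B), seed = as.integer(seed), fitter = fitter,
                 workflows = workflows, naive_config = naive_config,
                 replicate_config = replicate_config,
                 N_pop = as.integer(N_pop), C = as.integer(C),
                 H = as.integer(H), k_h = as.integer(k_h),
                 quantile_source = quantile_source),
            class = "scenario_spec")
}

scenario_id <- function(spec) {
  sprintf("M%d_n%d_rho%g_icc%g_%s", spec$M, spec$n_total, spec$rho,
          spec$icc, spec$regime)
}

stream_seed <- function() sample.int(.Machine$integer.max - 1L, 1L)

#' Run one simulation scenario
#'
#' For each of R Monte-Carlo replicates: generate a fresh finite population,
#' draw a fresh survey sample, and apply the requested workflows to that
#' identical sample — the naive fit (posterior-credible interval) and/or the
#' design-aware B-replicate workflow (replication-based interval). Each
#' replicate owns an independent L'Ecuyer-CMRG stream spawned from the
#' master seed, so results are reproducible and independent of execution
#' order.
#'
#' @param spec a [scenario_spec()].
#' @return an object of class \code{scenario_result}: \code{estimates} (one
#'   row per replicate x workflow: estimate, lo, hi, interval_kind),
#'   \code{delta_star}, and the scenario settings. Replicate failures are
#'   recorded; the
#'   scenario aborts below 80% success.
#' @export
run_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  hs <- h_spec(if (spec$M == 10L) "h10" else "h3")
  est <- estimand_spec(quantile_source = spec$quantile_source)
  delta_star <- if (spec$quantile_source == "theoretical-normal") {
    true_overall_effect(hs, est)$delta_star
  } else NA_real_

  streams <- replicate_streams(spec$seed, spec$R)
  rows <- vector("list", spec$R)
  zcols <- paste0("z", seq_len(spec$M))
  # the estimand's quantile points are known in simulation; the contrast is
  # evaluated at those same fixed points
  qpts <- rbind(rep(stats::qnorm(est$upper_q), spec$M),
                rep(stats::qnorm(est$lower_q), spec$M))

  for (r in seq_len(spec$R)) {
    rows[[r]] <- with_stream(streams[[r]], {
      cfg <- population_config(N_pop = spec$N_pop, M = spec$M,
                               rho = spec$rho, icc = spec$icc,
                               C = spec$C, H = spec$H, seed = stream_seed())
      pop <- generate_population(cfg, hs)
      ds_r <- delta_star
      if (spec$quantile_source == "population-empirical") {
        ds_r <- true_overall_effect(hs, est, pop)$delta_star
        qpts <- rbind(exposure_quantiles(pop$data, est$upper_q)[1L, ],
                      exposure_quantiles(pop$data, est$lower_q)[1L, ])
      }
      design <- sampling_design(n_total = spec$n_total, regime = spec$regime,
                                k_h = spec$k_h, seed = stream_seed())
      samp <- try(draw_sample(pop, design), silent = TRUE)
      if (inherits(samp, "try-error")) {
        return(data.frame(replicate = r, workflow = spec$workflows,
                          estimate = NA_real_, lo = NA_real_, hi = NA_real_,
                          interval_kind = NA_character_,
                          delta_star = ds_r))
      }
      out <- list()
      if ("naive" %in% spec$workflows) {
        agg <- try(naive_delta(samp, spec, zcols, qpts), silent = TRUE)
        out$naive <- wf_row(r, "naive", agg, ds_r)
      }
      if ("design_aware" %in% spec$workflows) {
        agg <- try(design_aware_delta(samp, spec, zcols, qpts),
                   silent = TRUE)
        out$design_aware <- wf_row(r, "design_aware", agg, ds_r)
      }
      do.call(rbind, out)
    })
  }

  estimates <- do.call(rbind, rows)
  rownames(estimates) <- NULL
  ok_rate <- mean(is.finite(estimates$estimate))
  if (ok_rate < 0.8) {
    stop(sprintf("only %.0f%% of scenario replicates succeeded; aborting",
                 100 * ok_rate))
  }
  structure(list(estimates = estimates, delta_star = delta_star,
                 spec = spec, id = scenario_id(spec)),
            class = "scenario_result")
}

naive_delta <- function(samp, spec, zcols, qpts) {
  Z <- as.matrix(as.data.frame(samp)[, zcols])
  if (spec$fitter == "quadratic") {
    return(quad_contrast(quadratic_fit(samp$y, Z), qpts[1L, ], qpts[2L, ]))
  }
  cfg <- spec$naive_config
  cfg$seed <- stream_seed()
  # standard practice: the contrast is evaluated at the analysis sample's
  # own quantile points (this is one channel of the naive workflow's bias
  # under informative sampling)
  qp <- rbind(joint_quantile_point(samp, 0.75),
              joint_quantile_point(samp, 0.25))
  fit <- mcmc_fit(samp$y, Z, config = cfg, h_points = qp,
                  h_draw_noise = TRUE)
  d <- fit$draws$h[, 1L] - fit$draws$h[, 2L]
  qs <- stats::quantile(d, c(0.025, 0.975), names = FALSE)
  structure(list(point = mean(d), lo = qs[1L], hi = qs[2L],
                 interval_kind = "posterior-credible", level = 0.95,
                 B = length(d)),
            class = "aggregated_estimate")
}

design_aware_delta <- function(samp, spec, zcols, qpts) {
  if (spec$fitter == "quadratic") {
    plan <- resample_plan(B = spec$B, seed = stream_seed())
    vals <- vapply(seq_len(spec$B), function(b) {
      res <- resample_design_aware(samp, plan)
      Z <- as.matrix(res[, zcols])
      quad_contrast(quadratic_fit(res$y, Z), qpts[1L, ], qpts[2L, ])$point
    }, numeric(1))
    return(aggregate_scalar(vals))
  }
  plan <- resample_plan(B = spec$B, replicate_config = spec$replicate_config,
                        seed = stream_seed())
  # per-replicate quantiles from the resampled (weight-proportional) data,
  # which approximate the population quantiles
  daf <- run_design_aware(samp, plan, summaries = list(summarize_delta()))
  estimate_delta(daf)
}

wf_row <- function(r, workflow, agg, ds) {
  if (inherits(agg, "try-error") || is.null(agg)) {
    return(data.frame(replicate = r, workflow = workflow,
                      estimate = NA_real_, lo = NA_real_, hi = NA_real_,
                      interval_kind = NA_character_, delta_star = ds))
  }
  data.frame(replicate = r, workflow = workflow, estimate = agg$point,
             lo = agg$lo, hi = agg$hi, interval_kind = agg$interval_kind,
             delta_star = ds)
}

#' Operating characteristics of an estimator over Monte-Carlo replicates
#'
#' bias = mean(estimate) - delta_star; width = mean(hi - lo); coverage =
#' proportion of replicates whose closed interval [lo, hi] contains
#' delta_star; rmse = sqrt(mean((estimate - delta_star)^2)). Failed
#' replicates (NA estimates) are dropped and counted in R_effective.
#'
#' @param estimates data frame with columns estimate, lo, hi (one row per
#'   replicate), e.g. one workflow's rows of a [run_scenario()] result.
#' @param delta_star the true overall effect.
#' @return one-row data frame: bias, width, coverage, rmse, R_effective.
#' @export
compute_metrics <- function(estimates, delta_star) {
  if (nrow(estimates) == 0) stop("no replicate estimates")
  ok <- is.finite(estimates$estimate)
  e <- estimates[ok, , drop = FALSE]
  data.frame(
    bias = mean(e$estimate) - delta_star,
    width = mean(e$hi - e$lo),
    coverage = mean(e$lo <= delta_star & delta_star <= e$hi),
    rmse = sqrt(mean((e$estimate - delta_star)^2)),
    R_effective = sum(ok))
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Scenario %s (fitter = %s, R = %d)\n", x$id, x$spec$fitter,
              x$spec$R))
  print(scenario_metrics(x))
  invisible(x)
}

#' Metrics table for a scenario result
#' @param result a [run_scenario()] result.
#' @return data frame with one row per workflow.
#' @export
scenario_metrics <- function(result) {
  stopifnot(inherits(result, "scenario_result"))
  do.call(rbind, lapply(unique(result$estimates$workflow), function(wf) {
    e <- result$estimates[result$estimates$workflow == wf, , drop = FALSE]
    ds <- if (is.finite(result$delta_star)) result$delta_star else
      e$delta_star[1L]
    cbind(data.frame(scenario = result$id, workflow = wf),
          compute_metrics(e, ds))
  }))
}

#' Full factorial experiment
#'
#' Crosses the factor levels, runs each scenario, and stacks the metric
#' rows. Deterministic given the master seed (scenario seeds are offsets of
#' it).
#'
#' @param base a [scenario_spec()] supplying everything not crossed.
#' @param n_total,rho,icc,regime factor levels.
#' @return long-format data frame: factors, workflow, bias, width,
#'   coverage, rmse, R_effective.
#' @export
full_factorial <- function(base = scenario_spec(),
                           n_total = c(300L, 800L, 1200L),
                           rho = c(0, 0.8), icc = c(0, 0.15),
                           regime = c("srs", "pps")) {
  grid <- expand.grid(n_total = n_total, rho = rho, icc = icc,
                      regime = regime, stringsAsFactors = FALSE)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    spec <- base
    spec$n_total <- as.integer(grid$n_total[i])
    spec$rho <- grid$rho[i]
    spec$icc <- grid$icc[i]
    spec$regime <- grid$regime[i]
    spec$seed <- base$seed + i - 1L
    res <- run_scenario(spec)
    m <- scenario_metrics(res)
    out[[i]] <- cbind(grid[i, , drop = FALSE], m[, -1L], row.names = NULL)
  }
  do.call(rbind, out)
}
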