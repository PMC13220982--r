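#' Per-exposure empirical quantiles of an analysis dataset
#'
#' Linear-interpolation (type 7) quantiles of each exposure column, the
#' quantile definition used by every summary in the package.
#'
#' @param data a data frame or matrix containing exposure columns z1..zM (a
#'   plain matrix is taken as the exposure matrix itself).
#' @param probs probabilities in (0, 1).
#' @return a length(probs) x M matrix of quantiles, rows named by prob.
#' @export
exposure_quantiles <- function(data, probs) {
  Z <- extract_Z(data)
  stopifnot(all(probs > 0), all(probs < 1))
  q <- apply(Z, 2L, stats::quantile, probs = probs, names = FALSE, type = 7)
  q <- matrix(q, nrow = length(probs))
  dimnames(q) <- list(format(probs), colnames(Z))
  q
}

extract_Z <- function(data) {
  if (is.matrix(data)) return(data)
  zcols <- grep("^z[0-9]+$", names(data), value = TRUE)
  if (length(zcols) == 0) stop("no exposure columns z1..zM found")
  as.matrix(data[, zcols[order(as.integer(sub("z", "", zcols)))]])
}

# Joint quantile point: each exposure at its own marginal p-th quantile.
joint_quantile_point <- function(data, p, M = NULL) {
  if (is.null(data)) {
    stopifnot(!is.null(M))
    return(rep(stats::qnorm(p), M))
  }
  as.numeric(exposure_quantiles(data, p))
}

# Summarize a T x G draw matrix into pointwise mean + equal-tailed interval.
draws_band <- function(H, interval_kind, level = 0.95) {
  a <- (1 - level) / 2
  data.frame(point = colMeans(H),
             lo = apply(H, 2L, stats::quantile, probs = a, names = FALSE),
             hi = apply(H, 2L, stats::quantile, probs = 1 - a,
                        names = FALSE)) |>
    structure(interval_kind = interval_kind)
}

fit_data <- function(object, data) {
  if (!is.null(data)) return(data)
  object$Z
}

# ---- overall mixture effect -------------------------------------------------

#' Overall mixture effect Delta
#'
#' The contrast in the modeled outcome when all exposures move jointly from
#' their \code{lower_q}-th to \code{upper_q}-th marginal quantiles (defaults
#' 0.25 and 0.75). For a single fit the posterior draws of
#' h(q_upper) - h(q_lower) are summarized by their mean and equal-tailed 95%
#' posterior credible interval; for a design-aware run the per-replicate
#' posterior means (computed by [summarize_delta()] during the run) are
#' aggregated into a replication-based interval; for a surface specification
#' (oracle mode) the exact value is returned with a zero-width interval.
#'
#' @param object a [mcmc_fit()] result, a [run_design_aware()] result, or an
#'   [h_spec()].
#' @param data analysis dataset supplying the quantiles; defaults to the
#'   fit's own data, or theoretical N(0,1) quantiles for an oracle surface.
#' @param lower_q,upper_q quantile pair.
#' @param ... passed to methods.
#' @return an \code{aggregated_estimate}.
#' @export
estimate_delta <- function(object, ...) UseMethod("estimate_delta")

#' @rdname estimate_delta
#' @param ndraws optional thinning of retained draws for the surface query.
#' @export
estimate_delta.bkmr_fit <- function(object, data = NULL, lower_q = 0.25,
                                    upper_q = 0.75, ndraws = NULL, ...) {
  data <- fit_data(object, data)
  pts <- rbind(joint_quantile_point(data, upper_q),
               joint_quantile_point(data, lower_q))
  H <- posterior_h(object, pts, draw_noise = TRUE, ndraws = ndraws)
  d <- H[, 1L] - H[, 2L]
  qs <- stats::quantile(d, c(0.025, 0.975), names = FALSE)
  structure(list(point = mean(d), lo = qs[1L], hi = qs[2L],
                 interval_kind = "posterior-credible", level = 0.95,
                 B = length(d)),
            class = "aggregated_estimate")
}

#' @rdname estimate_delta
#' @export
estimate_delta.design_aware_fit <- function(object, ...) {
  v <- replicate_summary(object, "delta")
  aggregate_scalar(v[, 1L], interval_kind = "replication-based")
}

#' @rdname estimate_delta
#' @export
estimate_delta.h_spec <- function(object, data = NULL, lower_q = 0.25,
                                  upper_q = 0.75, ...) {
  hi <- joint_quantile_point(data, upper_q, object$M)
  lo <- joint_quantile_point(data, lower_q, object$M)
  val <- h_true(hi, object) - h_true(lo, object)
  structure(list(point = val, lo = val, hi = val,
                 interval_kind = "oracle", level = 0.95, B = 1L),
            class = "aggregated_estimate")
}

# ---- overall effect curve ---------------------------------------------------

#' Overall mixture effect across joint exposure quantiles
#'
#' The change in the outcome when all exposures are jointly set to quantile
#' q, relative to the median level (q = 0.50, at which the curve is
#' constrained to zero in every draw or replicate).
#'
#' @inheritParams estimate_delta
#' @param quantiles quantile grid in (0, 1); must include 0.50.
#' @return data frame with columns q, point, lo, hi and attribute
#'   \code{interval_kind}.
#' @export
overall_effect_curve <- function(object, ...) UseMethod("overall_effect_curve")

check_overall_grid <- function(quantiles) {
  if (any(quantiles <= 0) || any(quantiles >= 1)) {
    stop("quantile grid must lie inside (0, 1)")
  }
  if (!any(abs(quantiles - 0.5) < 1e-12)) {
    stop("quantile grid must include the reference 0.50")
  }
}

overall_points <- function(data, quantiles, M) {
  t(vapply(quantiles, function(p) joint_quantile_point(data, p, M),
           numeric(M)))
}

#' @rdname overall_effect_curve
#' @param ndraws optional thinning of retained draws.
#' @export
overall_effect_curve.bkmr_fit <- function(object, data = NULL,
                                          quantiles = seq(0.25, 0.75, 0.05),
                                          ndraws = NULL, ...) {
  check_overall_grid(quantiles)
  data <- fit_data(object, data)
  pts <- overall_points(data, quantiles, ncol(object$Z))
  H <- posterior_h(object, pts, draw_noise = TRUE, ndraws = ndraws)
  ref <- which(abs(quantiles - 0.5) < 1e-12)[1L]
  H <- H - H[, ref]
  out <- draws_band(H, "posterior-credible")
  cbind(q = quantiles, out) |>
    structure(interval_kind = "posterior-credible")
}

#' @rdname overall_effect_curve
#' @export
overall_effect_curve.design_aware_fit <- function(object, ...) {
  mat <- replicate_summary(object, "overall")
  quantiles <- attr(mat, "meta")$quantiles
  out <- aggregate_functional(mat, "replication-based")
  cbind(q = quantiles, out) |>
    structure(interval_kind = "replication-based")
}

#' @rdname overall_effect_curve
#' @export
overall_effect_curve.h_spec <- function(object, data = NULL,
                                        quantiles = seq(0.25, 0.75, 0.05),
                                        ...) {
  check_overall_grid(quantiles)
  pts <- overall_points(data, quantiles, object$M)
  ref_pt <- joint_quantile_point(data, 0.5, object$M)
  v <- h_true(pts, object) - h_true(ref_pt, object)
  data.frame(q = quantiles, point = v, lo = v, hi = v) |>
    structure(interval_kind = "oracle")
}

# ---- univariate and bivariate response --------------------------------------

uni_points <- function(data, j, grid, M, cond_p = 0.5) {
  med <- joint_quantile_point(data, cond_p, M)
  pts <- matrix(rep(med, each = length(grid)), nrow = length(grid))
  pts[, j] <- grid
  pts
}

default_grid <- function(data, j, ngrid) {
  Z <- extract_Z(data)
  seq(min(Z[, j]), max(Z[, j]), length.out = ngrid)
}

#' Univariate exposure-response function
#'
#' h as a function of exposure j with all other exposures held at their
#' median values, reported relative to the all-median reference point (the
#' curve is zero at the median of z_j by construction). Centering removes
#' the additive indeterminacy between the surface and the intercept and
#' makes naive, design-aware and oracle curves directly comparable.
#'
#' @inheritParams estimate_delta
#' @param j exposure index.
#' @param grid evaluation grid for z_j; default 25 points spanning its
#'   observed range in \code{data}.
#' @param ngrid grid size when \code{grid} is NULL.
#' @return data frame with columns z, point, lo, hi and attribute
#'   \code{interval_kind}.
#' @export
univariate_response <- function(object, ...) UseMethod("univariate_response")

#' @rdname univariate_response
#' @param ndraws optional thinning of retained draws.
#' @export
univariate_response.bkmr_fit <- function(object, j, data = NULL, grid = NULL,
                                         ngrid = 25L, ndraws = NULL, ...) {
  data <- fit_data(object, data)
  M <- ncol(object$Z)
  if (j < 1 || j > M) stop("exposure index out of range")
  if (is.null(grid)) grid <- default_grid(data, j, ngrid)
  ref <- joint_quantile_point(data, 0.5, M)
  pts <- rbind(uni_points(data, j, grid, M), ref)
  H <- posterior_h(object, pts, draw_noise = TRUE, ndraws = ndraws)
  H <- (H - H[, ncol(H)])[, -ncol(H), drop = FALSE]
  cbind(z = grid, draws_band(H, "posterior-credible")) |>
    structure(interval_kind = "posterior-credible")
}

#' @rdname univariate_response
#' @export
univariate_response.design_aware_fit <- function(object, j, ...) {
  mat <- replicate_summary(object, paste0("uni", j))
  grid <- attr(mat, "meta")$grid
  out <- aggregate_functional(mat, "replication-based")
  cbind(z = grid, out) |> structure(interval_kind = "replication-based")
}

#' @rdname univariate_response
#' @export
univariate_response.h_spec <- function(object, j, data = NULL, grid = NULL,
                                       ngrid = 25L, ...) {
  if (j < 1 || j > object$M) stop("exposure index out of range")
  if (is.null(grid)) {
    grid <- if (is.null(data)) seq(-2, 2, length.out = ngrid) else
      default_grid(data, j, ngrid)
  }
  ref <- joint_quantile_point(data, 0.5, object$M)
  pts <- uni_points(data, j, grid, object$M)
  v <- h_true(pts, object) - h_true(ref, object)
  data.frame(z = grid, point = v, lo = v, hi = v) |>
    structure(interval_kind = "oracle")
}

#' Bivariate exposure-response function
#'
#' h as a function of exposure j, one curve per conditioning quantile of
#' exposure k, all remaining exposures at their medians; the whole family is
#' reported relative to the all-median reference point, so curve-to-curve
#' separation (the interaction diagnostic) is preserved while the additive
#' surface-versus-intercept indeterminacy is removed.
#'
#' @inheritParams univariate_response
#' @param k conditioning exposure index (k != j).
#' @param cond_quantiles conditioning quantiles for z_k.
#' @return data frame with columns z, cond_quantile, point, lo, hi.
#' @export
bivariate_response <- function(object, ...) UseMethod("bivariate_response")

biv_points <- function(data, j, k, grid, cond_quantiles, M) {
  do.call(rbind, lapply(cond_quantiles, function(cq) {
    pts <- uni_points(data, j, grid, M)
    zk <- if (is.null(data)) stats::qnorm(cq) else
      exposure_quantiles(data, cq)[1L, k]
    pts[, k] <- zk
    pts
  }))
}

#' @rdname bivariate_response
#' @export
bivariate_response.bkmr_fit <- function(object, j, k, data = NULL,
                                        grid = NULL, ngrid = 25L,
                                        cond_quantiles = c(0.25, 0.5, 0.75),
                                        ndraws = NULL, ...) {
  if (j == k) stop("focal and conditioning exposures must differ")
  data <- fit_data(object, data)
  M <- ncol(object$Z)
  if (is.null(grid)) grid <- default_grid(data, j, ngrid)
  ref <- joint_quantile_point(data, 0.5, M)
  pts <- rbind(biv_points(data, j, k, grid, cond_quantiles, M), ref)
  H <- posterior_h(object, pts, draw_noise = TRUE, ndraws = ndraws)
  H <- (H - H[, ncol(H)])[, -ncol(H), drop = FALSE]
  out <- draws_band(H, "posterior-credible")
  cbind(z = rep(grid, length(cond_quantiles)),
        cond_quantile = rep(cond_quantiles, each = length(grid)), out) |>
    structure(interval_kind = "posterior-credible")
}

#' @rdname bivariate_response
#' @export
bivariate_response.design_aware_fit <- function(object, j, k, ...) {
  mat <- replicate_summary(object, paste0("biv", j, "_", k))
  meta <- attr(mat, "meta")
  out <- aggregate_functional(mat, "replication-based")
  cbind(z = rep(meta$grid, length(meta$cond_quantiles)),
        cond_quantile = rep(meta$cond_quantiles, each = length(meta$grid)),
        out) |>
    structure(interval_kind = "replication-based")
}

#' @rdname bivariate_response
#' @export
bivariate_response.h_spec <- function(object, j, k, data = NULL, grid = NULL,
                                      ngrid = 25L,
                                      cond_quantiles = c(0.25, 0.5, 0.75),
                                      ...) {
  if (j == k) stop("focal and conditioning exposures must differ")
  if (is.null(grid)) {
    grid <- if (is.null(data)) seq(-2, 2, length.out = ngrid) else
      default_grid(data, j, ngrid)
  }
  ref <- joint_quantile_point(data, 0.5, object$M)
  pts <- biv_points(data, j, k, grid, cond_quantiles, object$M)
  v <- h_true(pts, object) - h_true(ref, object)
  data.frame(z = rep(grid, length(cond_quantiles)),
             cond_quantile = rep(cond_quantiles, each = length(grid)),
             point = v, lo = v, hi = v) |>
    structure(interval_kind = "oracle")
}

#' Single-variable risk contrasts
#'
#' For each exposure, the change in the outcome when that exposure moves
#' from its 25th to its 75th percentile while every other mixture component
#' is held at the \code{q_fixed} quantile.
#'
#' @inheritParams estimate_delta
#' @param q_fixed quantile at which all non-focal exposures are fixed
#'   (0.25, 0.50 or 0.75 in the study designs; any value in (0,1) accepted).
#' @return data frame with columns exposure, point, lo, hi.
#' @export
single_variable_risks <- function(object, ...) UseMethod("single_variable_risks")

risk_points <- function(data, M, q_fixed, lower_q, upper_q) {
  base <- joint_quantile_point(data, q_fixed, M)
  lo_q <- joint_quantile_point(data, lower_q, M)
  hi_q <- joint_quantile_point(data, upper_q, M)
  pts <- matrix(rep(base, each = 2L * M), nrow = 2L * M)
  for (j in seq_len(M)) {
    pts[2L * j - 1L, j] <- hi_q[j]
    pts[2L * j, j] <- lo_q[j]
  }
  pts
}

#' @rdname single_variable_risks
#' @export
single_variable_risks.bkmr_fit <- function(object, data = NULL,
                                           q_fixed = 0.5, lower_q = 0.25,
                                           upper_q = 0.75, ndraws = NULL,
                                           ...) {
  stopifnot(q_fixed > 0, q_fixed < 1)
  data <- fit_data(object, data)
  M <- ncol(object$Z)
  pts <- risk_points(data, M, q_fixed, lower_q, upper_q)
  H <- posterior_h(object, pts, draw_noise = TRUE, ndraws = ndraws)
  D <- H[, seq(1L, 2L * M, 2L), drop = FALSE] -
    H[, seq(2L, 2L * M, 2L), drop = FALSE]
  cbind(exposure = seq_len(M), draws_band(D, "posterior-credible")) |>
    structure(interval_kind = "posterior-credible")
}

#' @rdname single_variable_risks
#' @export
single_variable_risks.design_aware_fit <- function(object, q_fixed = 0.5,
                                                   ...) {
  mat <- replicate_summary(object, paste0("risks_q", format(q_fixed)))
  out <- aggregate_functional(mat, "replication-based")
  cbind(exposure = seq_len(nrow(out)), out) |>
    structure(interval_kind = "replication-based")
}

#' @rdname single_variable_risks
#' @export
single_variable_risks.h_spec <- function(object, data = NULL, q_fixed = 0.5,
                                         lower_q = 0.25, upper_q = 0.75,
                                         ...) {
  stopifnot(q_fixed > 0, q_fixed < 1)
  M <- object$M
  pts <- risk_points(data, M, q_fixed, lower_q, upper_q)
  v <- h_true(pts, object)
  d <- v[seq(1L, 2L * M, 2L)] - v[seq(2L, 2L * M, 2L)]
  data.frame(exposure = seq_len(M), point = d, lo = d, hi = d) |>
    structure(interval_kind = "oracle")
}

# ---- per-replicate summarizers for the design-aware workflow ---------------

new_summarizer <- function(name, points_fn, reduce, meta = list()) {
  structure(list(points_fn = points_fn, reduce = reduce),
            name = name, meta = meta, class = "replicate_summarizer")
}

replicate_summary <- function(object, name) {
  mat <- object$extra[[name]]
  if (is.null(mat)) {
    stop(sprintf(
      "design-aware run has no '%s' replicate summary; rerun run_design_aware() with the matching summarizer",
      name))
  }
  mat
}

#' Replicate summarizers for [run_design_aware()]
#'
#' Each constructor returns a summarizer: a recipe that names the surface
#' points a replicate fit must evaluate (quantiles taken from the resampled
#' dataset itself, which already embodies the weighting; fixed grids shared
#' across replicates so curves aggregate pointwise) and reduces that
#' replicate's h draws at those points to its posterior-mean summary. The h
#' draws are accumulated during the replicate's own MCMC run, reusing each
#' iteration's factorization.
#'
#' @param lower_q,upper_q,quantiles,grid,j,q_fixed as in the corresponding
#'   summary functions.
#' @return a \code{replicate_summarizer} to pass in the \code{summaries}
#'   list of [run_design_aware()].
#' @name replicate-summarizers
NULL

#' @rdname replicate-summarizers
#' @param points optional fixed 2 x M matrix (upper point, lower point) at
#'   which the contrast is evaluated; when given, per-replicate quantile
#'   estimation is bypassed — used by the simulation harness, where the
#'   estimand's quantile points are known.
#' @export
summarize_delta <- function(lower_q = 0.25, upper_q = 0.75, points = NULL) {
  new_summarizer(
    "delta",
    points_fn = function(data, M) {
      if (is.null(points)) {
        rbind(joint_quantile_point(data, upper_q),
              joint_quantile_point(data, lower_q))
      } else points
    },
    reduce = function(H, data) c(delta = mean(H[, 1L] - H[, 2L])),
    meta = list(lower_q = lower_q, upper_q = upper_q))
}

#' @rdname replicate-summarizers
#' @export
summarize_overall_curve <- function(quantiles = seq(0.25, 0.75, 0.05)) {
  check_overall_grid(quantiles)
  ref <- which(abs(quantiles - 0.5) < 1e-12)[1L]
  new_summarizer(
    "overall",
    points_fn = function(data, M) overall_points(data, quantiles, M),
    reduce = function(H, data) {
      stats::setNames(colMeans(H - H[, ref]),
                      paste0("q", format(quantiles)))
    },
    meta = list(quantiles = quantiles))
}

#' @rdname replicate-summarizers
#' @export
summarize_univariate <- function(j, grid) {
  new_summarizer(
    paste0("uni", j),
    points_fn = function(data, M) {
      rbind(uni_points(data, j, grid, M),
            joint_quantile_point(data, 0.5, M))
    },
    reduce = function(H, data) {
      colMeans((H - H[, ncol(H)])[, -ncol(H), drop = FALSE])
    },
    meta = list(j = j, grid = grid))
}

#' @rdname replicate-summarizers
#' @param k conditioning exposure index.
#' @param cond_quantiles conditioning quantiles for z_k.
#' @export
summarize_bivariate <- function(j, k, grid,
                                cond_quantiles = c(0.25, 0.5, 0.75)) {
  if (j == k) stop("focal and conditioning exposures must differ")
  new_summarizer(
    paste0("biv", j, "_", k),
    points_fn = function(data, M) {
      rbind(biv_points(data, j, k, grid, cond_quantiles, M),
            joint_quantile_point(data, 0.5, M))
    },
    reduce = function(H, data) {
      colMeans((H - H[, ncol(H)])[, -ncol(H), drop = FALSE])
    },
    meta = list(j = j, k = k, grid = grid,
                cond_quantiles = cond_quantiles))
}

#' @rdname replicate-summarizers
#' @export
summarize_risks <- function(q_fixed = 0.5, lower_q = 0.25, upper_q = 0.75) {
  new_summarizer(
    paste0("risks_q", format(q_fixed)),
    points_fn = function(data, M) {
      risk_points(data, M, q_fixed, lower_q, upper_q)
    },
    reduce = function(H, data) {
      M <- ncol(H) / 2L
      colMeans(H[, seq(1L, 2L * M, 2L), drop = FALSE] -
                 H[, seq(2L, 2L * M, 2L), drop = FALSE])
    },
    meta = list(q_fixed = q_fixed, lower_q = lower_q, upper_q = upper_q))
}

#' Tidy export of a summary table
#'
#' @param x a summary data frame from this module.
#' @param path CSV path.
#' @param workflow label ("naive", "design_aware", "oracle").
#' @export
write_summary <- function(x, path, workflow = "naive") {
  x$interval_kind <- attr(x, "interval_kind")
  x$workflow <- workflow
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Basic curve plot
#'
#' Unstyled base-graphics plot of a curve summary (point line plus interval
#' band) produced by [overall_effect_curve()], [univariate_response()] or
#' [bivariate_response()].
#'
#' @param x a curve summary data frame.
#' @param xlab,ylab axis labels.
#' @param ... passed to [plot()].
#' @export
plot_curve <- function(x, xlab = NULL, ylab = "h", ...) {
  xv <- if ("q" %in% names(x)) x$q else x$z
  if (is.null(xlab)) xlab <- if ("q" %in% names(x)) "quantile" else "z"
  plot(xv, x$point, type = "n", ylim = range(x$lo, x$hi),
       xlab = xlab, ylab = ylab, ...)
  groups <- if ("cond_quantile" %in% names(x)) x$cond_quantile else
    rep(1, nrow(x))
  for (g in unique(groups)) {
    i <- groups == g
    graphics::polygon(c(xv[i], rev(xv[i])), c(x$lo[i], rev(x$hi[i])),
                      col = grDevices::grey(0.9), border = NA)
  }
  for (g in unique(groups)) {
    i <- groups == g
    graphics::lines(xv[i], x$point[i])
  }
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
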