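#' Resampling plan for the design-aware workflow
#'
#' @param B number of bootstrap replicates, default 50.
#' @param psu_prob_rule PSU redraw probabilities proportional to the
#'   "sum_weights" (default) or "mean_weights" of each sampled PSU. The two
#'   rules coincide when within-PSU takes are equal; both are offered because
#'   either convention appears in practice.
#' @param replicate_config a [bkmr_config()] for the per-replicate short
#'   chains; default [bkmr_config_replicate()].
#' @param cores workers for replicate fitting; results are identical to
#'   serial execution for any worker count because each replicate owns a
#'   fixed RNG stream.
#' @param seed master seed; per-replicate L'Ecuyer-CMRG streams are spawned
#'   from it.
#' @return an object of class \code{resample_plan}.
#' @export
resample_plan <- function(B = 50L,
                          psu_prob_rule = c("sum_weights", "mean_weights"),
                          replicate_config = bkmr_config_replicate(),
                          cores = 1L, seed = 1L) {
  psu_prob_rule <- match.arg(psu_prob_rule)
  stopifnot(B >= 1, inherits(replicate_config, "bkmr_config"))
  structure(list(B = as.integer(B), psu_prob_rule = psu_prob_rule,
                 replicate_config = replicate_config,
                 cores = as.integer(cores), seed = as.integer(seed)),
            class = "resample_plan")
}

#' One design-aware resample of a survey sample
#'
#' Stratum by stratum, the sample's PSUs are redrawn with replacement (as
#' many draws as the stratum originally had PSUs) with probabilities
#' proportional to the chosen weight rule; within each drawn PSU, units are
#' redrawn with replacement with probabilities proportional to their
#' weights. The stratum's original multiset of within-PSU takes is kept as
#' the takes of the redrawn slots (identical to using each source PSU's own
#' take when takes are equal), so the per-stratum and total sizes are
#' preserved exactly in every resample. A PSU drawn twice contributes two
#' independent unit resamples under replicate-unique labels, preserving
#' between-PSU variability.
#'
#' @param sample a [draw_sample()] result (needs stratum, psu, w columns).
#' @param plan a [resample_plan()]; only \code{psu_prob_rule} is used here.
#' @return a data frame of resampled rows with columns \code{psu_label}
#'   (replicate-unique) and \code{source_psu} added.
#' @export
resample_design_aware <- function(sample, plan = resample_plan()) {
  stopifnot(all(c("stratum", "psu", "w") %in% names(sample)))
  if (anyNA(sample$w)) stop("missing weights")
  ws <- psu_weight_summary(sample)
  rows_of_psu <- split(seq_len(nrow(sample)), sample$psu)

  out_idx <- integer(0)
  labels <- integer(0)
  lab <- 0L
  for (s in sort(unique(ws$stratum))) {
    in_s <- ws[ws$stratum == s, ]
    if (nrow(in_s) == 0) stop("empty stratum")
    prob <- if (plan$psu_prob_rule == "sum_weights") in_s$sum_w else in_s$mean_w
    slot_takes <- vapply(as.character(in_s$psu),
                         function(p) length(rows_of_psu[[p]]), integer(1))
    draws <- sample.int(nrow(in_s), nrow(in_s), replace = TRUE,
                        prob = prob / sum(prob))
    for (i in seq_along(draws)) {
      lab <- lab + 1L
      psu_rows <- rows_of_psu[[as.character(in_s$psu[draws[i]])]]
      take <- slot_takes[i]
      w_psu <- sample$w[psu_rows]
      picked <- psu_rows[sample.int(length(psu_rows), take, replace = TRUE,
                                    prob = w_psu / sum(w_psu))]
      out_idx <- c(out_idx, picked)
      labels <- c(labels, rep.int(lab, take))
    }
  }
  out <- as.data.frame(sample)[out_idx, , drop = FALSE]
  out$source_psu <- out$psu
  out$psu_label <- labels
  rownames(out) <- NULL
  out
}

# Per-replicate RNG streams: L'Ecuyer-CMRG substreams spawned from the master
# seed, so replicate b's draws do not depend on worker count or run order.
replicate_streams <- function(master_seed, B) {
  old_kind <- RNGkind()
  on.exit(do.call(RNGkind, as.list(old_kind[1:3])), add = TRUE)
  RNGkind("L'Ecuyer-CMRG")
  set.seed(master_seed)
  streams <- vector("list", B)
  s <- .Random.seed
  for (b in seq_len(B)) {
    streams[[b]] <- s
    s <- parallel::nextRNGStream(s)
  }
  streams
}

with_stream <- function(stream, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  assign(".Random.seed", stream, envir = globalenv())
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  force(expr)
}

#' Run the design-aware workflow
#'
#' Draws B weight-proportional, PSU-preserving resamples of the survey
#' sample, refits the kernel machine model on each with short chains, and
#' collects per-replicate summaries (posterior means within each replicate).
#' Failed replicate fits are skipped with a warning; the run aborts if fewer
#' than 80% succeed.
#'
#' @param sample a [draw_sample()] result.
#' @param plan a [resample_plan()].
#' @param h_points optional matrix of surface query points accumulated during
#'   each replicate fit (original exposure scale).
#' @param summaries optional list of replicate summarizers (see
#'   [summarize_delta()] and friends), each computing a named numeric vector
#'   per replicate; results are stacked into B x length matrices consumed by
#'   the design-aware summary methods.
#' @return an object of class \code{design_aware_fit}: per-replicate PIP
#'   matrix, h posterior-mean matrix (B x nrow(h_points)), replicate
#'   summaries, and the plan.
#' @export
run_design_aware <- function(sample, plan = resample_plan(),
                             h_points = NULL, summaries = NULL) {
  if (!is.null(summaries)) {
    if (inherits(summaries, "replicate_summarizer")) {
      summaries <- list(summaries)
    }
    names(summaries) <- vapply(summaries, attr, character(1), "name")
  }
  stopifnot(inherits(plan, "resample_plan"))
  M <- attr(sample, "M")
  if (is.null(M)) M <- length(grep("^z[0-9]+$", names(sample)))
  zcols <- paste0("z", seq_len(M))
  streams <- replicate_streams(plan$seed, plan$B)

  one_replicate <- function(b) {
    with_stream(streams[[b]], {
      res <- resample_design_aware(sample, plan)
      cfg <- plan$replicate_config
      # the replicate fit consumes the stream RNG state, not a fixed seed
      cfg$seed <- sample.int(.Machine$integer.max, 1L)
      # summary points are evaluated during the chain itself, reusing each
      # iteration's factorization
      pts_list <- NULL
      if (!is.null(summaries)) {
        pts_list <- lapply(summaries, function(f) f$points_fn(res, M))
      }
      all_pts <- do.call(rbind, c(list(h_points), pts_list))
      fit <- try(mcmc_fit(res$y, as.matrix(res[, zcols, drop = FALSE]),
                          config = cfg, h_points = all_pts,
                          h_draw_noise = FALSE), silent = TRUE)
      if (inherits(fit, "try-error")) {
        return(list(ok = FALSE, error = as.character(fit)))
      }
      out <- list(ok = TRUE,
                  pips = compute_pips(fit),
                  accept = fit$accept,
                  fingerprint = sum(res$unit_id) %% 1e9)
      off <- 0L
      if (!is.null(h_points)) {
        out$h_mean <- colMeans(fit$draws$h[, seq_len(nrow(h_points)),
                                           drop = FALSE])
        off <- nrow(h_points)
      }
      if (!is.null(summaries)) {
        out$extra <- lapply(seq_along(summaries), function(k) {
          g <- nrow(pts_list[[k]])
          H <- fit$draws$h[, off + seq_len(g), drop = FALSE]
          off <<- off + g
          summaries[[k]]$reduce(H, res)
        })
        names(out$extra) <- names(summaries)
      }
      out
    })
  }

  reps <- if (plan$cores > 1L) {
    parallel::mclapply(seq_len(plan$B), one_replicate,
                       mc.cores = plan$cores, mc.set.seed = FALSE,
                       mc.preschedule = FALSE)
  } else {
    lapply(seq_len(plan$B), one_replicate)
  }

  ok <- vapply(reps, function(x) isTRUE(x$ok), logical(1))
  if (any(!ok)) {
    warning(sprintf("%d of %d replicate fits failed and were skipped",
                    sum(!ok), plan$B))
  }
  if (mean(ok) < 0.8) {
    stop("fewer than 80% of design-aware replicates succeeded; aborting")
  }
  reps <- reps[ok]

  pips <- do.call(rbind, lapply(reps, `[[`, "pips"))
  h_mean <- if (!is.null(h_points)) {
    do.call(rbind, lapply(reps, `[[`, "h_mean"))
  } else NULL
  extra <- NULL
  if (!is.null(summaries)) {
    extra <- lapply(names(summaries), function(nm) {
      m <- do.call(rbind, lapply(reps, function(x) x$extra[[nm]]))
      attr(m, "meta") <- attr(summaries[[nm]], "meta")
      m
    })
    names(extra) <- names(summaries)
  }

  structure(list(pips = pips, h_mean = h_mean, extra = extra,
                 h_points = h_points, B_effective = sum(ok), plan = plan,
                 sample = sample),
            class = "design_aware_fit")
}

#' @export
print.design_aware_fit <- function(x, ...) {
  cat(sprintf(
    "Design-aware kernel machine fit: %d/%d bootstrap replicates succeeded\n",
    x$B_effective, x$plan$B))
  cat("  mean PIPs across replicates:",
      paste(sprintf("%s = %.2f", colnames(x$pips), colMeans(x$pips)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Write replicate-level summaries as long-format CSV
#'
#' One row per replicate x summary element (replicate, summary_name,
#' grid_value, estimate), for audit of a design-aware run.
#'
#' @param daf a [run_design_aware()] result fitted with \code{summaries}.
#' @param path CSV path.
#' @export
write_replicate_summaries <- function(daf, path) {
  stopifnot(inherits(daf, "design_aware_fit"))
  if (is.null(daf$extra)) stop("run had no replicate summaries")
  rows <- lapply(names(daf$extra), function(nm) {
    m <- daf$extra[[nm]]
    grid <- colnames(m)
    if (is.null(grid)) grid <- as.character(seq_len(ncol(m)))
    data.frame(replicate = rep(seq_len(nrow(m)), times = ncol(m)),
               summary_name = nm,
               grid_value = rep(grid, each = nrow(m)),
               estimate = as.vector(m))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Aggregate replicate scalars into a replication-based estimate
#'
#' Point estimate = empirical mean across replicates; interval = 2.5th and
#' 97.5th percentiles (linear interpolation between order statistics).
#'
#' @param values finite replicate values (length B >= 1).
#' @param interval_kind label recorded on the result; design-aware replicate
#'   aggregation uses "replication-based".
#' @param level interval level, default 0.95.
#' @return an object of class \code{aggregated_estimate} with \code{point},
#'   \code{lo}, \code{hi} and \code{interval_kind}.
#' @export
aggregate_scalar <- function(values, interval_kind = "replication-based",
                             level = 0.95) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("no values to aggregate")
  stopifnot(all(is.finite(values)))
  a <- (1 - level) / 2
  qs <- stats::quantile(values, probs = c(a, 1 - a), names = FALSE, type = 7)
  structure(list(point = mean(values), lo = qs[1L], hi = qs[2L],
                 interval_kind = interval_kind, level = level,
                 B = length(values)),
            class = "aggregated_estimate")
}

#' @export
print.aggregated_estimate <- function(x, ...) {
  cat(sprintf("%.4f [%.4f, %.4f] (%g%% %s interval, %d values)\n",
              x$point, x$lo, x$hi, 100 * x$level, x$interval_kind, x$B))
  invisible(x)
}

#' Pointwise aggregation of replicate curves on a shared grid
#'
#' @param curves B x G matrix: one row per replicate, one column per grid
#'   point (all replicates share the grid).
#' @param interval_kind,level as in [aggregate_scalar()].
#' @return data frame with columns point, lo, hi (one row per grid point)
#'   and attribute \code{interval_kind}.
#' @export
aggregate_functional <- function(curves, interval_kind = "replication-based",
                                 level = 0.95) {
  curves <- as.matrix(curves)
  cols <- lapply(seq_len(ncol(curves)), function(g) {
    a <- aggregate_scalar(curves[, g], interval_kind, level)
    c(point = a$point, lo = a$lo, hi = a$hi)
  })
  out <- as.data.frame(do.call(rbind, cols))
  attr(out, "interval_kind") <- interval_kind
  out
}
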