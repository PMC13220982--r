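#' Stratified two-stage sampling design
#'
#' First stage: within each stratum, \code{k_h} PSUs are drawn by simple
#' random sampling without replacement. Second stage: within each selected
#' PSU, units are drawn without replacement either simple-randomly
#' (\code{regime = "srs"}) or with probabilities proportional to a shifted
#' positive function of the first exposure (\code{regime = "pps"}), which
#' makes selection informative because Z1 drives the outcome through h().
#'
#' @param n_total target sample size (realized exactly).
#' @param regime "srs" (non-informative) or "pps" (informative).
#' @param k_h PSUs sampled per stratum, default 4.
#' @param seed integer RNG seed for the draw.
#' @return an object of class \code{sampling_design}.
#' @export
sampling_design <- function(n_total = 300L, regime = c("srs", "pps"),
                            k_h = 4L, seed = 1L) {
  regime <- match.arg(regime)
  stopifnot(n_total >= 1, k_h >= 1)
  structure(list(n_total = as.integer(n_total), regime = regime,
                 k_h = as.integer(k_h), seed = as.integer(seed)),
            class = "sampling_design")
}

#' First-stage PSU selection
#'
#' @param population a [generate_population()] result.
#' @param design a [sampling_design()].
#' @return integer vector of selected PSU ids (sorted), exactly \code{k_h}
#'   per stratum.
#' @export
select_psus <- function(population, design) {
  stopifnot(inherits(population, "true_population"),
            inherits(design, "sampling_design"))
  H <- population$config$H
  C <- population$config$C
  psu_stratum <- ((seq_len(C) - 1L) %% H) + 1L
  sel <- integer(0)
  for (h in seq_len(H)) {
    pool <- which(psu_stratum == h)
    if (length(pool) < design$k_h) {
      stop(sprintf("stratum %d has %d PSUs, fewer than k_h = %d",
                   h, length(pool), design$k_h))
    }
    sel <- c(sel, if (length(pool) == design$k_h) pool else
      sample(pool, design$k_h))
  }
  sort(sel)
}

#' Within-PSU PPS selection probabilities
#'
#' Probabilities proportional to \code{max(Z1_i - min_j(Z1_j) + 1e-6, 0)}
#' within the cluster, normalized to sum to 1. The shift guarantees strict
#' positivity, so every unit remains selectable.
#'
#' @param z1_cluster Z1 values of the units in one PSU.
#' @return normalized probability vector, monotone nondecreasing in Z1.
#' @export
within_psu_probs_pps <- function(z1_cluster) {
  stopifnot(length(z1_cluster) >= 1)
  p <- pmax(z1_cluster - min(z1_cluster) + 1e-6, 0)
  p / sum(p)
}

# Second-stage take per selected PSU: base floor(n / (H*k_h)); the remainder
# is given one extra unit each to the first selected PSUs in label order.
allocate_takes <- function(n_total, selected_psus) {
  S <- length(selected_psus)
  base <- n_total %/% S
  extra <- n_total %% S
  takes <- rep.int(base, S)
  if (extra > 0) takes[seq_len(extra)] <- base + 1L
  stats::setNames(takes, selected_psus)
}

#' Approximate inclusion probabilities
#'
#' First-stage inclusion is \code{k_h / C_h}; second-stage is \code{m_c/N_c}
#' under SRS or \code{min(1, m_c * p_ic)} under PPS, with \code{p_ic} the
#' normalized within-PSU probability. The product is the approximate overall
#' inclusion probability used for weighting; it is an approximation (not the
#' exact without-replacement probability) by construction.
#'
#' @param p_within within-PSU selection probability per sampled unit
#'   (normalized PPS probability, or \code{1/N_c} under SRS).
#' @param m_c second-stage take of the unit's PSU.
#' @param N_c size of the unit's PSU.
#' @param k_h,C_h sampled and total PSUs in the unit's stratum.
#' @param regime "srs" or "pps".
#' @return vector of inclusion probabilities in (0, 1].
#' @export
inclusion_probs <- function(p_within, m_c, N_c, k_h, C_h,
                            regime = c("srs", "pps")) {
  regime <- match.arg(regime)
  p_first <- k_h / C_h
  p_second <- if (regime == "srs") m_c / N_c else pmin(1, m_c * p_within)
  pi <- p_first * p_second
  stopifnot(all(pi > 0), all(pi <= 1))
  pi
}

#' Base and rescaled survey weights
#'
#' Base weights are the inverse inclusion probabilities, \code{w_base = 1/pi};
#' analysis weights rescale them to mean 1 within the sample. Only relative
#' weights drive the resampling workflow, so rescaling leaves the estimand
#' unchanged while avoiding extreme magnitudes. No trimming is applied.
#'
#' @param pi inclusion probabilities in (0, 1].
#' @return list with \code{w_base} and \code{w} (mean exactly 1).
#' @export
make_weights <- function(pi) {
  stopifnot(all(is.finite(pi)), all(pi > 0), all(pi <= 1))
  w_base <- 1 / pi
  list(w_base = w_base, w = w_base / mean(w_base))
}

#' Draw a stratified two-stage survey sample
#'
#' @param population a [generate_population()] result.
#' @param design a [sampling_design()].
#' @return an object of class \code{survey_sample}: a data frame with columns
#'   unit_id, stratum, psu, z1..zM, y, p_within, pi, w_base, w, plus the
#'   design and population truth metadata as attributes.
#' @export
draw_sample <- function(population, design) {
  stopifnot(inherits(population, "true_population"),
            inherits(design, "sampling_design"))
  set.seed(design$seed)
  cfg <- population$config
  dat <- population$data
  C_h <- cfg$C / cfg$H

  sel <- select_psus(population, design)
  takes <- allocate_takes(design$n_total, sel)
  sizes <- population$psu_sizes

  rows <- vector("list", length(sel))
  pw <- vector("list", length(sel))
  for (i in seq_along(sel)) {
    c_id <- sel[i]
    idx <- which(dat$psu == c_id)
    m_c <- takes[i]
    if (m_c > length(idx)) {
      stop(sprintf("take m_c = %d exceeds PSU %d size %d",
                   m_c, c_id, length(idx)))
    }
    if (design$regime == "srs") {
      pick_local <- sample.int(length(idx), m_c)
      p_within_all <- rep(1 / length(idx), length(idx))
    } else {
      p_within_all <- within_psu_probs_pps(dat$z1[idx])
      pick_local <- sample.int(length(idx), m_c, prob = p_within_all)
    }
    rows[[i]] <- idx[pick_local]
    pw[[i]] <- p_within_all[pick_local]
  }

  take_of <- rep.int(takes, times = lengths(rows))
  size_of <- rep.int(sizes[sel], times = lengths(rows))
  idx <- unlist(rows)
  samp <- dat[idx, c("unit_id", "stratum", "psu",
                     paste0("z", seq_len(cfg$M)), "y")]
  samp$p_within <- unlist(pw)
  samp$pi <- inclusion_probs(samp$p_within, take_of, size_of,
                             design$k_h, C_h, design$regime)
  wts <- make_weights(samp$pi)
  samp$w_base <- wts$w_base
  samp$w <- wts$w
  rownames(samp) <- NULL

  structure(samp,
            class = c("survey_sample", "data.frame"),
            design = design, M = cfg$M,
            selected_psus = sel, psu_takes = takes)
}

#' @export
print.survey_sample <- function(x, ...) {
  d <- attr(x, "design")
  cat(sprintf(
    "Survey sample: n = %d from %d PSUs in %d strata (regime = %s)\n",
    nrow(x), length(unique(x$psu)), length(unique(x$stratum)), d$regime))
  cat(sprintf("  weights: mean %.6f, range [%.3f, %.3f]\n",
              mean(x$w), min(x$w), max(x$w)))
  invisible(x)
}

#' Per-PSU weight totals and means
#'
#' @param sample a [draw_sample()] result.
#' @return data frame with psu, stratum, sum_w and mean_w (\eqn{\bar w_c}).
#' @export
psu_weight_summary <- function(sample) {
  agg <- stats::aggregate(sample$w, by = list(psu = sample$psu,
                                              stratum = sample$stratum), sum)
  cnt <- as.integer(table(sample$psu)[as.character(agg$psu)])
  data.frame(psu = agg$psu, stratum = agg$stratum,
             sum_w = agg$x, mean_w = agg$x / cnt)
}

#' Lossless CSV round trip for survey samples
#' @param sample a [draw_sample()] result.
#' @param path CSV path.
#' @export
write_survey_sample <- function(sample, path) {
  df <- as.data.frame(sample)
  # full double precision so the round trip is lossless
  for (j in names(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_survey_sample
#' @export
read_survey_sample <- function(path) {
  df <- utils::read.csv(path)
  zcols <- grep("^z[0-9]+$", names(df), value = TRUE)
  structure(df, class = c("survey_sample", "data.frame"),
            M = length(zcols))
}
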