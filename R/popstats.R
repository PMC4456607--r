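#' Position histogram in dyad-relative coordinates
#'
#' Bins called positions with the origin at the initial dyad, the display
#' convention for nucleosome/TF position distributions. Bins are centered so
#' a bin straddles the origin (`[-bin/2, bin/2)`).
#'
#' @param positions Called positions (dyad-relative coordinates unless `origin` is
#'   supplied, in which case `origin` is subtracted first).
#' @param bin_bp Bin width, bp.
#' @param origin Origin subtracted from `positions` (default 0).
#' @return A data frame with `bin_start`, `bin_mid`, `count`. Empty input
#'   yields an empty histogram.
#' @export
position_histogram <- function(positions, bin_bp = 5, origin = 0) {
  positions <- positions[is.finite(positions)] - origin
  if (!length(positions)) {
    return(data.frame(bin_start = numeric(0), bin_mid = numeric(0),
                      count = integer(0)))
  }
  start <- floor(positions / bin_bp + 0.5) * bin_bp - bin_bp / 2
  agg <- table(start)
  data.frame(bin_start = as.numeric(names(agg)),
             bin_mid = as.numeric(names(agg)) + bin_bp / 2,
             count = as.integer(agg), row.names = NULL)
}

#' Conditional Poisson event fractions
#'
#' Given the probability `p0` that a molecule experienced no remodeling
#' event, infers the Poisson event mean `lambda = -log(p0)` and the
#' fractions of *remodeled* molecules that were remodeled exactly once or
#' more than once:
#' `frac_once = lambda * exp(-lambda) / (1 - exp(-lambda))`.
#'
#' @param p0 Unremodeled probability, strictly inside (0, 1).
#' @return A list with `p0`, `lambda`, `frac_once`, `frac_multi`.
#' @examples
#' poisson_event_fractions(0.55)  # ~73% once, ~27% more than once
#' @export
poisson_event_fractions <- function(p0) {
  if (!is.numeric(p0) || length(p0) != 1L || p0 <= 0 || p0 >= 1) {
    stop("`p0` must lie strictly inside (0, 1)", call. = FALSE)
  }
  lambda <- -log(p0)
  frac_once <- lambda * exp(-lambda) / (1 - exp(-lambda))
  list(p0 = p0, lambda = lambda, frac_once = frac_once,
       frac_multi = 1 - frac_once)
}

#' Fit the single-site binding isotherm
#'
#' Least-squares fit of `fraction = c / (c + Kd)` to fraction-bound data,
#' yielding the equilibrium dissociation constant. Accepts a
#' `titration_dataset` or a data frame with `concentration` and `fraction`
#' (optionally `n` for binomial errors).
#'
#' @param titration A `titration_dataset` or data frame.
#' @return A `kd_fit`: list with `kd`, `se`, `fit` (the `nls` object) and
#'   `per_conc` (with binomial standard errors when counts are known).
#' @export
fit_binding_isotherm <- function(titration) {
  d <- if (inherits(titration, "titration_dataset")) {
    titration$per_conc
  } else {
    as.data.frame(titration)
  }
  if (!all(c("concentration", "fraction") %in% names(d))) {
    stop("need `concentration` and `fraction` columns", call. = FALSE)
  }
  if (length(unique(d$concentration)) < 3) {
    stop("need at least 3 concentrations", call. = FALSE)
  }
  if (all(d$fraction >= 1) || all(d$fraction <= 0)) {
    stop("Kd is unidentifiable: all molecules bound or all unbound",
         call. = FALSE)
  }
  start_kd <- d$concentration[which.min(abs(d$fraction - 0.5))]
  fit <- minpack.lm::nlsLM(
    fraction ~ concentration / (concentration + kd),
    data = d, start = list(kd = max(start_kd, 1e-6)),
    lower = 0, control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  co <- summary(fit)$coefficients
  if ("n" %in% names(d)) {
    d$se <- sqrt(pmax(d$fraction * (1 - d$fraction), 0) / d$n)
  }
  structure(list(kd = unname(co[1, 1]), se = unname(co[1, 2]), fit = fit,
                 per_conc = d),
            class = "kd_fit")
}

#' Fit bound fraction versus time
#'
#' Ordinary least-squares line through occupancy-versus-time data, with a
#' stability verdict: occupancy is "stable" (no significant dissociation)
#' when the confidence interval of the slope covers zero.
#'
#' @param times Time points (e.g. minutes).
#' @param fractions Bound fractions at each time.
#' @param level Confidence level for the slope interval.
#' @return A list with `slope`, `intercept`, `slope_ci`, `stable`, `fit`.
#' @export
fit_occupancy_vs_time <- function(times, fractions, level = 0.95) {
  if (length(times) < 2 || length(times) != length(fractions)) {
    stop("need at least two (time, fraction) pairs", call. = FALSE)
  }
  fit <- stats::lm(fractions ~ times)
  cf <- stats::coef(fit)
  ci <- if (length(times) > 2) {
    # perfect fits (zero residual) trigger a spurious precision warning
    suppressWarnings(stats::confint(fit, "times", level = level))
  } else {
    matrix(c(-Inf, Inf), nrow = 1)
  }
  list(slope = unname(cf[2]), intercept = unname(cf[1]),
       slope_ci = as.numeric(ci), stable = ci[1] <= 0 && ci[2] >= 0,
       fit = fit)
}

#' Precision and accuracy of position calls
#'
#' Accuracy is the difference between the mean called position and the
#' expected position (bias); precision is the sample standard deviation of
#' the calls.
#'
#' @param calls Called positions, bp.
#' @param expected Expected true position, bp.
#' @return A list with `bias`, `sd`, `n`.
#' @export
precision_accuracy <- function(calls, expected) {
  calls <- calls[is.finite(calls)]
  if (length(calls) < 2) stop("need at least 2 calls", call. = FALSE)
  list(bias = mean(calls) - expected, sd = stats::sd(calls),
       n = length(calls))
}

#' Barrier-centering statistics of remodeled dyads
#'
#' For each molecule, the distance the nucleosome moved and the deviation of
#' its final dyad from the midpoint of the accessible segment between the TF
#' footprint edge and the template end (the expected steady state of a
#' barrier-sensing remodeler). Molecules without an initially bound TF are
#' flagged as outliers; they are kept in the distance-moved summary by
#' default and always excluded from the midpoint-deviation summary (the
#' barrier midpoint is undefined without a barrier).
#'
#' @param initial_dyads,final_dyads Dyad positions, template coordinates.
#' @param layout The template layout (barrier and end coordinates).
#' @param tf_bound Optional logical vector of initial TF occupancy.
#' @param exclude_outliers Logical; also drop TF-free molecules from the
#'   distance-moved summary.
#' @return A list with `per_molecule` (data frame: `distance_moved`,
#'   `midpoint_deviation`, `outlier`), `midpoint`, `mean_distance_moved`,
#'   `sem_distance_moved`, `mean_abs_midpoint_deviation`,
#'   `mean_midpoint_deviation`, `sem_midpoint_deviation`, `n_outliers`.
#' @export
centering_statistic <- function(initial_dyads, final_dyads, layout,
                                tf_bound = NULL, exclude_outliers = FALSE) {
  stopifnot(length(initial_dyads) == length(final_dyads))
  if (is.na(layout$tf_center)) {
    stop("layout has no TF barrier", call. = FALSE)
  }
  n <- length(final_dyads)
  tf_bound <- tf_bound %||% rep(TRUE, n)
  side <- sign(stats::median(initial_dyads) - layout$tf_center)
  edge <- layout$tf_center + side * layout$tf_footprint
  end <- if (side > 0) layout$template_len - 1 else 0
  midpoint <- (edge + end) / 2

  per <- data.frame(
    distance_moved = abs(final_dyads - initial_dyads),
    midpoint_deviation = final_dyads - midpoint,
    outlier = !tf_bound
  )
  keep_dist <- if (exclude_outliers) !per$outlier else rep(TRUE, n)
  keep_mid <- !per$outlier
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  list(
    per_molecule = per, midpoint = midpoint,
    mean_distance_moved = mean(per$distance_moved[keep_dist]),
    sem_distance_moved = sem(per$distance_moved[keep_dist]),
    mean_abs_midpoint_deviation = mean(abs(per$midpoint_deviation[keep_mid])),
    mean_midpoint_deviation = mean(per$midpoint_deviation[keep_mid]),
    sem_midpoint_deviation = sem(per$midpoint_deviation[keep_mid]),
    n_outliers = sum(per$outlier)
  )
}

#' Directionality and TF-eviction summary of an ensemble
#'
#' Classifies each remodeled, initially TF-bound molecule by the sign of its
#' dyad displacement relative to the TF site, and tabulates TF retention and
#' the fraction of final dyads that ended up beyond the TF site.
#'
#' @param molecules Data frame with `dyad_initial`, `dyad_final`,
#'   `tf_bound_initial`, `tf_bound_final` (e.g.
#'   `simulate_remodeling_ensemble()$molecules`, or pipeline calls joined to
#'   truth).
#' @param tf_center TF consensus center, template coordinates.
#' @param remodel_threshold_bp Minimum |displacement| to count a molecule as
#'   remodeled, bp.
#' @return A list with `n_remodeled`, `frac_remodeled`, `frac_toward_tf`,
#'   `frac_away`, `frac_tf_retained`, `frac_passed_tf` (fractions are `NaN`
#'   when no molecule qualifies).
#' @export
directionality_and_eviction_summary <- function(molecules, tf_center,
                                                remodel_threshold_bp = 2) {
  m <- molecules[molecules$tf_bound_initial, , drop = FALSE]
  disp <- m$dyad_final - m$dyad_initial
  rem <- abs(disp) > remodel_threshold_bp
  mr <- m[rem, , drop = FALSE]
  disp_r <- disp[rem]
  toward <- sign(tf_center - mr$dyad_initial)
  passed <- sign(mr$dyad_final - tf_center) != sign(mr$dyad_initial - tf_center)
  list(
    n_remodeled = nrow(mr),
    frac_remodeled = if (nrow(m)) mean(rem) else NaN,
    frac_toward_tf = mean(sign(disp_r) == toward),
    frac_away = mean(sign(disp_r) == -toward),
    frac_tf_retained = mean(mr$tf_bound_final),
    frac_passed_tf = mean(passed)
  )
}
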