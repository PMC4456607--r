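#' Simulate a nucleosome-remodeling ensemble
#'
#' Draws, for `n` molecules, an initial TF occupancy (bound with probability
#' `p_tf_bound`, emulating reactions run near binding saturation), a Poisson
#' number of remodeling events set by the reaction duration, and applies the
#' remodeler's repositioning rules event by event:
#'
#' * `none`: no events; every molecule keeps its initial dyad and occupancy.
#' * `isw1a`: each event contracts the dyad toward the midpoint of the
#'   accessible segment (between the bound-TF footprint edge and the template
#'   end on the nucleosome's side, or the whole template when no TF is
#'   bound); the footprint never crosses a bound TF or a template end.
#' * `swisnf`: each event displaces the dyad by a Normal step (first event
#'   biased toward the TF), clamped to the template; if the sliding
#'   footprint overlaps the TF footprint at any point of the move, a bound
#'   TF is evicted.
#'
#' @param layout A [build_template()] layout.
#' @param remodeler A [remodeler_model()].
#' @param n Number of molecules.
#' @param duration `"short"` (single-event regime) or `"long"` (multiple
#'   rounds).
#' @param seed Seed; per-molecule sub-seeds are derived from it and recorded.
#' @param p_tf_bound Probability that the TF site is initially occupied
#'   (ignored for layouts without a TF site).
#' @param render_traces Logical; also simulate an unzipping trace of each
#'   molecule's final state.
#' @param signature,instrument Models used when rendering traces.
#' @return An `ensemble_dataset`: list with `molecules` (data frame: `id`,
#'   `sub_seed`, `n_events`, `dyad_initial`, `dyad_final`,
#'   `tf_bound_initial`, `tf_bound_final`, in template coordinates),
#'   `events` (data frame of per-event logs: `id`, `event`, `dyad_from`,
#'   `dyad_to`, `overlapped_tf`), `layout`, `remodeler`, `duration`,
#'   `traces` (list or `NULL`).
#' @export
simulate_remodeling_ensemble <- function(layout, remodeler, n,
                                         duration = c("short", "long"),
                                         seed = NULL, p_tf_bound = 0.95,
                                         render_traces = FALSE,
                                         signature = signature_model(),
                                         instrument = instrument_model()) {
  stopifnot(inherits(layout, "template_layout"),
            inherits(remodeler, "remodeler_model"), n >= 1)
  duration <- match.arg(duration)
  lambda <- if (remodeler$kind == "none") 0 else {
    switch(duration, short = remodeler$lambda_short,
           long = remodeler$lambda_long)
  }
  L <- layout$template_len
  has_tf <- !is.na(layout$tf_center)
  tf_c <- layout$tf_center
  tf_hw <- layout$tf_footprint
  overlap_dist <- 73 + tf_hw   # dyad-to-TF-center distance below which footprints overlap

  with_seed(seed, {
    sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
    mols <- vector("list", n)
    evlogs <- vector("list", n)

    for (m in seq_len(n)) {
      set.seed(sub_seeds[m])
      dyad <- layout$dyad0
      tf0 <- has_tf && stats::runif(1) < p_tf_bound
      tf <- tf0
      K <- stats::rpois(1, lambda)
      ev <- if (K > 0) {
        data.frame(id = m, event = seq_len(K), dyad_from = NA_real_,
                   dyad_to = NA_real_, overlapped_tf = FALSE)
      } else NULL

      for (k in seq_len(K)) {
        from <- dyad
        if (remodeler$kind == "isw1a") {
          # accessible segment on the nucleosome's side of the barrier
          if (tf) {
            if (dyad > tf_c) {
              seg <- c(tf_c + tf_hw, L - 1)
            } else {
              seg <- c(0, tf_c - tf_hw)
            }
          } else {
            seg <- c(0, L - 1)
          }
          lo <- seg[1] + 73
          hi <- seg[2] - 73
          mid <- mean(seg)
          eta <- remodeler$isw1a_center_sd * sqrt(1 - remodeler$isw1a_pull^2)
          new <- mid + remodeler$isw1a_pull * (dyad - mid) +
            stats::rnorm(1, 0, eta)
          tries <- 0
          while ((new < lo || new > hi) && tries < 100) {
            new <- mid + remodeler$isw1a_pull * (dyad - mid) +
              stats::rnorm(1, 0, eta)
            tries <- tries + 1
          }
          new <- min(max(new, lo), hi)
          dyad <- new
        } else if (remodeler$kind == "swisnf") {
          step <- stats::rnorm(1, 0, remodeler$step_sd)
          if (tf && has_tf) {
            toward <- sign(tf_c - dyad)
            if (toward != 0) {
              s_dir <- if (stats::runif(1) < remodeler$swisnf_asymmetry) {
                toward
              } else {
                -toward
              }
              step <- s_dir * abs(step)
            }
          }
          new <- min(max(dyad + step, 73), L - 1 - 73)
          overlapped <- has_tf &&
            (min(dyad, new) - overlap_dist <= tf_c) &&
            (max(dyad, new) + overlap_dist >= tf_c)
          ev$overlapped_tf[k] <- overlapped
          if (overlapped && tf && remodeler$evict_on_overlap) tf <- FALSE
          dyad <- new
        }
        ev$dyad_from[k] <- from
        ev$dyad_to[k] <- dyad
      }

      mols[[m]] <- data.frame(
        id = m, sub_seed = sub_seeds[m], n_events = K,
        dyad_initial = layout$dyad0, dyad_final = dyad,
        tf_bound_initial = tf0, tf_bound_final = tf
      )
      evlogs[[m]] <- ev
    }

    molecules <- do.call(rbind, mols)
    events <- do.call(rbind, evlogs[!vapply(evlogs, is.null, logical(1))])
    if (is.null(events)) {
      events <- data.frame(id = integer(0), event = integer(0),
                           dyad_from = numeric(0), dyad_to = numeric(0),
                           overlapped_tf = logical(0))
    }

    traces <- NULL
    if (isTRUE(render_traces)) {
      traces <- lapply(seq_len(n), function(m) {
        simulate_trace(layout, tf_bound = molecules$tf_bound_final[m],
                       nuc_present = TRUE, signature = signature,
                       instrument = instrument,
                       seed = sub_seeds[m] %% .Machine$integer.max,
                       dyad = molecules$dyad_final[m])
      })
    }

    structure(
      list(molecules = molecules, events = events, layout = layout,
           remodeler = remodeler, duration = duration, seed = seed,
           traces = traces),
      class = "ensemble_dataset"
    )
  })
}

#' Simulate an equilibrium binding titration
#'
#' Each molecule at concentration `c` is bound with the single-site
#' isotherm probability `c / (c + Kd)`; per-concentration bound counts are
#' the resulting binomial draws.
#'
#' @param concentrations TF concentrations, nM (all positive).
#' @param true_kd Generating dissociation constant, nM.
#' @param n_per_conc Molecules measured per concentration (scalar or
#'   vector).
#' @param seed Seed.
#' @return A `titration_dataset`: list with `per_conc` (data frame:
#'   `concentration`, `n`, `n_bound`, `fraction`), `bound` (list of
#'   per-molecule logical vectors) and `true_kd`.
#' @export
simulate_binding_titration <- function(concentrations, true_kd, n_per_conc,
                                       seed = NULL) {
  if (any(concentrations <= 0)) {
    stop("concentrations must be positive", call. = FALSE)
  }
  if (true_kd < 0) stop("`true_kd` must be >= 0", call. = FALSE)
  if (any(n_per_conc < 1)) stop("`n_per_conc` must be >= 1", call. = FALSE)
  n_per_conc <- rep_len(as.integer(n_per_conc), length(concentrations))
  with_seed(seed, {
    bound <- lapply(seq_along(concentrations), function(i) {
      p <- concentrations[i] / (concentrations[i] + true_kd)
      stats::runif(n_per_conc[i]) < p
    })
    per_conc <- data.frame(
      concentration = concentrations,
      n = n_per_conc,
      n_bound = vapply(bound, sum, integer(1)),
      fraction = vapply(bound, mean, numeric(1))
    )
    structure(list(per_conc = per_conc, bound = bound, true_kd = true_kd),
              class = "titration_dataset")
  })
}

#' @export
print.ensemble_dataset <- function(x, ...) {
  cat(sprintf("<ensemble_dataset> %d molecules, remodeler = %s, duration = %s\n",
              nrow(x$molecules), x$remodeler$kind, x$duration))
  cat(sprintf("  events per molecule: mean %.2f; TF retained: %d/%d initially bound\n",
              mean(x$molecules$n_events),
              sum(x$molecules$tf_bound_final & x$molecules$tf_bound_initial),
              sum(x$molecules$tf_bound_initial)))
  invisible(x)
}
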