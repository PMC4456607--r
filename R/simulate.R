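#' Simulate a single unzipping trace
#'
#' Generates a force-versus-position record for one molecule under a
#' per-base-pair disruption-threshold model. Every bp carries a threshold:
#' the seeded naked-DNA baseline profile, raised inside the TF and nucleosome
#' signature regions by two-sided exponential kernels. The fork advances
#' while the current force meets the threshold; otherwise the force ramps at
#' the loading rate until disruption, and after each disruption the excess
#' force relaxes toward the baseline with a `relax_bp` constant, so closely
#' spaced interactions are met at an elevated initial force. The returned
#' record holds one force sample per bp (the reduced, bandwidth-limited
#' product of acquisition), with per-bp dwell times accumulated into an
#' optional time series.
#'
#' Signature geometry follows the field's conventions: a bound TF yields a
#' single 18-20 pN peak at `tf_center - 8` bp (unzipping coordinates) and a
#' nucleosome yields two 25-35 pN clusters with the first-cluster center at
#' `dyad - 43` bp. On noiseless settings (`baseline_sd = 0`,
#' `force_noise_sd = 0`) the recorded profiles are exactly symmetric about
#' those positions.
#'
#' @param layout A [build_template()] layout.
#' @param tf_bound,nuc_present Logical occupancy of the TF site and the
#'   nucleosome.
#' @param signature A [signature_model()].
#' @param instrument An [instrument_model()].
#' @param seed Seed for the per-trace draws (peak forces, measurement noise).
#' @param dyad Nucleosome dyad in template coordinates; defaults to the
#'   layout's initial dyad (override to render remodeled molecules).
#' @param include_time Logical; record the cumulative dwell-time series.
#' @return An `unzip_trace`: list with `positions` (bp unzipped, 1 bp grid),
#'   `forces` (pN), optional `time_s`, and `meta` truth annotations
#'   (template geometry, direction, occupancy, true positions in unzipping
#'   coordinates, drawn peak forces, seed, applied distortion).
#' @examples
#' lay <- build_template(800, 10, "from_tf_side")
#' tr <- simulate_trace(lay, tf_bound = TRUE, nuc_present = TRUE, seed = 1)
#' range(tr$forces)
#' @export
simulate_trace <- function(layout, tf_bound = FALSE, nuc_present = FALSE,
                           signature = signature_model(),
                           instrument = instrument_model(),
                           seed = NULL, dyad = layout$dyad0,
                           include_time = FALSE) {
  stopifnot(inherits(layout, "template_layout"),
            inherits(signature, "signature_model"),
            inherits(instrument, "instrument_model"))
  L <- layout$template_len
  x <- 0:(L - 1)

  base <- baseline_profile(L, signature$baseline_mean, signature$baseline_sd,
                           signature$baseline_corr_bp, signature$baseline_seed)

  with_seed(seed, {
    elev <- numeric(L)
    tf_peak_u <- NA_real_
    tf_peak_force <- NA_real_
    c1_u <- NA_real_
    c2_u <- NA_real_
    cluster_forces <- c(NA_real_, NA_real_)

    # raises the disruption threshold so the recorded peak force equals the
    # drawn disruption force at the signature center, whatever the local
    # baseline value there
    kernel <- function(center, peak_force, half_width) {
      lo <- max(0L, ceiling(center - half_width))
      hi <- min(L - 1L, floor(center + half_width))
      if (lo > hi) return(invisible(NULL))
      b_center <- base[max(1L, min(L, as.integer(round(center)) + 1L))]
      amp <- max(peak_force - b_center, 1)
      idx <- (lo:hi) + 1L
      bump <- amp * exp(-abs((lo:hi) - center) / signature$decay_bp)
      elev[idx] <<- pmax(elev[idx], bump)
      invisible(NULL)
    }

    if (isTRUE(tf_bound)) {
      if (is.na(layout$tf_center)) {
        stop("layout has no TF site but `tf_bound = TRUE`", call. = FALSE)
      }
      tf_u <- template_to_unzip(layout$tf_center, L, layout$direction)
      tf_peak_u <- tf_u + signature$tf_peak_offset
      r <- signature$tf_peak_force_range
      tf_peak_force <- stats::runif(1, r[1], r[2])
      kernel(tf_peak_u, tf_peak_force, signature$tf_half_width)
    }
    if (isTRUE(nuc_present)) {
      dyad_u <- template_to_unzip(dyad, L, layout$direction)
      c1_u <- dyad_u + signature$nuc_cluster1_offset
      c2_u <- dyad_u + signature$nuc_cluster2_offset
      r <- signature$cluster_peak_force_range
      cluster_forces <- stats::runif(2, r[1], r[2])
      kernel(c1_u, cluster_forces[1], signature$cluster_half_width)
      kernel(c2_u, cluster_forces[2], signature$cluster_half_width)
    }

    thr <- base + elev
    rho <- exp(-1 / instrument$relax_bp)
    bare_dwell <- 1 / instrument$fork_velocity

    force <- numeric(L)
    dwell <- numeric(L)
    f <- thr[1]
    force[1] <- f
    dwell[1] <- bare_dwell + max(0, thr[1] - base[1]) / instrument$ramp_rate
    for (i in 2:L) {
      arrival <- base[i] + (f - base[i - 1]) * rho
      if (arrival < base[i]) arrival <- base[i]
      if (arrival < thr[i]) {
        dwell[i] <- bare_dwell + (thr[i] - arrival) / instrument$ramp_rate
        f <- thr[i]
      } else {
        dwell[i] <- bare_dwell
        f <- arrival
      }
      force[i] <- f
    }

    if (instrument$force_noise_sd > 0) {
      force <- force + stats::rnorm(L, 0, instrument$force_noise_sd)
    }

    trace <- list(
      positions = as.numeric(x),
      forces = force,
      time_s = if (include_time) cumsum(dwell) else NULL,
      meta = list(
        template = layout,
        direction = layout$direction,
        seed = seed,
        tf_bound = isTRUE(tf_bound),
        nuc_present = isTRUE(nuc_present),
        dyad_template = if (isTRUE(nuc_present)) dyad else NA_real_,
        dyad_u = if (isTRUE(nuc_present)) {
          template_to_unzip(dyad, L, layout$direction)
        } else NA_real_,
        tf_center_u = if (isTRUE(tf_bound)) {
          template_to_unzip(layout$tf_center, L, layout$direction)
        } else NA_real_,
        tf_peak_u = tf_peak_u,
        tf_peak_force = tf_peak_force,
        c1_u = c1_u,
        c2_u = c2_u,
        cluster_forces = cluster_forces,
        shift_bp = 0,
        stretch = 1,
        synthetic = TRUE
      )
    )
    class(trace) <- "unzip_trace"
    trace
  })
}

#' Apply an instrumental shift and stretch to a trace
#'
#' Maps trace positions through the affine distortion `x -> stretch * x +
#' shift`, emulating instrument drift, bead-size variation and DNA-linker
#' variation. Distortions outside the declared alignment search bounds
#' (|shift| <= 10 bp, |stretch - 1| < 0.02) are rejected.
#'
#' @param trace An `unzip_trace`.
#' @param shift_bp Additive position offset, bp.
#' @param stretch Multiplicative position scale.
#' @param instrument An [instrument_model()] supplying the declared bounds.
#' @return The distorted `unzip_trace`; `meta$shift_bp` and `meta$stretch`
#'   record the cumulative applied distortion.
#' @export
distort_trace <- function(trace, shift_bp, stretch,
                          instrument = instrument_model()) {
  stopifnot(inherits(trace, "unzip_trace"))
  if (abs(shift_bp) > instrument$shift_bound + 1e-9) {
    stop(sprintf("|shift_bp| must be <= %g bp", instrument$shift_bound),
         call. = FALSE)
  }
  if (abs(stretch - 1) > instrument$stretch_bound + 1e-9) {
    stop(sprintf("|stretch - 1| must be within %g", instrument$stretch_bound),
         call. = FALSE)
  }
  trace$positions <- stretch * trace$positions + shift_bp
  trace$meta$shift_bp <- stretch * trace$meta$shift_bp + shift_bp
  trace$meta$stretch <- stretch * trace$meta$stretch
  trace
}

#' Noiseless model pair
#'
#' Convenience constructor for a flat-baseline, noise-free signature and
#' instrument model pair, under which the simulator's position conventions
#' are exact.
#'
#' @return A list with elements `signature` and `instrument`.
#' @export
noiseless_models <- function() {
  list(signature = signature_model(baseline_sd = 0),
       instrument = instrument_model(force_noise_sd = 0))
}

#' @export
print.unzip_trace <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<unzip_trace> %d samples, %.1f-%.1f bp, force %.1f-%.1f pN\n",
              length(x$positions), min(x$positions), max(x$positions),
              min(x$forces), max(x$forces)))
  cat(sprintf("  direction = %s, tf_bound = %s, nuc_present = %s\n",
              m$direction %||% "?", m$tf_bound %||% NA, m$nuc_present %||% NA))
  invisible(x)
}
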