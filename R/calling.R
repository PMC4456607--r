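#' Estimate the naked-DNA baseline and detection threshold
#'
#' The baseline is the smoothed force of the aligned naked-DNA reference;
#' the detection threshold adds `k` times the reference residual SD, with a
#' configurable floor, so that "readily differentiable" excursions above the
#' naked-DNA force are flagged and baseline-level noise is not.
#'
#' @param trace An aligned `unzip_trace` sharing the reference grid.
#' @param reference The naked-DNA `unzip_trace` on the same grid.
#' @param k Threshold multiplier on the reference residual SD.
#' @param smooth_bp Running-mean window (odd, bp) for the baseline.
#' @param min_prominence Floor on the threshold level above baseline, pN.
#' @return A `baseline_estimate`: list with `positions`, `baseline`,
#'   `threshold`, `level` (threshold minus baseline) and `resid_sd`.
#' @export
estimate_baseline <- function(trace, reference, k = 3, smooth_bp = 5,
                              min_prominence = 1) {
  stopifnot(inherits(trace, "unzip_trace"), inherits(reference, "unzip_trace"))
  idx <- match(round(trace$positions, 6), round(reference$positions, 6))
  if (anyNA(idx)) {
    stop("trace and reference are not on a common position grid; align first",
         call. = FALSE)
  }
  base_full <- run_mean(reference$forces, smooth_bp)
  resid_sd <- stats::sd(reference$forces - base_full)
  level <- max(k * resid_sd, min_prominence)
  baseline <- base_full[idx]
  structure(
    list(positions = trace$positions, baseline = baseline,
         threshold = baseline + level, level = level, resid_sd = resid_sd),
    class = "baseline_estimate"
  )
}

#' Detect disruption-force events above baseline
#'
#' Finds local maxima of the (lightly smoothed) force excess over the
#' baseline that exceed the detection threshold. Peak positions are refined
#' to sub-bp resolution by a three-point parabolic fit; on a symmetric
#' noiseless peak the refinement is exact. The reported `peak_force` is the
#' raw recorded force at the peak; `prominence` is the smoothed excess over
#' baseline.
#'
#' @param trace An aligned `unzip_trace`.
#' @param baseline A [estimate_baseline()] result on the same grid.
#' @param smooth_bp Running-mean window (odd, bp) applied to the residual
#'   before peak picking.
#' @return A data frame of events ordered by position: `position`,
#'   `peak_force`, `prominence`, `index`. Zero rows when nothing exceeds the
#'   threshold.
#' @export
detect_events <- function(trace, baseline, smooth_bp = 3) {
  stopifnot(inherits(baseline, "baseline_estimate"))
  if (length(trace$positions) != length(baseline$positions) ||
      max(abs(trace$positions - baseline$positions)) > 1e-6) {
    stop("trace and baseline grids differ", call. = FALSE)
  }
  r <- trace$forces - baseline$baseline
  rs <- run_mean(r, smooth_bp)
  n <- length(rs)
  empty <- data.frame(position = numeric(0), peak_force = numeric(0),
                      prominence = numeric(0), index = integer(0))
  if (n < 3) return(empty)

  above <- rs > baseline$level
  i <- 2:(n - 1)
  is_peak <- above[i] & rs[i] >= rs[i - 1] & rs[i] > rs[i + 1]
  idx <- i[is_peak]
  if (!length(idx)) return(empty)

  step <- trace$positions[2] - trace$positions[1]
  pos <- vapply(idx, function(j) {
    denom <- rs[j - 1] - 2 * rs[j] + rs[j + 1]
    off <- if (denom < 0) 0.5 * (rs[j - 1] - rs[j + 1]) / denom else 0
    trace$positions[j] + max(-1, min(1, off)) * step
  }, numeric(1))

  out <- data.frame(position = pos, peak_force = trace$forces[idx],
                    prominence = rs[idx], index = idx)
  out[order(out$position), , drop = FALSE]
}

#' Group events into force clusters
#'
#' Splits position-sorted events wherever the inter-event gap exceeds
#' `gap_bp`. For each cluster the position centroid is, by default, the
#' force-weighted mean of the above-threshold trace samples belonging to the
#' cluster (weights are the raw force excess over baseline); with
#' `centroid = "events"` it is the prominence-weighted mean of the event
#' positions. The cluster span is the range of above-threshold samples
#' within `gap_bp` of the cluster's events.
#'
#' @param events A [detect_events()] data frame.
#' @param gap_bp Gap threshold separating clusters, bp.
#' @param trace,baseline The trace and baseline used for detection
#'   (required for the sample-weighted centroid and span).
#' @param centroid `"samples"` (default) or `"events"`.
#' @param smooth_bp Residual smoothing used to reproduce the detection
#'   above-threshold mask.
#' @return A data frame with one row per cluster: `start`, `end`, `width`,
#'   `centroid`, `max_force`, `n_events`.
#' @export
segment_clusters <- function(events, gap_bp = 15, trace = NULL,
                             baseline = NULL,
                             centroid = c("samples", "events"),
                             smooth_bp = 3) {
  centroid <- match.arg(centroid)
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      width = numeric(0), centroid = numeric(0),
                      max_force = numeric(0), n_events = integer(0))
  if (!nrow(events)) return(empty)
  ev <- events[order(events$position), , drop = FALSE]
  grp <- cumsum(c(1, diff(ev$position) > gap_bp))

  use_samples <- centroid == "samples" && !is.null(trace) && !is.null(baseline)
  if (centroid == "samples" && (is.null(trace) || is.null(baseline))) {
    stop("sample-weighted centroids need `trace` and `baseline`", call. = FALSE)
  }
  if (use_samples) {
    r <- trace$forces - baseline$baseline
    rs <- run_mean(r, smooth_bp)
    above <- rs > baseline$level
  }

  rows <- lapply(split(seq_len(nrow(ev)), grp), function(ii) {
    e <- ev[ii, , drop = FALSE]
    if (use_samples) {
      sel <- above & trace$positions >= min(e$position) - gap_bp &
        trace$positions <= max(e$position) + gap_bp
      xs <- trace$positions[sel]
      wts <- pmax(r[sel], 0)
      cen <- if (sum(wts) > 0) sum(xs * wts) / sum(wts) else mean(xs)
      data.frame(start = min(xs), end = max(xs), width = diff(range(xs)),
                 centroid = cen,
                 max_force = max(trace$forces[sel]),
                 n_events = nrow(e))
    } else {
      cen <- sum(e$position * e$prominence) / sum(e$prominence)
      data.frame(start = min(e$position), end = max(e$position),
                 width = diff(range(e$position)), centroid = cen,
                 max_force = max(e$peak_force), n_events = nrow(e))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$start), , drop = FALSE]
}

#' Call the transcription-factor binding state and center
#'
#' Looks for a disruption event inside a window around the expected TF site.
#' The called consensus center is the peak position shifted by 8 bp along
#' the unzipping direction (the peak marks the front edge of the TF
#' footprint). If the search window is covered by a nucleosome force
#' cluster the call is flagged `masked` (the TF signature cannot be
#' distinguished from the nucleosome's) rather than reported unbound.
#'
#' @param events A [detect_events()] data frame.
#' @param clusters A [segment_clusters()] data frame (to exclude nucleosome
#'   peaks and detect masking).
#' @param layout The template layout (expected TF site).
#' @param direction Unzipping direction of the trace.
#' @param signature A [signature_model()] (calling offsets).
#' @param window_bp Half-width of the search window around the expected TF
#'   center, bp.
#' @param nuc_force_floor Minimum cluster max force for a cluster to count
#'   as nucleosomal, pN.
#' @return A `tf_call`: list with `bound` (logical, `NA` when masked),
#'   `masked`, `peak_position`, `peak_force`, `called_center` (unzipping
#'   coordinates), `called_center_template`, `called_center_rel`.
#' @export
call_tf <- function(events, clusters, layout, direction = layout$direction,
                    signature = signature_model(), window_bp = 30,
                    nuc_force_floor = 22) {
  co <- layout_unzip_coords(layout, direction, signature)
  if (is.na(co$tf_center_u)) {
    stop("layout has no TF site to call", call. = FALSE)
  }
  win <- co$tf_center_u + c(-window_bp, window_bp)

  nuc <- clusters[clusters$max_force >= nuc_force_floor, , drop = FALSE]
  overlap <- nrow(nuc) > 0 && any(nuc$start <= win[2] & nuc$end >= win[1])

  cand <- events[events$position >= win[1] & events$position <= win[2], ,
                 drop = FALSE]
  if (nrow(nuc) > 0 && nrow(cand) > 0) {
    in_nuc <- vapply(cand$position, function(p) {
      any(p >= nuc$start & p <= nuc$end)
    }, logical(1))
    cand <- cand[!in_nuc, , drop = FALSE]
  }

  L <- layout$template_len
  if (nrow(cand) > 0) {
    top <- cand[which.max(cand$prominence), ]
    center_u <- top$position - signature$tf_peak_offset
    center_t <- unzip_to_template(center_u, L, direction)
    call <- list(bound = TRUE, masked = FALSE,
                 peak_position = top$position, peak_force = top$peak_force,
                 called_center = center_u,
                 called_center_template = center_t,
                 called_center_rel = template_to_rel(center_t, layout$dyad0))
  } else if (overlap) {
    call <- list(bound = NA, masked = TRUE, peak_position = NA_real_,
                 peak_force = NA_real_, called_center = NA_real_,
                 called_center_template = NA_real_,
                 called_center_rel = NA_real_)
  } else {
    call <- list(bound = FALSE, masked = FALSE, peak_position = NA_real_,
                 peak_force = NA_real_, called_center = NA_real_,
                 called_center_template = NA_real_,
                 called_center_rel = NA_real_)
  }
  structure(call, class = "tf_call")
}

#' Call the nucleosome presence and dyad
#'
#' A nucleosome is present when at least one force cluster reaches the
#' nucleosome force floor (nucleosome disruption forces are well above TF
#' peaks). The dyad is the force-weighted centroid of the first-encountered
#' qualifying cluster shifted by 43 bp along the unzipping direction.
#' Structural features (cluster max forces, widths, inter-cluster distance)
#' are reported when two qualifying clusters exist.
#'
#' @param clusters A [segment_clusters()] data frame.
#' @param layout The template layout.
#' @param direction Unzipping direction of the trace.
#' @param signature A [signature_model()] (calling offsets).
#' @param force_floor Minimum cluster max force to qualify, pN.
#' @return A `nucleosome_call`: list with `present`, `called_dyad`
#'   (unzipping coordinates), `called_dyad_template`, `called_dyad_rel`
#'   and `features` (`max_force_c1`, `max_force_c2`, `width_c1`, `width_c2`,
#'   `intercluster_distance`; `NA` when fewer than two clusters qualify).
#' @export
call_nucleosome <- function(clusters, layout, direction = layout$direction,
                            signature = signature_model(), force_floor = 22) {
  qual <- clusters[clusters$max_force >= force_floor, , drop = FALSE]
  feats <- list(max_force_c1 = NA_real_, max_force_c2 = NA_real_,
                width_c1 = NA_real_, width_c2 = NA_real_,
                intercluster_distance = NA_real_)
  if (!nrow(qual)) {
    return(structure(list(present = FALSE, called_dyad = NA_real_,
                          called_dyad_template = NA_real_,
                          called_dyad_rel = NA_real_, features = feats),
                     class = "nucleosome_call"))
  }
  qual <- qual[order(qual$start), , drop = FALSE]
  dyad_u <- qual$centroid[1] - signature$nuc_cluster1_offset
  L <- layout$template_len
  dyad_t <- unzip_to_template(dyad_u, L, direction)
  if (nrow(qual) >= 2) {
    feats <- list(max_force_c1 = qual$max_force[1],
                  max_force_c2 = qual$max_force[2],
                  width_c1 = qual$width[1], width_c2 = qual$width[2],
                  intercluster_distance = qual$centroid[2] - qual$centroid[1])
  } else {
    feats$max_force_c1 <- qual$max_force[1]
    feats$width_c1 <- qual$width[1]
  }
  structure(
    list(present = TRUE, called_dyad = dyad_u,
         called_dyad_template = dyad_t,
         called_dyad_rel = template_to_rel(dyad_t, layout$dyad0),
         features = feats),
    class = "nucleosome_call"
  )
}

#' Dwell-time histogram along the template
#'
#' Aggregates the fork residence time per position bin from a trace that
#' carries its time series. Under the loading-rate clamp the fork dwells
#' longest where the disruption threshold rises fastest, so the histogram
#' highlights the strongest interaction of each signature region.
#'
#' @param trace An `unzip_trace` with `time_s`.
#' @param bin_bp Bin width, bp.
#' @return A data frame with `bin_start`, `bin_mid`, `dwell_s`.
#' @export
compute_dwell_histogram <- function(trace, bin_bp = 1) {
  stopifnot(inherits(trace, "unzip_trace"))
  if (is.null(trace$time_s)) {
    stop("trace carries no time series; simulate with `include_time = TRUE`",
         call. = FALSE)
  }
  dwell <- diff(c(0, trace$time_s))
  bin <- floor(trace$positions / bin_bp) * bin_bp
  agg <- tapply(dwell, bin, sum)
  data.frame(bin_start = as.numeric(names(agg)),
             bin_mid = as.numeric(names(agg)) + bin_bp / 2,
             dwell_s = as.numeric(agg), row.names = NULL)
}

#' @export
print.tf_call <- function(x, ...) {
  if (isTRUE(x$masked)) {
    cat("<tf_call> masked by nucleosome signature\n")
  } else if (isTRUE(x$bound)) {
    cat(sprintf("<tf_call> bound; center = %.1f bp (rel. dyad %.1f), peak %.1f pN\n",
                x$called_center, x$called_center_rel, x$peak_force))
  } else {
    cat("<tf_call> unbound\n")
  }
  invisible(x)
}

#' @export
print.nucleosome_call <- function(x, ...) {
  if (isTRUE(x$present)) {
    cat(sprintf("<nucleosome_call> present; dyad = %.1f bp (rel. dyad %.1f)\n",
                x$called_dyad, x$called_dyad_rel))
  } else {
    cat("<nucleosome_call> absent\n")
  }
  invisible(x)
}
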