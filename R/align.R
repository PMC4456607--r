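#' Select protein-free alignment windows
#'
#' Chooses the regions of a trace used for cross-correlation alignment
#' against the naked-DNA reference: the stretch of naked DNA immediately
#' before the first expected protein signature and (for internal
#' nucleosomes) immediately after the last one. For an end-positioned
#' nucleosome only the pre-signature window exists. Windows stay clear of
#' the template ends by `edge_margin` bp so that any distortion within the
#' declared bounds keeps them inside the recorded trace.
#'
#' When a `trace` is supplied, regions where the observed force exceeds
#' `force_cap` (protein disruptions, wherever they sit after remodeling) are
#' additionally excluded, padded by `pad` bp to absorb any distortion within
#' the declared bounds.
#'
#' @param layout A [build_template()] layout.
#' @param direction Unzipping direction; defaults to the layout's.
#' @param signature A [signature_model()] (expected signature geometry).
#' @param trace Optional observed `unzip_trace` whose high-force regions are
#'   excluded from the windows.
#' @param guard Clearance between a window and a signature region, bp.
#' @param min_len Minimum usable window length, bp.
#' @param max_len Maximum window length, bp (the portion adjacent to the
#'   signatures is kept).
#' @param edge_margin Clearance from the template ends, bp.
#' @param force_cap Force above which observed trace samples mark an
#'   excluded protein region, pN.
#' @param pad Padding around observed high-force regions, bp.
#' @return A list of numeric `c(start, end)` windows in unzipping
#'   coordinates. Errors if no window of at least `min_len` bp exists.
#' @export
select_alignment_regions <- function(layout, direction = layout$direction,
                                     signature = signature_model(),
                                     trace = NULL,
                                     guard = 10, min_len = 50, max_len = 300,
                                     edge_margin = 30, force_cap = 22,
                                     pad = 30) {
  L <- layout$template_len
  co <- layout_unzip_coords(layout, direction, signature)

  spans <- list()
  if (!is.na(co$tf_peak_u)) {
    spans <- c(spans, list(c(co$tf_peak_u - signature$tf_half_width - 5,
                             co$tf_peak_u + signature$tf_half_width + 10)))
  }
  spans <- c(spans, list(c(co$c1_u - signature$cluster_half_width - 5,
                           co$c2_u + signature$cluster_half_width + 15)))
  spans <- spans[!vapply(spans, function(s) any(is.na(s)), logical(1))]
  if (!length(spans)) stop("layout defines no signature regions", call. = FALSE)
  lo <- min(vapply(spans, `[`, numeric(1), 1))
  hi <- max(vapply(spans, `[`, numeric(1), 2))

  windows <- list()
  pre <- c(edge_margin, lo - guard)
  if (diff(pre) >= min_len) {
    pre[1] <- max(pre[1], pre[2] - max_len)
    windows <- c(windows, list(pre))
  }
  post <- c(hi + guard, (L - 1) - edge_margin)
  if (diff(post) >= min_len) {
    post[2] <- min(post[2], post[1] + max_len)
    windows <- c(windows, list(post))
  }
  if (!is.null(trace)) {
    hot <- trace$positions[trace$forces > force_cap]
    if (length(hot)) {
      breaks <- c(0, which(diff(hot) > 2), length(hot))
      bad <- lapply(seq_len(length(breaks) - 1), function(i) {
        c(hot[breaks[i] + 1] - pad, hot[breaks[i + 1]] + pad)
      })
      windows <- subtract_intervals(windows, bad, min_len)
    }
  }
  if (!length(windows)) {
    stop("no protein-free window of sufficient length is available",
         call. = FALSE)
  }
  windows
}

# remove `bad` intervals from `windows`, keeping pieces of at least min_len
subtract_intervals <- function(windows, bad, min_len) {
  for (b in bad) {
    out <- list()
    for (w in windows) {
      if (b[2] <= w[1] || b[1] >= w[2]) {
        out <- c(out, list(w))
      } else {
        if (b[1] - w[1] >= min_len) out <- c(out, list(c(w[1], b[1])))
        if (w[2] - b[2] >= min_len) out <- c(out, list(c(b[2], w[2])))
      }
    }
    windows <- out
  }
  windows
}

#' Fit the additive shift and multiplicative stretch of a trace
#'
#' Aligns a measured trace to the naked-DNA reference of the same template by
#' maximizing the normalized cross-correlation of forces over the supplied
#' protein-free windows. The search is an exhaustive grid over stretch
#' (default step 0.001 within +/-2%) with, at each stretch, a shift scan on a
#' 0.1 bp interpolation grid within +/-10 bp. Forces are z-scored per window
#' and the windows enter the correlation concatenated with equal per-sample
#' weight. Ties are broken toward the smaller |shift|, then the stretch
#' closer to 1, so the result is deterministic.
#'
#' The fitted parameters describe the forward distortion `x_trace =
#' stretch * x_reference + shift`; [apply_alignment()] inverts it.
#'
#' @param trace An `unzip_trace` (possibly distorted).
#' @param reference The naked-DNA `unzip_trace` of the same template.
#' @param windows Alignment windows (reference coordinates); defaults to
#'   [select_alignment_regions()] on the reference's layout.
#' @param shift_bounds,stretch_bounds Search bounds.
#' @param shift_step,stretch_step Grid steps (bp; dimensionless).
#' @return An `alignment_result`: list with `shift_bp`, `stretch`, `score`
#'   (normalized cross-correlation in \[-1, 1\]) and `windows`.
#' @export
fit_shift_stretch <- function(trace, reference, windows = NULL,
                              shift_bounds = c(-10, 10),
                              stretch_bounds = c(0.98, 1.02),
                              shift_step = 0.1, stretch_step = 0.001) {
  stopifnot(inherits(trace, "unzip_trace"), inherits(reference, "unzip_trace"))
  if (is.null(windows)) {
    windows <- select_alignment_regions(reference$meta$template,
                                        reference$meta$direction)
  }

  # fine grid over the trace for fast indexed interpolation (never coarser
  # than 0.1 bp, whatever the shift grid)
  res <- min(shift_step, 0.1)
  xt <- seq(min(trace$positions), max(trace$positions), by = res)
  ft <- stats::approx(trace$positions, trace$forces, xt)$y

  xref <- numeric(0)
  zref <- numeric(0)
  grp <- integer(0)
  for (w in seq_along(windows)) {
    win <- windows[[w]]
    sel <- reference$positions >= win[1] & reference$positions <= win[2]
    if (sum(sel) < 2) next
    fr <- reference$forces[sel]
    s <- stats::sd(fr) * sqrt((sum(sel) - 1) / sum(sel))  # population sd
    if (!is.finite(s) || s == 0) {
      stop("degenerate (constant) alignment window", call. = FALSE)
    }
    xref <- c(xref, reference$positions[sel])
    zref <- c(zref, (fr - mean(fr)) / s)
    grp <- c(grp, rep.int(w, sum(sel)))
  }
  if (!length(xref)) stop("alignment windows contain no samples", call. = FALSE)
  npts <- length(xref)
  gsize <- tabulate(grp)

  stretches <- seq(stretch_bounds[1], stretch_bounds[2], by = stretch_step)
  shifts <- seq(shift_bounds[1], shift_bounds[2], by = shift_step)
  K <- as.integer(round(shifts / res))

  best <- list(score = -Inf, shift = NA_real_, stretch = NA_real_)
  for (s in stretches) {
    base_idx <- as.integer(round((s * xref - xt[1]) / res)) + 1L
    idx <- outer(base_idx, K, `+`)
    ok <- idx >= 1L & idx <= length(ft)
    valid_col <- colSums(ok) == npts
    if (!any(valid_col)) next
    idx[!ok] <- 1L
    M <- matrix(ft[idx], nrow = npts)

    # per-window z-scoring of the trace samples, per shift column
    score <- numeric(ncol(M))
    for (w in unique(grp)) {
      rows <- grp == w
      mw <- colMeans(M[rows, , drop = FALSE])
      m2 <- colMeans(M[rows, , drop = FALSE]^2)
      sdw <- sqrt(pmax(m2 - mw^2, 0))
      cw <- (colMeans(M[rows, , drop = FALSE] * zref[rows]))
      contrib <- ifelse(sdw > 0, cw / sdw, 0)
      score <- score + gsize[w] * contrib
    }
    score <- score / npts
    score[!valid_col] <- -Inf

    for (j in seq_along(shifts)) {
      sc <- score[j]
      if (!is.finite(sc)) next
      better <- sc > best$score + 1e-12 ||
        (abs(sc - best$score) <= 1e-12 &&
           (abs(shifts[j]) < abs(best$shift) - 1e-12 ||
              (abs(abs(shifts[j]) - abs(best$shift)) <= 1e-12 &&
                 abs(s - 1) < abs(best$stretch - 1) - 1e-12)))
      if (better) best <- list(score = sc, shift = shifts[j], stretch = s)
    }
  }
  if (!is.finite(best$score)) {
    stop("alignment failed: no valid (shift, stretch) candidate", call. = FALSE)
  }
  structure(
    list(shift_bp = best$shift, stretch = best$stretch, score = best$score,
         windows = windows),
    class = "alignment_result"
  )
}

#' Apply a fitted alignment to a trace
#'
#' Inverts the fitted distortion (`x -> (x - shift) / stretch`) and, when a
#' reference is supplied, resamples the forces onto the reference position
#' grid by linear interpolation so trace and reference share a common grid
#' for baseline estimation.
#'
#' @param trace An `unzip_trace`.
#' @param result An `alignment_result` (or a list with `shift_bp`,
#'   `stretch`).
#' @param reference Optional reference `unzip_trace` whose grid to resample
#'   onto (positions outside the corrected trace range are dropped).
#' @return The aligned `unzip_trace`.
#' @export
apply_alignment <- function(trace, result, reference = NULL) {
  stopifnot(inherits(trace, "unzip_trace"))
  pos <- (trace$positions - result$shift_bp) / result$stretch
  if (is.null(reference)) {
    trace$positions <- pos
    return(trace)
  }
  keep <- reference$positions >= min(pos) & reference$positions <= max(pos)
  grid <- reference$positions[keep]
  trace$forces <- stats::approx(pos, trace$forces, grid)$y
  if (!is.null(trace$time_s)) {
    trace$time_s <- stats::approx(pos, trace$time_s, grid)$y
  }
  trace$positions <- grid
  trace$meta$aligned <- TRUE
  trace
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> shift = %.2f bp, stretch = %.4f, score = %.4f (%d windows)\n",
              x$shift_bp, x$stretch, x$score, length(x$windows)))
  invisible(x)
}
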