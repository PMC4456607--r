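#' Construct a DNA template layout
#'
#' Describes the geometry of one unzipping template: total length, the initial
#' dyad of the nucleosome positioning element, the transcription-factor (TF)
#' consensus center, and the unzipping direction. Positions are 0-based
#' template coordinates with the TF side at low values; dyad-relative display
#' coordinates place the origin at the initial dyad (`x - dyad0`).
#'
#' For an internal nucleosome the dyad sits at the template midpoint; with
#' `end_positioned = TRUE` the dyad is placed 73 bp from the far template end
#' so the histone footprint touches the end. The TF consensus center is then
#' placed so that the gap between the TF-protected region (center +/-
#' `tf_footprint`) and the nucleosome footprint edge (dyad - 73) equals
#' `separation_bp`.
#'
#' @param length_bp Template length in bp, between 600 and 1200.
#' @param separation_bp Gap in bp between the TF site edge and the nucleosome
#'   footprint edge. The study geometries use 10, 11, 24, 50 and 75 bp, but
#'   any positive integer compatible with the template bounds is accepted.
#' @param direction `"from_tf_side"` (fork meets the TF first) or
#'   `"from_nucleosome_side"`.
#' @param end_positioned Logical; place the nucleosome at the template end.
#' @param tf_footprint Half-width in bp of the TF-protected region.
#' @param tf_present Logical; `FALSE` builds a template without a TF site
#'   (naked-DNA / no-barrier controls).
#' @return An object of class `template_layout` with fields `template_len`,
#'   `dyad0`, `tf_center` (`NA` if absent), `tf_footprint`, `separation`,
#'   `direction`, `end_positioned`.
#' @examples
#' build_template(800, 10, "from_tf_side")
#' build_template(800, 75, "from_tf_side", end_positioned = TRUE)
#' @export
build_template <- function(length_bp, separation_bp,
                           direction = c("from_tf_side", "from_nucleosome_side"),
                           end_positioned = FALSE, tf_footprint = 10,
                           tf_present = TRUE) {
  direction <- match.arg(direction)
  if (!is.numeric(length_bp) || length_bp < 600 || length_bp > 1200) {
    stop("`length_bp` must lie in [600, 1200]", call. = FALSE)
  }
  length_bp <- as.integer(round(length_bp))
  if (tf_present && (!is.numeric(separation_bp) || separation_bp < 1)) {
    stop("`separation_bp` must be a positive integer", call. = FALSE)
  }
  separation_bp <- as.integer(round(separation_bp))

  dyad0 <- if (end_positioned) length_bp - 1L - 73L else as.integer(round(length_bp / 2))
  tf_center <- if (tf_present) {
    dyad0 - 73L - separation_bp - as.integer(tf_footprint)
  } else {
    NA_integer_
  }

  # nucleosome footprint must fit the template
  if (dyad0 - 73L < 0L || dyad0 + 73L > length_bp - 1L) {
    stop("nucleosome footprint (dyad +/- 73 bp) exceeds template bounds",
         call. = FALSE)
  }
  if (tf_present && (tf_center - tf_footprint < 0L || tf_center + tf_footprint > length_bp - 1L)) {
    stop("TF footprint exceeds template bounds for this separation",
         call. = FALSE)
  }

  structure(
    list(
      template_len = length_bp,
      dyad0 = dyad0,
      tf_center = tf_center,
      tf_footprint = as.integer(tf_footprint),
      separation = separation_bp,
      direction = direction,
      end_positioned = isTRUE(end_positioned)
    ),
    class = "template_layout"
  )
}

#' Layout positions in unzipping coordinates
#'
#' Converts the fixed template geometry into the coordinate frame of a trace
#' unzipped in `direction`: the expected TF consensus center, the expected TF
#' force peak (8 bp before the center along the unzipping direction), the
#' dyad, and the expected first/second nucleosome force-cluster centers
#' (dyad - 43 bp and dyad + 5 bp along the unzipping direction).
#'
#' @param layout A `template_layout`.
#' @param direction Unzipping direction; defaults to the layout's.
#' @param signature A [signature_model()] supplying the signature offsets.
#' @return A list with `tf_center_u`, `tf_peak_u`, `dyad_u`, `c1_u`, `c2_u`.
#' @export
layout_unzip_coords <- function(layout, direction = layout$direction,
                                signature = signature_model()) {
  L <- layout$template_len
  dyad_u <- template_to_unzip(layout$dyad0, L, direction)
  tf_u <- if (is.na(layout$tf_center)) NA_real_ else {
    template_to_unzip(layout$tf_center, L, direction)
  }
  list(
    tf_center_u = tf_u,
    tf_peak_u = if (is.na(tf_u)) NA_real_ else tf_u + signature$tf_peak_offset,
    dyad_u = dyad_u,
    c1_u = dyad_u + signature$nuc_cluster1_offset,
    c2_u = dyad_u + signature$nuc_cluster2_offset
  )
}

#' @export
print.template_layout <- function(x, ...) {
  cat(sprintf("<template_layout> %d bp, dyad0 = %d, direction = %s%s\n",
              x$template_len, x$dyad0, x$direction,
              if (x$end_positioned) " (end-positioned nucleosome)" else ""))
  if (!is.na(x$tf_center)) {
    cat(sprintf("  TF center = %d (footprint +/- %d bp), separation = %d bp\n",
                x$tf_center, x$tf_footprint, x$separation))
  } else {
    cat("  no TF site\n")
  }
  invisible(x)
}
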