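#' Write an unzipping trace to a TSV file
#'
#' Plain-text trace format: `#key=value` comment lines carrying the template
#' geometry, direction, truth annotations and seed, followed by a
#' tab-separated table with columns `position_bp`, `force_pN` and, when
#' present, `time_s`.
#'
#' @param trace An `unzip_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "unzip_trace"))
  m <- trace$meta
  lay <- m$template
  hdr <- c(
    sprintf("#template_len=%d", lay$template_len),
    sprintf("#dyad0=%d", lay$dyad0),
    sprintf("#tf_center=%s", if (is.na(lay$tf_center)) "NA" else lay$tf_center),
    sprintf("#tf_footprint=%d", lay$tf_footprint),
    sprintf("#separation=%d", lay$separation),
    sprintf("#direction=%s", lay$direction),
    sprintf("#end_positioned=%s", lay$end_positioned),
    sprintf("#tf_bound=%s", m$tf_bound),
    sprintf("#nuc_present=%s", m$nuc_present),
    sprintf("#dyad_template=%s", format_num(m$dyad_template)),
    sprintf("#shift_bp=%s", format_num(m$shift_bp)),
    sprintf("#stretch=%s", format_num(m$stretch)),
    sprintf("#seed=%s", m$seed %||% "NA")
  )
  cols <- c("position_bp", "force_pN")
  body <- cbind(sprintf("%.6f", trace$positions), sprintf("%.6f", trace$forces))
  if (!is.null(trace$time_s)) {
    cols <- c(cols, "time_s")
    body <- cbind(body, sprintf("%.8f", trace$time_s))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(cols, collapse = "\t"), con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

format_num <- function(x) {
  if (is.null(x) || length(x) == 0 || is.na(x)) "NA" else format(x, digits = 12)
}

#' Read an unzipping trace from a TSV file
#'
#' Inverse of [write_trace()]: parses `#key=value` metadata into the trace's
#' `meta` (rebuilding the `template_layout`) and the data table into
#' positions, forces and optional times.
#'
#' @param path File path.
#' @return An `unzip_trace`.
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  kv <- strsplit(sub("^#", "", lines[is_meta]), "=", fixed = TRUE)
  meta_raw <- stats::setNames(
    lapply(kv, function(p) paste(p[-1], collapse = "=")),
    vapply(kv, `[`, character(1), 1)
  )
  num <- function(k) {
    v <- meta_raw[[k]]
    if (is.null(v) || v == "NA") NA_real_ else as.numeric(v)
  }
  lgl <- function(k) identical(meta_raw[[k]], "TRUE")

  body <- utils::read.delim(text = lines[!is_meta], sep = "\t",
                            check.names = FALSE)
  if (!all(c("position_bp", "force_pN") %in% names(body))) {
    stop(sprintf("'%s' is not a trace file (missing columns)", path),
         call. = FALSE)
  }

  layout <- build_template(
    length_bp = num("template_len"),
    separation_bp = if (is.na(num("separation"))) 10 else num("separation"),
    direction = meta_raw[["direction"]] %||% "from_tf_side",
    end_positioned = lgl("end_positioned"),
    tf_footprint = if (is.na(num("tf_footprint"))) 10 else num("tf_footprint"),
    tf_present = !is.na(num("tf_center"))
  )
  trace <- list(
    positions = body$position_bp,
    forces = body$force_pN,
    time_s = if ("time_s" %in% names(body)) body$time_s else NULL,
    meta = list(
      template = layout, direction = layout$direction,
      seed = if (identical(meta_raw[["seed"]], "NA")) NULL else
        as.numeric(meta_raw[["seed"]]),
      tf_bound = lgl("tf_bound"), nuc_present = lgl("nuc_present"),
      dyad_template = num("dyad_template"),
      shift_bp = if (is.na(num("shift_bp"))) 0 else num("shift_bp"),
      stretch = if (is.na(num("stretch"))) 1 else num("stretch"),
      synthetic = TRUE
    )
  )
  class(trace) <- "unzip_trace"
  trace
}

#' Write an ensemble manifest
#'
#' One CSV row per molecule: identifiers, truth fields and trace file paths.
#'
#' @param molecules The `molecules` data frame of an ensemble (with an added
#'   `file` column).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(molecules, path) {
  utils::write.csv(molecules, path, row.names = FALSE)
  invisible(path)
}

#' Read an ensemble manifest
#' @param path Manifest CSV path.
#' @return A data frame.
#' @export
read_manifest <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
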