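#' Simulate a remodeling experiment to disk
#'
#' Generates a naked-DNA reference trace and an ensemble of per-molecule
#' traces for the configured template, remodeler and duration, applies a
#' random instrumental shift/stretch to each molecule (within the declared
#' bounds) when `ensemble$distort` is set, and writes TSV traces, the
#' reference, a manifest CSV and the configuration to `out_dir`. The run is
#' deterministic per (config, seed).
#'
#' @param config A [default_config()]-style `run_config`.
#' @param out_dir Output directory (created if missing).
#' @param seed Overrides `config$seed` when given.
#' @return Invisibly, a list with `manifest` (data frame), `layout` and the
#'   paths written.
#' @export
run_simulate <- function(config = default_config(), out_dir,
                         seed = NULL) {
  seed <- seed %||% config$seed
  config$seed <- seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory", call. = FALSE)

  layout <- config_layout(config)
  sig <- config_signature(config)
  instr <- config_instrument(config)
  rem <- config_remodeler(config)

  ens <- simulate_remodeling_ensemble(
    layout, rem, n = config$ensemble$n, duration = config$ensemble$duration,
    seed = seed, p_tf_bound = config$ensemble$p_tf_bound,
    render_traces = TRUE, signature = sig, instrument = instr
  )

  ref <- simulate_trace(layout, tf_bound = FALSE, nuc_present = FALSE,
                        signature = sig, instrument = instr,
                        seed = seed + 1L)
  ref_path <- file.path(out_dir, "reference.tsv")
  write_trace(ref, ref_path)

  with_seed(seed + 2L, {
    n <- nrow(ens$molecules)
    shifts <- if (isTRUE(config$ensemble$distort)) {
      stats::runif(n, -instr$shift_bound, instr$shift_bound)
    } else rep(0, n)
    stretches <- if (isTRUE(config$ensemble$distort)) {
      stats::runif(n, 1 - 0.95 * instr$stretch_bound,
                   1 + 0.95 * instr$stretch_bound)
    } else rep(1, n)

    files <- character(n)
    for (m in seq_len(n)) {
      tr <- distort_trace(ens$traces[[m]], shifts[m], stretches[m], instr)
      files[m] <- file.path(out_dir, sprintf("trace_%03d.tsv", m))
      write_trace(tr, files[m])
    }

    manifest <- cbind(ens$molecules,
                      file = basename(files),
                      shift_bp = shifts, stretch = stretches)
    write_manifest(manifest, file.path(out_dir, "manifest.csv"))
    write_config(config, file.path(out_dir, "config.yaml"))

    invisible(list(manifest = manifest, layout = layout,
                   reference = ref_path, out_dir = out_dir))
  })
}

#' Analyze a simulated (or recorded) experiment directory
#'
#' Runs align - call - summarize over every trace in the manifest: each
#' trace is aligned to the naked-DNA reference by cross-correlation,
#' signatures are detected against the reference baseline, TF and
#' nucleosome positions are called with the 8 bp / 43 bp conventions, and
#' population summaries (position histogram, double-Gaussian decomposition,
#' Poisson event fractions, precision/accuracy against manifest truth) are
#' computed. Per-trace failures are logged as warnings and skipped; the run
#' continues.
#'
#' @param out_dir Directory produced by [run_simulate()] (must contain
#'   `manifest.csv`, `reference.tsv`, `config.yaml`).
#' @param config Optional `run_config` overriding the one on disk.
#' @return Invisibly, a list with `calls` (data frame, one row per
#'   molecule) and `summary` (named list). Writes `calls.csv` and
#'   `summary.json` into `out_dir`.
#' @export
run_analyze <- function(out_dir, config = NULL) {
  manifest_path <- file.path(out_dir, "manifest.csv")
  if (!file.exists(manifest_path)) stop("manifest.csv not found", call. = FALSE)
  config <- config %||% read_config(file.path(out_dir, "config.yaml"))
  ref_path <- file.path(out_dir, "reference.tsv")
  if (!file.exists(ref_path)) {
    stop("reference.tsv not found: analysis needs the naked-DNA reference",
         call. = FALSE)
  }

  layout <- config_layout(config)
  sig <- config_signature(config)
  a <- config$analysis
  manifest <- read_manifest(manifest_path)
  reference <- read_trace(ref_path)

  if (nrow(manifest) == 0) {
    warning("empty manifest: writing empty outputs")
    calls <- data.frame()
    utils::write.csv(calls, file.path(out_dir, "calls.csv"), row.names = FALSE)
    summary <- list(n_molecules = 0)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(list(calls = calls, summary = summary)))
  }

  rows <- vector("list", nrow(manifest))
  for (m in seq_len(nrow(manifest))) {
    rows[[m]] <- tryCatch({
      tr <- read_trace(file.path(out_dir, manifest$file[m]))
      windows <- select_alignment_regions(layout, signature = sig, trace = tr,
                                          force_cap = a$nuc_force_floor)
      al <- fit_shift_stretch(tr, reference, windows)
      tra <- apply_alignment(tr, al, reference)
      bl <- estimate_baseline(tra, reference, k = a$k,
                              smooth_bp = a$baseline_smooth_bp,
                              min_prominence = a$min_prominence)
      ev <- detect_events(tra, bl, smooth_bp = a$smooth_bp)
      cl <- segment_clusters(ev, gap_bp = a$gap_bp, trace = tra,
                             baseline = bl, smooth_bp = a$smooth_bp)
      tf <- call_tf(ev, cl, layout, signature = sig,
                    window_bp = a$tf_window_bp,
                    nuc_force_floor = a$nuc_force_floor)
      nuc <- call_nucleosome(cl, layout, signature = sig,
                             force_floor = a$nuc_force_floor)
      data.frame(
        id = manifest$id[m], file = manifest$file[m],
        align_shift = al$shift_bp, align_stretch = al$stretch,
        align_score = al$score,
        tf_bound = tf$bound, tf_masked = tf$masked,
        tf_center_template = tf$called_center_template,
        tf_peak_force = tf$peak_force,
        nuc_present = nuc$present,
        dyad_template = nuc$called_dyad_template,
        dyad_rel = nuc$called_dyad_rel,
        max_force_c1 = nuc$features$max_force_c1,
        max_force_c2 = nuc$features$max_force_c2,
        width_c1 = nuc$features$width_c1,
        width_c2 = nuc$features$width_c2,
        intercluster_distance = nuc$features$intercluster_distance
      )
    }, error = function(e) {
      warning(sprintf("trace %s failed: %s", manifest$file[m],
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
  }
  calls <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  utils::write.csv(calls, file.path(out_dir, "calls.csv"), row.names = FALSE)

  summary <- summarize_calls(calls, manifest, layout, config)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(calls = calls, summary = summary))
}

summarize_calls <- function(calls, manifest, layout, config) {
  a <- config$analysis
  out <- list(
    n_molecules = nrow(calls),
    n_tf_bound = sum(calls$tf_bound %in% TRUE),
    n_tf_masked = sum(calls$tf_masked %in% TRUE),
    n_nuc_present = sum(calls$nuc_present %in% TRUE),
    mean_align_score = mean(calls$align_score)
  )

  dyads <- calls$dyad_rel[calls$nuc_present %in% TRUE]
  out$dyad_histogram <- position_histogram(dyads, a$histogram_bin_bp)

  truth <- manifest[match(calls$id, manifest$id), ]
  moved <- abs(truth$dyad_final - truth$dyad_initial) > a$remodel_threshold_bp
  unmoved_dyads <- calls$dyad_template[!moved & calls$nuc_present %in% TRUE]
  if (sum(is.finite(unmoved_dyads)) >= 2) {
    pa <- precision_accuracy(unmoved_dyads, layout$dyad0)
    out$dyad_accuracy_bp <- pa$bias
    out$dyad_precision_bp <- pa$sd
  }
  err <- calls$dyad_template - truth$dyad_final
  out$dyad_rmse_bp <- sqrt(mean(err[is.finite(err)]^2))

  p0 <- mean(!moved)
  out$frac_unremodeled_truth <- p0
  if (p0 > 0 && p0 < 1) {
    out$poisson <- poisson_event_fractions(p0)
  }

  if (sum(is.finite(dyads)) >= 20 && stats::sd(dyads, na.rm = TRUE) > 0) {
    fit <- tryCatch(fit_double_gaussian(dyads), error = function(e) NULL)
    if (!is.null(fit)) {
      out$mixture <- fit[c("w_unremodeled", "mu1", "sigma1", "mu2", "sigma2",
                           "converged", "degenerate")]
    }
  }
  out
}

#' Render a human-readable analysis report
#'
#' Writes `report.md` (deterministic text tables regenerated byte-identically
#' from the same summary) and figure files (dyad position histogram, mixture
#' overlay when fitted) from a `summary.json` produced by [run_analyze()].
#'
#' @param out_dir Directory containing `summary.json` and `calls.csv`.
#' @return Invisibly, the report path.
#' @export
run_report <- function(out_dir) {
  spath <- file.path(out_dir, "summary.json")
  if (!file.exists(spath)) stop("summary.json not found", call. = FALSE)
  s <- jsonlite::read_json(spath, simplifyVector = TRUE)

  lines <- c(
    "# Unzipping analysis report", "",
    sprintf("Molecules analyzed: %d", s$n_molecules %||% 0)
  )
  if ((s$n_molecules %||% 0) > 0) {
    lines <- c(lines,
      sprintf("TF bound: %d (masked: %d)", s$n_tf_bound, s$n_tf_masked),
      sprintf("Nucleosome present: %d", s$n_nuc_present),
      sprintf("Mean alignment score: %.4f", s$mean_align_score), "")
    if (!is.null(s$dyad_precision_bp)) {
      lines <- c(lines,
        sprintf("Dyad accuracy (bias): %.2f bp", s$dyad_accuracy_bp),
        sprintf("Dyad precision (sd): %.2f bp", s$dyad_precision_bp), "")
    }
    if (!is.null(s$poisson)) {
      lines <- c(lines, "## Remodeling event statistics", "",
        sprintf("Unremodeled fraction p0 = %.3f, lambda = %.3f", s$poisson$p0,
                s$poisson$lambda),
        sprintf("Of remodeled molecules: %.1f%% once, %.1f%% more than once",
                100 * s$poisson$frac_once, 100 * s$poisson$frac_multi), "")
    }
    if (!is.null(s$mixture)) {
      lines <- c(lines, "## Double-Gaussian decomposition", "",
        sprintf("Narrow (unremodeled) weight: %.1f%%",
                100 * s$mixture$w_unremodeled),
        sprintf("Narrow: N(%.2f, %.2f) bp; broad: N(%.2f, %.2f) bp",
                s$mixture$mu1, s$mixture$sigma1, s$mixture$mu2,
                s$mixture$sigma2), "")
    }
  }
  rpath <- file.path(out_dir, "report.md")
  writeLines(lines, rpath)

  h <- s$dyad_histogram
  if (!is.null(h) && length(h$bin_mid) > 0) {
    grDevices::png(file.path(out_dir, "dyad_histogram.png"),
                   width = 800, height = 500)
    graphics::barplot(h$count, names.arg = h$bin_mid,
                      xlab = "dyad position (bp from initial dyad)",
                      ylab = "molecules", col = "grey70", border = NA)
    if (!is.null(s$mixture)) {
      xx <- seq(min(h$bin_mid), max(h$bin_mid), length.out = 200)
      bin <- if (length(h$bin_mid) > 1) diff(h$bin_mid[1:2]) else 5
      yy <- s$n_nuc_present * bin *
        (s$mixture$w_unremodeled * stats::dnorm(xx, s$mixture$mu1, s$mixture$sigma1) +
           (1 - s$mixture$w_unremodeled) * stats::dnorm(xx, s$mixture$mu2, s$mixture$sigma2))
      sc <- length(h$bin_mid) / diff(range(h$bin_mid))
      graphics::lines((xx - min(h$bin_mid)) * sc * 1.2 + 0.7, yy,
                      col = "red", lwd = 2)
    }
    grDevices::dev.off()
  }
  invisible(rpath)
}
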