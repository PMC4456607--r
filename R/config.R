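#' Default run configuration
#'
#' Nested configuration driving the pipeline commands: seed, template
#' geometry, signature/instrument/remodeler parameter blocks, ensemble size
#' and analysis thresholds. Every stochastic pipeline operation consumes the
#' run seed, and a configuration round-trips unchanged through the YAML
#' serialization used by [write_config()] / [read_config()].
#'
#' @return A nested list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    template = list(length_bp = 800L, separation_bp = 10L,
                    direction = "from_tf_side", end_positioned = FALSE,
                    tf_footprint = 10L),
    signature = list(baseline_mean = 15, baseline_sd = 1.5,
                     baseline_corr_bp = 3, baseline_seed = 20150605,
                     tf_peak_force_min = 18, tf_peak_force_max = 20,
                     tf_peak_offset = -8, tf_half_width = 10,
                     nuc_cluster1_offset = -43, nuc_cluster2_offset = 5,
                     cluster_half_width = 20,
                     cluster_peak_force_min = 25, cluster_peak_force_max = 35,
                     decay_bp = 5),
    instrument = list(ramp_rate = 15, sample_rate = 12000,
                      output_bandwidth = 60, force_noise_sd = 0.15,
                      fork_velocity = 300, relax_bp = 5,
                      shift_bound = 10, stretch_bound = 0.02),
    remodeler = list(kind = "none", lambda_short = -log(0.55),
                     lambda_long = 8, step_sd = 60, isw1a_center_sd = 5,
                     isw1a_pull = 0.3, swisnf_asymmetry = 0.85,
                     evict_on_overlap = TRUE),
    ensemble = list(n = 20L, duration = "short", p_tf_bound = 0.95,
                    distort = TRUE),
    analysis = list(k = 3, baseline_smooth_bp = 5, smooth_bp = 3,
                    min_prominence = 1, gap_bp = 15, nuc_force_floor = 22,
                    tf_window_bp = 30, remodel_threshold_bp = 2,
                    histogram_bin_bp = 5)
  ), class = "run_config")
}

#' Preset configurations for the study geometries
#'
#' Named presets covering the experiment layouts analysed in this package:
#' a 10 bp TF-to-nucleosome separation on an 800 bp internal-nucleosome
#' template (single-round directionality, both unzipping directions), the
#' end-positioned templates with 24/50/75 bp separations (barrier-centering,
#' long ISW1a reactions), and the ~1200 bp centered-nucleosome template with
#' 11 bp separation (multi-round SWI/SNF eviction).
#'
#' @param name One of `"internal_sep10"`, `"internal_sep10_rev"`,
#'   `"end_sep24"`, `"end_sep50"`, `"end_sep75"`, `"long_sep11"`.
#' @return A `run_config`.
#' @export
preset_config <- function(name = c("internal_sep10", "internal_sep10_rev",
                                   "end_sep24", "end_sep50", "end_sep75",
                                   "long_sep11")) {
  name <- match.arg(name)
  cfg <- default_config()
  if (name == "internal_sep10") {
    # defaults
  } else if (name == "internal_sep10_rev") {
    cfg$template$direction <- "from_nucleosome_side"
  } else if (name %in% c("end_sep24", "end_sep50", "end_sep75")) {
    cfg$template$separation_bp <- as.integer(sub("end_sep", "", name))
    cfg$template$end_positioned <- TRUE
    cfg$remodeler$kind <- "isw1a"
    cfg$ensemble$duration <- "long"
  } else if (name == "long_sep11") {
    cfg$template$length_bp <- 1200L
    cfg$template$separation_bp <- 11L
    cfg$remodeler$kind <- "swisnf"
    cfg$ensemble$duration <- "long"
  }
  cfg
}

#' Write a configuration to YAML
#' @param config A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' Read a configuration from YAML
#' @param path YAML path.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  structure(yaml::read_yaml(path), class = "run_config")
}

# Constructors from config blocks.
config_layout <- function(config) {
  t <- config$template
  build_template(t$length_bp, t$separation_bp, t$direction,
                 end_positioned = isTRUE(t$end_positioned),
                 tf_footprint = t$tf_footprint %||% 10)
}

config_signature <- function(config) {
  s <- config$signature
  signature_model(
    baseline_mean = s$baseline_mean, baseline_sd = s$baseline_sd,
    baseline_corr_bp = s$baseline_corr_bp, baseline_seed = s$baseline_seed,
    tf_peak_force_range = c(s$tf_peak_force_min, s$tf_peak_force_max),
    tf_peak_offset = s$tf_peak_offset, tf_half_width = s$tf_half_width,
    nuc_cluster1_offset = s$nuc_cluster1_offset,
    nuc_cluster2_offset = s$nuc_cluster2_offset,
    cluster_half_width = s$cluster_half_width,
    cluster_peak_force_range = c(s$cluster_peak_force_min,
                                 s$cluster_peak_force_max),
    decay_bp = s$decay_bp
  )
}

config_instrument <- function(config) {
  i <- config$instrument
  instrument_model(
    ramp_rate = i$ramp_rate, sample_rate = i$sample_rate,
    output_bandwidth = i$output_bandwidth, force_noise_sd = i$force_noise_sd,
    fork_velocity = i$fork_velocity, relax_bp = i$relax_bp,
    shift_bound = i$shift_bound, stretch_bound = i$stretch_bound
  )
}

config_remodeler <- function(config) {
  r <- config$remodeler
  remodeler_model(
    kind = r$kind, lambda_short = r$lambda_short, lambda_long = r$lambda_long,
    step_sd = r$step_sd, isw1a_center_sd = r$isw1a_center_sd,
    isw1a_pull = r$isw1a_pull, swisnf_asymmetry = r$swisnf_asymmetry,
    evict_on_overlap = isTRUE(r$evict_on_overlap)
  )
}
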