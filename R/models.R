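#' Force-signature model
#'
#' Parameters of the protein force signatures painted onto the naked-DNA
#' baseline. Offsets are signed displacements in unzipping coordinates
#' (positive = further along the unzipping direction): the TF disruption peak
#' sits 8 bp before the consensus center (`tf_peak_offset = -8`) and the
#' first nucleosome force cluster is centered 43 bp before the dyad
#' (`nuc_cluster1_offset = -43`), so the standard calling conventions (shift
#' the peak by +8 bp, shift the first-cluster centroid by +43 bp along the
#' unzipping direction) recover the true positions exactly on noiseless
#' traces.
#'
#' Each signature raises the per-bp disruption threshold by a two-sided
#' exponential kernel `A * exp(-|x - c| / decay_bp)` truncated at the
#' half-width. The kernel decay equals the post-disruption force relaxation
#' constant by default, which makes the recorded noiseless force profile
#' exactly symmetric about the signature center (ascending side follows the
#' threshold, descending side follows the relaxation, both with the same bp
#' constant).
#'
#' @param baseline_mean Naked-DNA unzipping force, pN.
#' @param baseline_sd SD of the smoothed bp-to-bp baseline variation, pN
#'   (the stochastic surrogate for sequence dependence). 0 gives a flat
#'   baseline.
#' @param baseline_corr_bp Correlation length of the baseline variation, bp.
#' @param baseline_seed Seed of the per-template baseline profile; all traces
#'   of one template (including its naked reference) share it.
#' @param tf_peak_force_range Disruption-force draw range for the TF peak, pN.
#' @param tf_peak_offset Signed TF peak offset from the consensus center, bp.
#' @param tf_half_width Truncation half-width of the TF signature kernel, bp.
#' @param nuc_cluster1_offset,nuc_cluster2_offset Signed cluster-center
#'   offsets from the dyad, bp.
#' @param cluster_half_width Truncation half-width of each nucleosome
#'   cluster kernel, bp.
#' @param cluster_peak_force_range Disruption-force draw range for the
#'   nucleosome clusters, pN.
#' @param decay_bp Exponential decay constant of the signature kernels, bp.
#' @return A list of class `signature_model`.
#' @export
signature_model <- function(baseline_mean = 15, baseline_sd = 1.5,
                            baseline_corr_bp = 3, baseline_seed = 20150605,
                            tf_peak_force_range = c(18, 20),
                            tf_peak_offset = -8, tf_half_width = 10,
                            nuc_cluster1_offset = -43, nuc_cluster2_offset = 5,
                            cluster_half_width = 20,
                            cluster_peak_force_range = c(25, 35),
                            decay_bp = 5) {
  if (min(tf_peak_force_range) <= baseline_mean) {
    stop("TF peak forces must exceed the baseline mean", call. = FALSE)
  }
  if (min(cluster_peak_force_range) <= max(tf_peak_force_range)) {
    stop("nucleosome cluster peak forces must exceed TF peak forces",
         call. = FALSE)
  }
  if (baseline_sd < 0 || decay_bp <= 0) {
    stop("`baseline_sd` must be >= 0 and `decay_bp` > 0", call. = FALSE)
  }
  structure(
    list(baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         baseline_corr_bp = baseline_corr_bp, baseline_seed = baseline_seed,
         tf_peak_force_range = sort(tf_peak_force_range),
         tf_peak_offset = tf_peak_offset, tf_half_width = tf_half_width,
         nuc_cluster1_offset = nuc_cluster1_offset,
         nuc_cluster2_offset = nuc_cluster2_offset,
         cluster_half_width = cluster_half_width,
         cluster_peak_force_range = sort(cluster_peak_force_range),
         decay_bp = decay_bp),
    class = "signature_model"
  )
}

#' Instrument model
#'
#' Acquisition and distortion parameters of the optical-trap unzipping
#' instrument: the loading-rate clamp ramps force linearly at `ramp_rate`
#' whenever the fork stalls; data are digitized at `sample_rate` and low-pass
#' filtered to `output_bandwidth`; residual drift and calibration errors
#' appear as a small additive position shift (up to 10 bp) and multiplicative
#' stretch (within 2%), which the alignment stage must cover.
#'
#' @param ramp_rate Force loading rate while stalled, pN/s.
#' @param sample_rate Digitization rate, Hz.
#' @param output_bandwidth Output low-pass bandwidth, Hz.
#' @param force_noise_sd Per-sample measurement noise on the recorded force,
#'   pN.
#' @param fork_velocity Fork progression rate through unhindered DNA, bp/s
#'   (sets the dwell time of non-stalled base pairs).
#' @param relax_bp Post-disruption force relaxation constant, bp: after a
#'   disruption the excess force decays toward the local baseline by a factor
#'   `exp(-1/relax_bp)` per bp advanced, so closely spaced interactions are
#'   met at an elevated initial force.
#' @param shift_bound,stretch_bound Declared distortion bounds (|shift| <=
#'   `shift_bound` bp, |stretch - 1| < `stretch_bound`).
#' @return A list of class `instrument_model`.
#' @export
instrument_model <- function(ramp_rate = 15, sample_rate = 12000,
                             output_bandwidth = 60, force_noise_sd = 0.15,
                             fork_velocity = 300, relax_bp = 5,
                             shift_bound = 10, stretch_bound = 0.02) {
  if (ramp_rate <= 0 || sample_rate <= 0 || output_bandwidth <= 0 ||
      fork_velocity <= 0 || relax_bp <= 0) {
    stop("rates, bandwidths and relaxation constants must be positive",
         call. = FALSE)
  }
  if (force_noise_sd < 0) stop("`force_noise_sd` must be >= 0", call. = FALSE)
  structure(
    list(ramp_rate = ramp_rate, sample_rate = sample_rate,
         output_bandwidth = output_bandwidth, force_noise_sd = force_noise_sd,
         fork_velocity = fork_velocity, relax_bp = relax_bp,
         shift_bound = shift_bound, stretch_bound = stretch_bound),
    class = "instrument_model"
  )
}

#' Remodeler model
#'
#' Phenomenological rules for nucleosome repositioning by a chromatin
#' remodeler. Remodeling events per reaction are Poisson with mean
#' `lambda_short` (brief reactions, mostly zero or one event) or
#' `lambda_long` (long reactions, multiple rounds).
#'
#' `"isw1a"` events draw the new dyad by contraction toward the midpoint of
#' the accessible DNA segment (between the bound-TF footprint edge and the
#' template end): `new = mid + pull * (old - mid) + noise`, with the noise
#' scaled so the stationary spread around the midpoint is `isw1a_center_sd`.
#' A bound TF is an absolute barrier: the footprint never crosses it.
#' `"swisnf"` events displace the dyad by `Normal(0, step_sd)` (the first
#' event biased toward the TF with probability `swisnf_asymmetry`), ignore
#' the TF, and evict it the first time the sliding footprint overlaps the TF
#' footprint. `"none"` fixes `lambda = 0`.
#'
#' @param kind One of `"none"`, `"isw1a"`, `"swisnf"`.
#' @param lambda_short,lambda_long Poisson event means per reaction. The
#'   short default `-log(0.55)` leaves 55% of molecules unremodeled.
#' @param step_sd SWI/SNF per-event displacement SD, bp.
#' @param isw1a_center_sd Stationary spread of ISW1a-remodeled dyads around
#'   the accessible-segment midpoint, bp.
#' @param isw1a_pull Contraction factor per ISW1a event (0 = one-step
#'   centering, 1 = no centering).
#' @param swisnf_asymmetry Probability that the first SWI/SNF event moves the
#'   nucleosome toward the TF.
#' @param evict_on_overlap Logical; SWI/SNF evicts the TF on first footprint
#'   overlap.
#' @return A list of class `remodeler_model`.
#' @export
remodeler_model <- function(kind = c("none", "isw1a", "swisnf"),
                            lambda_short = -log(0.55), lambda_long = 8,
                            step_sd = 60, isw1a_center_sd = 5,
                            isw1a_pull = 0.3, swisnf_asymmetry = 0.85,
                            evict_on_overlap = TRUE) {
  kind <- match.arg(kind)
  if (lambda_short < 0 || lambda_long < 0) {
    stop("Poisson means must be >= 0", call. = FALSE)
  }
  if (isw1a_pull < 0 || isw1a_pull >= 1) {
    stop("`isw1a_pull` must lie in [0, 1)", call. = FALSE)
  }
  if (swisnf_asymmetry < 0 || swisnf_asymmetry > 1) {
    stop("`swisnf_asymmetry` must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(kind = kind, lambda_short = lambda_short, lambda_long = lambda_long,
         step_sd = step_sd, isw1a_center_sd = isw1a_center_sd,
         isw1a_pull = isw1a_pull, swisnf_asymmetry = swisnf_asymmetry,
         evict_on_overlap = isTRUE(evict_on_overlap)),
    class = "remodeler_model"
  )
}
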