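---
title: "Mapping transcription factors and nucleosomes by DNA unzipping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping transcription factors and nucleosomes by DNA unzipping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unzipnuc)
```

## The measurement this package models

Mechanically unzipping a double-stranded DNA molecule converts protein-DNA
interactions into a force signal. A loading-rate clamp raises the force
linearly in time (15 pN/s) whenever the unzipping fork stalls at an
interaction; the force at which the interaction yields — the disruption
force — and the base-pair position at which it occurs identify the bound
protein. Naked DNA unzips at a baseline near 15 pN. A bound transcription
factor (TF; the package's running example is a Gal4 DNA-binding domain on a
single recognition site) produces a single disruption peak of 18-20 pN just
above the baseline; a nucleosome positioned on a 601 element produces two
clusters of much stronger peaks (25-35 pN here) reflecting the two halves of
the histone-DNA contact array.

Two empirical conventions convert signatures to positions, and the whole
analysis hinges on them:

* the TF disruption peak sits **8 bp before** the consensus-sequence center
  along the unzipping direction (the fork stalls at the front edge of the
  footprint), so the called center is the peak position shifted by +8 bp;
* the mean force location of the **first** nucleosome force cluster sits
  **43 bp before** the dyad, so the called dyad is the first-cluster
  force-weighted centroid shifted by +43 bp.

Both offsets are applied along the unzipping direction, so templates can be
read from either end and yield the same positions in template coordinates.
Dyad-relative display coordinates put the origin at the initial dyad.

No raw traces from the motivating experiments are publicly available, so the
package pairs the analysis pipeline with a synthetic generator rich enough
to exercise every stage, and every claim the package makes is a
parameter-recovery statement about that generator — not a re-analysis of
experimental data.

## The trace generator

`simulate_trace()` uses a per-base-pair disruption-threshold model. Each bp
`j` carries a threshold: the naked-DNA baseline profile, raised inside
signature regions. The fork advances while the current force meets the
threshold; otherwise the force ramps at 15 pN/s until disruption. After a
disruption the excess force relaxes toward the baseline by a factor
`exp(-1/relax_bp)` per bp advanced (`relax_bp` = 5 bp), so closely spaced
interactions are met at an elevated initial force — the behaviour that makes
the dwell-time histogram highlight the strongest interaction of a region.

**Baseline surrogate.** Sequence-dependent unzipping thermodynamics is out
of scope; the baseline is a stationary stochastic surrogate: mean 15 pN,
SD 1.5 pN, ~3 bp correlation length, seeded once per template so that every
trace of a template and its naked reference share the same features. That
shared texture is not cosmetic — it is the information the
cross-correlation alignment locks onto, exactly as the sequence-dependent
force landscape is in the real measurement. The amplitude and correlation
length were chosen so that alignment achieves the near-base-pair accuracy
the real technique is known for (see below); both are config keys.

**Signature kernels.** A signature raises the threshold by a two-sided
exponential `A * exp(-|x - c|/5 bp)`, truncated at a half-width (10 bp TF,
20 bp clusters), with `A` anchored so the recorded peak force equals the
drawn disruption force (TF: uniform 18-20 pN; clusters: uniform 25-35 pN).
The kernel decay deliberately equals the relaxation constant: on the rising
side the recorded force follows the threshold, on the falling side it
follows the relaxation, and with equal bp constants the recorded profile is
*exactly symmetric* about the kernel center on noiseless input. That is
what makes the position conventions exact by construction: the TF peak
argmax falls exactly at `tf_center - 8` and the first-cluster force-weighted
centroid exactly at `dyad - 43`. A smooth bump with an asymmetric
relaxation tail cannot deliver that exactness, which is why this shape was
chosen over alternatives.

**Instrument.** Acquisition at ~12 kHz low-passed to 60 Hz is represented by
the reduced one-sample-per-bp force-versus-position record (with per-bp
dwell times kept for the optional time series); per-sample force noise
defaults to 0.15 pN, realistic for 60 Hz-filtered optical-trap data and
consistent with the targeted ±0.2 bp alignment recovery. Instrument drift,
bead-size and linker variation appear as an affine position distortion
(`distort_trace()`): additive shift up to ±10 bp and multiplicative stretch
within ±2%, the declared bounds the alignment search must cover.

## Alignment

`fit_shift_stretch()` aligns a trace to the naked-DNA reference of its
template by maximizing normalized cross-correlation of forces over
protein-free windows (`select_alignment_regions()`): the region immediately
before the first expected signature and, for internal nucleosomes, the
region immediately after the last one; end-positioned nucleosomes leave only
the pre-signature window. When the observed trace is supplied, windows also
exclude any region where the observed force exceeds the nucleosome floor —
necessary after remodeling, when a slid nucleosome can sit inside the
nominal post-signature window.

The search is an exhaustive grid: stretch in steps of 0.001 over ±2%, and at
each stretch a shift scan on a 0.1 bp interpolation grid over ±10 bp.
Windows are z-scored individually and concatenated with equal per-sample
weight; ties break toward the smaller |shift|, then the stretch closer
to 1, so the fit is deterministic. Exhaustive search was preferred over
gradient descent because the correlation surface has local maxima at
feature-repeat distances and the grid is cheap (~8000 candidates,
vectorized). `apply_alignment()` inverts the fitted distortion and resamples
onto the reference grid (linear interpolation). Measured performance at
default settings: worst-case 0.4 bp / 0.001 recovery error over the full
(±10 bp) x (0.98-1.02) distortion box, 0.5 bp at 1 pN force noise.

## Signature calling

`estimate_baseline()` smooths the aligned naked reference (5 bp running
mean) and sets the detection threshold at baseline + max(k x residual SD,
1 pN), k = 3. The 1 pN floor exists because with k alone the expected
number of threshold crossings across a 60 bp search window is not small
enough for the >= 99% bound/unbound specificity the pipeline maintains;
with the floor, detection operates at an effective >5 sigma. Both k and the
floor are config keys.

`detect_events()` finds local maxima of the 3 bp-smoothed force excess with
three-point parabolic sub-bp refinement (exact on symmetric noiseless
peaks). `segment_clusters()` splits events at gaps > 15 bp and computes, per
cluster, the force-weighted centroid of its above-threshold samples — the
default reading of "mean force location within a cluster"; an
event-position-weighted variant is available (`centroid = "events"`).
`call_tf()` searches ±30 bp around the expected site, excludes peaks inside
nucleosome-grade clusters (max force >= 22 pN), and flags the call "masked"
instead of unbound when a nucleosome cluster covers the window — the
situation the real assay resolves by unzipping from the other direction.
`call_nucleosome()` takes the first qualifying cluster (+43 bp convention)
and reports the structural features (cluster max forces, widths,
inter-cluster distance). The cluster gap (15 bp) and force floor (22 pN)
were chosen so the default signature geometry is separated with wide
margin; they are config keys, not claims about experimental values.

## Remodeling ensembles

`simulate_remodeling_ensemble()` draws per molecule: an initial TF occupancy
(bound with probability 0.95, matching reactions run at ~95% site
saturation — the ~5% TF-free molecules reproduce the far-traveling outliers
seen in barrier experiments), a Poisson number of remodeling events, and
sequential repositioning moves.

* **Event counts.** Short reactions use lambda = -log(0.55), so 55% of
  molecules draw zero events; long reactions use lambda = 8 ("multiple
  rounds"). The printed unremodeled/remodeled fractions in the motivating
  work sum to 101% (56%/45%); the package treats p0 as the single source of
  truth and takes p0 = 0.55.
* **ISW1a-like remodeler.** Each event contracts the dyad toward the
  midpoint of the accessible segment — between the bound-TF footprint edge
  and the template end — as `new = mid + 0.3 (old - mid) + noise`, with the
  noise scaled for a stationary spread of 5 bp about the midpoint. The
  footprint never crosses a bound TF or a template end. The AR(1) form was
  chosen over a direct draw at the midpoint so single-event (short-reaction)
  moves are partial, while long reactions converge to the centered steady
  state. Without a bound TF the accessible segment is the whole template.
* **SWI/SNF-like remodeler.** Each event displaces the dyad by
  Normal(0, 60 bp), clamped to the template; while the TF is bound the step
  direction is biased toward the TF with probability 0.85 (the
  linker-sensing orientation of the remodeler's DNA-binding subunit, which
  persists as long as the TF blocks one side); the TF is evicted the first
  time the sliding footprint overlaps the TF footprint at any point of a
  move. A first-event-only bias was tried and rejected: it leaves 25-30% of
  remodeled molecules with a retained TF after long reactions, contradicting
  the observed complete loss of the TF signature; with the persistent bias,
  long-reaction retention is 1-3%, and short-reaction directionality stays
  ~0.8 toward the TF. All rates, spreads and biases are config keys.

## Population statistics

* `fit_double_gaussian()` decomposes position distributions into a narrow
  (unremodeled) and broad (remodeled) component, constrained
  `sigma1 <= sigma2`, by EM on the raw positions from fixed deterministic
  starts (binning-free, reproducible); a histogram least-squares mode is
  provided for fidelity with histogram-based practice and agrees with the
  likelihood fit on well-behaved data. A fit is flagged degenerate when a
  component collapses, a weight vanishes, or the mixture fails a
  likelihood-ratio heuristic against a single Gaussian.
* `poisson_event_fractions()` converts the unremodeled probability p0 into
  lambda = -log(p0) and the fractions of remodeled molecules remodeled once
  (`lambda e^-lambda / (1 - e^-lambda)`) versus more than once; p0 = 0.55
  gives 73%/27%.
* `fit_binding_isotherm()` fits fraction bound = c/(c + Kd) by nonlinear
  least squares; `fit_occupancy_vs_time()` fits the stability line and calls
  occupancy stable when the slope CI covers zero.
* `precision_accuracy()`, `centering_statistic()` and
  `directionality_and_eviction_summary()` compute the headline ensemble
  numbers: bias/SD of calls against truth, distance moved and deviation from
  the accessible-segment midpoint (TF-free outliers flagged; kept in
  distance summaries, excluded from midpoint deviation, which is undefined
  without a barrier), displacement direction relative to the TF, TF
  retention, and the fraction of dyads that passed the TF site.

## Reproducibility, problem sizes, and limitations

Every stochastic function takes a seed; ensembles record per-molecule
sub-seeds; pipeline runs (`run_simulate()` / `run_analyze()` /
`run_report()`) are deterministic per (config, seed) and round-trip their
configuration through YAML. The test suite exercises the full distortion box
(5 x 5 grid, 10 seeds per cell), 100-200-trace Monte-Carlo precision
experiments, 200-400-molecule ensembles, and a 10^6-draw Poisson oracle —
sizes at which the checked tolerances (0.5 bp alignment, 1 bp bias / 2 bp
SD calling, 3% mixture weight, 5% Kd) are comfortably resolved.

What passing these tests does *not* show: the generator has no
sequence-dependent energetics (its baseline is a surrogate), no partial or
intermediate nucleosome disruption states, no histone loss, no remodeler
kinetics beyond event counts and displacement rules, and a TF footprint
half-width (10 bp) that is a config default, not a measured value. Position
calls on real traces would additionally face bp-to-nm calibration and
elasticity modeling, both out of scope here. A TF signature physically
overlapping a nucleosome signature is flagged "masked", never deconvolved —
the experimental remedy (unzip from the other side) is available in the
simulator via `direction = "from_nucleosome_side"`.
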