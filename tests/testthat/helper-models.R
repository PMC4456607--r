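# Shared fixtures: default and noiseless model pairs, standard layouts, and
# a cached naked reference per layout (trace simulation is cheap but the
# reference is reused across many tests).

default_layout <- function() build_template(800, 10, "from_tf_side")

nl <- noiseless_models()

sim_pair <- function(layout, tf = TRUE, nuc = TRUE, seed = 1,
                     noiseless = FALSE, ...) {
  sig <- if (noiseless) nl$signature else signature_model()
  ins <- if (noiseless) nl$instrument else instrument_model()
  list(
    trace = simulate_trace(layout, tf_bound = tf, nuc_present = nuc,
                           signature = sig, instrument = ins, seed = seed, ...),
    reference = simulate_trace(layout, FALSE, FALSE, signature = sig,
                               instrument = ins, seed = seed + 10000L)
  )
}

# full same-grid calling pipeline (no alignment step)
call_pipeline <- function(trace, reference, layout) {
  bl <- estimate_baseline(trace, reference)
  ev <- detect_events(trace, bl)
  cl <- segment_clusters(ev, trace = trace, baseline = bl)
  list(baseline = bl, events = ev, clusters = cl,
       tf = call_tf(ev, cl, layout),
       nuc = call_nucleosome(cl, layout))
}
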