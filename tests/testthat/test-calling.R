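test_that("baseline estimation recovers the reference and flags grids", {
  lay <- default_layout()
  p <- sim_pair(lay, tf = FALSE, nuc = FALSE, seed = 2)
  ref <- p$reference
  bl <- estimate_baseline(ref, ref)
  # the reference against itself never exceeds its own threshold
  expect_equal(nrow(detect_events(ref, bl)), 0)
  expect_gt(bl$level, 0)

  # constant reference -> constant baseline
  flat <- sim_pair(lay, tf = FALSE, nuc = FALSE, seed = 2,
                   noiseless = TRUE)$reference
  blf <- estimate_baseline(flat, flat)
  expect_true(all(blf$baseline == 15))

  shifted <- flat
  shifted$positions <- shifted$positions + 0.5
  expect_error(estimate_baseline(shifted, flat), "grid")
})

test_that("events appear only in the true signature windows", {
  lay <- default_layout()
  co <- layout_unzip_coords(lay)
  for (seed in 1:5) {
    p <- sim_pair(lay, seed = seed)
    out <- call_pipeline(p$trace, p$reference, lay)
    expect_gte(nrow(out$events), 3)
    in_window <- abs(out$events$position - co$tf_peak_u) <= 15 |
      abs(out$events$position - co$c1_u) <= 25 |
      abs(out$events$position - co$c2_u) <= 25
    expect_true(all(in_window))
  }
  # naked trace: no events
  pn <- sim_pair(lay, tf = FALSE, nuc = FALSE, seed = 6)
  bl <- estimate_baseline(pn$trace, pn$reference)
  expect_equal(nrow(detect_events(pn$trace, bl)), 0)
})

test_that("cluster segmentation follows the gap rule", {
  ev <- data.frame(position = c(100, 105, 160, 163),
                   peak_force = c(25, 26, 30, 28),
                   prominence = c(10, 11, 15, 13), index = 1:4)
  cl <- segment_clusters(ev, gap_bp = 15, centroid = "events")
  expect_equal(nrow(cl), 2)
  expect_equal(cl$n_events, c(2L, 2L))

  single <- segment_clusters(ev[1, ], gap_bp = 15, centroid = "events")
  expect_equal(nrow(single), 1)
  expect_equal(single$width, 0)
  expect_equal(single$centroid, 100)

  # everything within gaps -> one cluster
  one <- segment_clusters(ev, gap_bp = 100, centroid = "events")
  expect_equal(nrow(one), 1)
})

test_that("position-calling conventions recover truth exactly without noise", {
  for (dir in c("from_tf_side", "from_nucleosome_side")) {
    lay <- build_template(800, 10, dir)
    p <- sim_pair(lay, seed = 9, noiseless = TRUE)
    out <- call_pipeline(p$trace, p$reference, lay)
    expect_true(out$tf$bound)
    expect_equal(out$tf$called_center_template, lay$tf_center, tolerance = 1e-9)
    expect_true(out$nuc$present)
    expect_equal(out$nuc$called_dyad_template, lay$dyad0, tolerance = 1e-6)
    expect_equal(out$nuc$called_dyad_rel, 0, tolerance = 1e-6)
    # structural features of the two clusters
    f <- out$nuc$features
    expect_equal(f$intercluster_distance, 48, tolerance = 1e-6)
    expect_true(f$max_force_c1 >= 25 && f$max_force_c1 <= 35)
  }
})

test_that("naked traces yield unbound/absent calls", {
  lay <- default_layout()
  p <- sim_pair(lay, tf = FALSE, nuc = FALSE, seed = 13)
  out <- call_pipeline(p$trace, p$reference, lay)
  expect_false(isTRUE(out$tf$bound))
  expect_false(out$tf$masked)
  expect_false(out$nuc$present)
})

test_that("a nucleosome covering the TF window masks the TF call", {
  lay <- default_layout()
  # render a remodeled molecule whose nucleosome slid onto the TF site
  tr <- simulate_trace(lay, tf_bound = FALSE, nuc_present = TRUE,
                       seed = 3, dyad = lay$tf_center + 45)
  ref <- sim_pair(lay)$reference
  out <- call_pipeline(tr, ref, lay)
  expect_true(out$tf$masked)
  expect_true(is.na(out$tf$bound))
})

test_that("bound/unbound classification is near-perfect at default noise", {
  lay <- default_layout()
  ref <- sim_pair(lay)$reference
  calls <- vapply(1:500, function(i) {
    bound <- i %% 2 == 0
    tr <- simulate_trace(lay, tf_bound = bound, nuc_present = FALSE,
                         seed = 20000 + i)
    out <- call_pipeline(tr, ref, lay)
    isTRUE(out$tf$bound) == bound
  }, logical(1))
  expect_gte(mean(calls), 0.99)
})

test_that("noisy position calls keep near base-pair precision and accuracy", {
  lay <- default_layout()
  ref <- sim_pair(lay)$reference
  res <- t(vapply(1:200, function(i) {
    tr <- simulate_trace(lay, TRUE, TRUE, seed = 30000 + i)
    out <- call_pipeline(tr, ref, lay)
    c(out$tf$called_center_template, out$nuc$called_dyad_template)
  }, numeric(2)))
  tf_pa <- precision_accuracy(res[, 1], lay$tf_center)
  nuc_pa <- precision_accuracy(res[, 2], lay$dyad0)
  expect_lte(abs(tf_pa$bias), 1)
  expect_lte(tf_pa$sd, 2)
  expect_lte(abs(nuc_pa$bias), 1)
  expect_lte(nuc_pa$sd, 2)
})

test_that("both unzipping directions give matching dyad-relative coordinates", {
  res <- lapply(c("from_tf_side", "from_nucleosome_side"), function(dir) {
    lay <- build_template(800, 24, dir)
    ref <- simulate_trace(lay, FALSE, FALSE, seed = 555)
    calls <- t(vapply(1:40, function(i) {
      tr <- simulate_trace(lay, TRUE, TRUE, seed = 40000 + i)
      out <- call_pipeline(tr, ref, lay)
      c(out$tf$called_center_rel, out$nuc$called_dyad_rel)
    }, numeric(2)))
    colMeans(calls)
  })
  expect_lt(abs(res[[1]][1] - res[[2]][1]), 1.5)  # TF center, dyad-relative
  expect_lt(abs(res[[1]][2] - res[[2]][2]), 1.5)  # dyad, dyad-relative
})
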