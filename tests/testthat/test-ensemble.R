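test_that("a 'none' remodeler leaves every molecule untouched", {
  lay <- default_layout()
  ens <- simulate_remodeling_ensemble(lay, remodeler_model("none"), 25,
                                      "long", seed = 1)
  expect_equal(nrow(ens$molecules), 25)
  expect_true(all(ens$molecules$n_events == 0))
  expect_true(all(ens$molecules$dyad_final == lay$dyad0))
  expect_identical(ens$molecules$tf_bound_final, ens$molecules$tf_bound_initial)
})

test_that("ensembles are reproducible per seed", {
  lay <- default_layout()
  a <- simulate_remodeling_ensemble(lay, remodeler_model("isw1a"), 30,
                                    "short", seed = 7)
  b <- simulate_remodeling_ensemble(lay, remodeler_model("isw1a"), 30,
                                    "short", seed = 7)
  expect_identical(a$molecules, b$molecules)
})

test_that("short-duration event counts follow the Poisson zero fraction", {
  lay <- default_layout()
  ens <- simulate_remodeling_ensemble(lay, remodeler_model("isw1a"), 4000,
                                      "short", seed = 11)
  p0_hat <- mean(ens$molecules$n_events == 0)
  se <- sqrt(0.55 * 0.45 / 4000)
  expect_lt(abs(p0_hat - 0.55), 4 * se)
  expect_true(all(ens$molecules$n_events >= 0))
})

test_that("ISW1a never slides the footprint across a bound TF or template end", {
  lay <- build_template(800, 75, "from_tf_side", end_positioned = TRUE)
  ens <- simulate_remodeling_ensemble(lay, remodeler_model("isw1a"), 150,
                                      "long", seed = 21)
  m <- ens$molecules
  ev <- ens$events
  bound_ids <- m$id[m$tf_bound_initial]
  evb <- ev[ev$id %in% bound_ids, ]
  # footprint edge never crosses the TF footprint edge, nor the template end
  expect_true(all(evb$dyad_to - 73 >= lay$tf_center + lay$tf_footprint))
  expect_true(all(ev$dyad_to + 73 <= lay$template_len - 1))
  expect_true(all(ev$dyad_to - 73 >= 0))
  # TF is never evicted by ISW1a
  expect_identical(m$tf_bound_final, m$tf_bound_initial)
})

test_that("long ISW1a reactions center the nucleosome in the accessible segment", {
  lay <- build_template(800, 75, "from_tf_side", end_positioned = TRUE)
  ens <- simulate_remodeling_ensemble(lay, remodeler_model("isw1a"), 100,
                                      "long", seed = 31)
  cs <- centering_statistic(ens$molecules$dyad_initial,
                            ens$molecules$dyad_final, lay,
                            tf_bound = ens$molecules$tf_bound_initial)
  expect_equal(cs$midpoint,
               (lay$tf_center + lay$tf_footprint + lay$template_len - 1) / 2)
  expect_lte(cs$mean_abs_midpoint_deviation, 5)
})

test_that("TF-free molecules travel far and can pass the TF site", {
  lay <- build_template(800, 75, "from_tf_side", end_positioned = TRUE)
  ens <- simulate_remodeling_ensemble(lay, remodeler_model("isw1a"), 400,
                                      "long", seed = 41, p_tf_bound = 0.95)
  m <- ens$molecules
  expect_gt(sum(!m$tf_bound_initial), 0)
  cs <- centering_statistic(m$dyad_initial, m$dyad_final, lay,
                            tf_bound = m$tf_bound_initial)
  # outliers moved much farther on average than barrier-bounded molecules
  far <- cs$per_molecule$distance_moved[cs$per_molecule$outlier]
  near <- cs$per_molecule$distance_moved[!cs$per_molecule$outlier]
  expect_gt(mean(far), mean(near) + 50)
  expect_true(any(m$dyad_final[!m$tf_bound_initial] < lay$tf_center))
})

test_that("SWI/SNF evicts the TF exactly when footprints ever overlapped", {
  lay <- build_template(1200, 11, "from_tf_side")
  ens <- simulate_remodeling_ensemble(lay, remodeler_model("swisnf"), 50,
                                      "long", seed = 51)
  m <- ens$molecules
  ev <- ens$events
  overlapped <- vapply(m$id, function(i) {
    any(ev$overlapped_tf[ev$id == i])
  }, logical(1))
  evicted <- m$tf_bound_initial & !m$tf_bound_final
  expect_identical(evicted, m$tf_bound_initial & overlapped)
})

test_that("long SWI/SNF reactions spread dyads to both sides and evict the TF", {
  lay <- build_template(1200, 11, "from_tf_side")
  ens <- simulate_remodeling_ensemble(lay, remodeler_model("swisnf"), 200,
                                      "long", seed = 61)
  s <- directionality_and_eviction_summary(ens$molecules, lay$tf_center)
  expect_lte(s$frac_tf_retained, 0.05)
  expect_gt(s$frac_passed_tf, 0.1)
  sides <- sign(ens$molecules$dyad_final - lay$tf_center)
  expect_setequal(unique(sides[ens$molecules$tf_bound_initial]), c(-1, 1))
})

test_that("short reactions show opposite directionality for the two remodelers", {
  lay <- default_layout()
  isw <- simulate_remodeling_ensemble(lay, remodeler_model("isw1a"), 300,
                                      "short", seed = 71)
  sw <- simulate_remodeling_ensemble(lay, remodeler_model("swisnf"), 300,
                                     "short", seed = 71)
  d_isw <- directionality_and_eviction_summary(isw$molecules, lay$tf_center)
  d_sw <- directionality_and_eviction_summary(sw$molecules, lay$tf_center)
  expect_gt(d_isw$frac_away, 0.95)
  expect_gt(d_sw$frac_toward_tf, 0.6)
})

test_that("binding titrations follow the single-site isotherm", {
  tit <- simulate_binding_titration(3.4, 3.4, 1e6, seed = 5)
  expect_lt(abs(tit$per_conc$fraction - 0.5), 0.002)

  # saturation limit
  sat <- simulate_binding_titration(1e6, 3.4, 2000, seed = 6)
  expect_gt(sat$per_conc$fraction, 0.99)

  expect_error(simulate_binding_titration(c(-1, 2), 3.4, 10), "positive")
  expect_error(simulate_binding_titration(2, -3, 10), "kd")
})
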