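test_that("alignment windows flank the expected signature regions", {
  lay <- default_layout()
  w <- select_alignment_regions(lay)
  expect_length(w, 2)
  co <- layout_unzip_coords(lay)
  expect_lt(w[[1]][2], co$tf_peak_u)   # pre-TF window
  expect_gt(w[[2]][1], co$c2_u)        # post-nucleosome window
  expect_true(all(vapply(w, diff, numeric(1)) >= 50))

  # end-positioned nucleosome: only the pre-signature window remains
  lay_end <- build_template(800, 75, "from_tf_side", end_positioned = TRUE)
  w_end <- select_alignment_regions(lay_end)
  expect_length(w_end, 1)
  expect_lt(w_end[[1]][2], layout_unzip_coords(lay_end)$tf_peak_u)

  # signatures covering everything usable -> error
  expect_error(select_alignment_regions(lay, min_len = 500), "window")
})

test_that("self-alignment is the identity with score ~1", {
  lay <- default_layout()
  ref <- sim_pair(lay)$reference
  al <- fit_shift_stretch(ref, ref)
  expect_equal(al$shift_bp, 0)
  expect_equal(al$stretch, 1)
  expect_gt(al$score, 0.999)
})

test_that("known distortions are recovered near base-pair level", {
  lay <- default_layout()
  ref <- sim_pair(lay)$reference
  w <- select_alignment_regions(lay)
  for (seed in 1:3) {
    tr <- distort_trace(simulate_trace(lay, TRUE, TRUE, seed = seed), 7, 1.010)
    al <- fit_shift_stretch(tr, ref, w)
    expect_lt(abs(al$shift_bp - 7), 0.2 + 1e-9)
    expect_lt(abs(al$stretch - 1.010), 0.001 + 1e-9)
  }
})

test_that("alignment inverts distortion to within interpolation error", {
  lay <- default_layout()
  tr <- simulate_trace(lay, TRUE, TRUE, seed = 4)
  d <- distort_trace(tr, 9, 1.015)
  back <- apply_alignment(d, list(shift_bp = 9, stretch = 1.015))
  expect_lt(max(abs(back$positions - tr$positions)), 0.1)

  # composing two alignments equals one composed alignment
  d2 <- distort_trace(distort_trace(tr, 3, 1.004), 2, 1.003)
  one <- apply_alignment(d2, list(shift_bp = 1.003 * 3 + 2,
                                  stretch = 1.003 * 1.004))
  two <- apply_alignment(apply_alignment(d2, list(shift_bp = 2, stretch = 1.003)),
                         list(shift_bp = 3, stretch = 1.004))
  expect_lt(max(abs(one$positions - two$positions)), 0.1)
})

test_that("grid search matches a brute-force oracle on coarse grids", {
  lay <- default_layout()
  ref <- sim_pair(lay)$reference
  tr <- distort_trace(simulate_trace(lay, TRUE, TRUE, seed = 8), 4, 1.01)
  w <- select_alignment_regions(lay)

  # oracle: evaluate every coarse grid point by direct interpolation
  stretches <- c(0.99, 1.00, 1.01)
  shifts <- -10:10
  zscore <- function(v) (v - mean(v)) / (stats::sd(v) * sqrt((length(v) - 1) / length(v)))
  eval_point <- function(sh, st) {
    num <- 0; nn <- 0
    for (win in w) {
      sel <- ref$positions >= win[1] & ref$positions <= win[2]
      xr <- ref$positions[sel]
      fr <- zscore(ref$forces[sel])
      fv <- stats::approx(tr$positions, tr$forces, st * xr + sh)$y
      num <- num + sum(fr * zscore(fv)) ; nn <- nn + length(xr)
    }
    num / nn
  }
  grid <- expand.grid(shift = shifts, stretch = stretches)
  grid$score <- mapply(eval_point, grid$shift, grid$stretch)
  oracle <- grid[which.max(grid$score), ]

  al <- fit_shift_stretch(tr, ref, w, shift_bounds = c(-10, 10),
                          stretch_bounds = c(0.99, 1.01),
                          shift_step = 1, stretch_step = 0.01)
  expect_equal(al$shift_bp, oracle$shift)
  expect_equal(al$stretch, oracle$stretch)
  expect_equal(al$score, oracle$score, tolerance = 1e-3)
})

test_that("fitted optimum scores at least as high as the true parameters", {
  lay <- default_layout()
  ref <- sim_pair(lay)$reference
  w <- select_alignment_regions(lay)
  tr <- distort_trace(simulate_trace(lay, TRUE, TRUE, seed = 12), -5, 0.99)
  al <- fit_shift_stretch(tr, ref, w)
  truth <- fit_shift_stretch(tr, ref, w, shift_bounds = c(-5, -5),
                             stretch_bounds = c(0.99, 0.99))
  expect_gte(al$score, truth$score - 1e-9)
})

test_that("degenerate constant windows are rejected", {
  lay <- default_layout()
  ref <- sim_pair(lay, noiseless = TRUE)$reference  # flat baseline
  expect_error(fit_shift_stretch(ref, ref), "degenerate")
})
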