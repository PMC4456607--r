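test_that("position histograms bin in dyad-relative coordinates", {
  h <- position_histogram(c(0, 0, 0), bin_bp = 5)
  expect_equal(nrow(h), 1)
  expect_equal(h$bin_start, -2.5)
  expect_equal(h$count, 3L)

  # {-2, 2} fall into the single origin bin [-2.5, 2.5)
  h2 <- position_histogram(c(-2, 2), bin_bp = 5)
  expect_equal(nrow(h2), 1)
  expect_equal(h2$count, 2L)

  expect_equal(nrow(position_histogram(numeric(0))), 0)
  expect_equal(sum(position_histogram(rnorm(100, 0, 30))$count), 100L)
})

test_that("Poisson event fractions match the closed form and a Monte-Carlo oracle", {
  ef <- poisson_event_fractions(0.55)
  expect_equal(ef$lambda, -log(0.55))
  expect_equal(round(100 * ef$frac_once), 73)
  expect_equal(round(100 * ef$frac_multi), 27)

  expect_equal(poisson_event_fractions(0.56)$frac_once, 0.738, tolerance = 1e-3)

  # oracle: conditional frequency among 10^6 Poisson draws
  for (p0 in c(0.3, 0.55, 0.8)) {
    set.seed(17)
    k <- stats::rpois(1e6, -log(p0))
    mc_once <- sum(k == 1) / sum(k >= 1)
    expect_lt(abs(poisson_event_fractions(p0)$frac_once - mc_once), 0.003)
  }

  # small-lambda limit: almost all remodeled molecules remodeled once
  expect_gt(poisson_event_fractions(0.999)$frac_once, 0.999)
  expect_error(poisson_event_fractions(1), "inside")
  expect_error(poisson_event_fractions(0), "inside")
})

test_that("double-Gaussian fit recovers generating weights", {
  gen <- function(w, n, seed) {
    set.seed(seed)
    narrow <- stats::runif(n) < w
    ifelse(narrow, stats::rnorm(n, 0, 2), stats::rnorm(n, 0, 30))
  }
  for (w in c(0.3, 0.56, 0.7)) {
    errs <- vapply(1:5, function(s) {
      x <- gen(w, 2000, 100 * w + s)
      fit <- fit_double_gaussian(x)
      expect_true(fit$converged)
      expect_lte(fit$sigma1, fit$sigma2)
      fit$w_unremodeled - w
    }, numeric(1))
    se <- sqrt(w * (1 - w) / 2000)
    expect_lte(stats::median(abs(errs)), 3 * se)
  }
  # smaller samples: recovery within 3 binomial SEs as well
  errs <- vapply(1:5, function(s) {
    fit_double_gaussian(gen(0.56, 200, 900 + s))$w_unremodeled - 0.56
  }, numeric(1))
  expect_lte(stats::median(abs(errs)), 3 * sqrt(0.56 * 0.44 / 200))
})

test_that("likelihood and histogram mixture fits agree on default data", {
  set.seed(12)
  x <- ifelse(stats::runif(2000) < 0.56, stats::rnorm(2000, 0, 2),
              stats::rnorm(2000, 0, 30))
  ml <- fit_double_gaussian(x)
  hist <- fit_double_gaussian(x, method = "histogram")
  expect_lt(abs(ml$w_unremodeled - hist$w_unremodeled), 0.05)
  expect_lt(abs(ml$sigma2 - hist$sigma2) / ml$sigma2, 0.15)
})

test_that("mixture EM agrees with an independent implementation", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  set.seed(23)
  x <- ifelse(stats::runif(1500) < 0.56, stats::rnorm(1500, 0, 2),
              stats::rnorm(1500, 0, 30))
  ours <- fit_double_gaussian(x)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  w_narrow_mc <- mc$parameters$pro[which.min(mc$parameters$variance$sigmasq)]
  expect_lt(abs(ours$w_unremodeled - w_narrow_mc), 0.02)
  expect_lt(abs(ours$loglik - mc$loglik), 1)
})

test_that("degenerate single-population input is flagged", {
  set.seed(5)
  fit <- fit_double_gaussian(stats::rnorm(200, 0, 2))
  expect_true(fit$degenerate || fit$w_unremodeled > 0.95)
  expect_error(fit_double_gaussian(stats::rnorm(10)), "at least 20")
})

test_that("posterior classification separates the components", {
  set.seed(31)
  narrow <- stats::rnorm(500, 0, 2)
  broad <- stats::rnorm(500, 0, 30)
  fit <- fit_double_gaussian(c(narrow, broad))
  cls <- classify_remodeled(fit, c(-1, 1, 60, -60))
  expect_identical(cls, c(FALSE, FALSE, TRUE, TRUE))
})

test_that("isotherm fits recover the dissociation constant", {
  conc <- c(0.5, 1, 2, 3.4, 5, 10, 20, 50)
  exact <- data.frame(concentration = conc, fraction = conc / (conc + 3.4))
  fit <- fit_binding_isotherm(exact)
  expect_equal(fit$kd, 3.4, tolerance = 1e-6)

  # simulated counting noise
  tit <- simulate_binding_titration(conc, 3.4, 500, seed = 3)
  fit2 <- fit_binding_isotherm(tit)
  expect_lt(abs(fit2$kd - 3.4) / 3.4, 0.15)
  expect_true(all(c("se") %in% names(fit2$per_conc) |
                    "se" %in% names(fit2)))

  expect_error(fit_binding_isotherm(
    data.frame(concentration = conc, fraction = rep(1, 8))), "unidentifiable")
  expect_error(fit_binding_isotherm(
    data.frame(concentration = c(1, 2), fraction = c(0.2, 0.4))), "3")
})

test_that("Kd recovery under 2% noise is within 5% (median over seeds)", {
  conc <- c(0.5, 1, 2, 3.4, 5, 10, 20, 50)
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    f <- pmin(1, conc / (conc + 3.4) * (1 + stats::rnorm(8, 0, 0.02)))
    abs(fit_binding_isotherm(
      data.frame(concentration = conc, fraction = f))$kd - 3.4) / 3.4
  }, numeric(1))
  expect_lt(stats::median(errs), 0.05)
})

test_that("occupancy-vs-time fit detects stability and decay", {
  flat <- fit_occupancy_vs_time(seq(0, 60, by = 10), rep(0.95, 7))
  expect_equal(flat$slope, 0)
  expect_true(flat$stable)

  # stable occupancy with binomial noise: CI covers zero in most seeds
  covered <- vapply(1:20, function(s) {
    set.seed(s)
    t <- seq(0, 60, length.out = 20)
    f <- stats::rbinom(20, 50, 0.95) / 50
    fit_occupancy_vs_time(t, f)$stable
  }, logical(1))
  expect_gte(mean(covered), 0.9)

  decay <- fit_occupancy_vs_time(0:10, seq(1, 0.5, length.out = 11))
  expect_lt(decay$slope, 0)
  expect_false(decay$stable)
})

test_that("precision_accuracy matches its closed forms", {
  expect_equal(precision_accuracy(c(10, 10), 10),
               list(bias = 0, sd = 0, n = 2L))
  pa <- precision_accuracy(c(9, 11), 10)
  expect_equal(pa$bias, 0)
  expect_equal(pa$sd, sqrt(2))
  expect_error(precision_accuracy(5, 5), "at least 2")
})

test_that("centering statistic measures midpoint deviation per molecule", {
  lay <- build_template(800, 75, "from_tf_side", end_positioned = TRUE)
  mid <- (lay$tf_center + lay$tf_footprint + lay$template_len - 1) / 2
  cs <- centering_statistic(rep(lay$dyad0, 3), c(mid, mid + 10, mid - 10), lay)
  expect_equal(cs$per_molecule$midpoint_deviation, c(0, 10, -10))
  expect_equal(cs$mean_midpoint_deviation, 0)
  expect_equal(cs$mean_distance_moved,
               mean(abs(c(mid, mid + 10, mid - 10) - lay$dyad0)))
})
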