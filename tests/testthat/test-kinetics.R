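test_that("Eyring rates match closed-form evaluations of the stated constants", {
  # independent closed-form oracle with the same constants
  k_oracle <- function(dg, T) 2.083661e10 * T * exp(-dg / (1.987204e-3 * T))
  expect_equal(eyring_rate(6.8, 298.15)$k, k_oracle(6.8, 298.15))
  expect_equal(eyring_rate(6.8, 298.15)$k, 6.44e7, tolerance = 1e-3)
  expect_equal(eyring_rate(31.2, 408.15)$k, 1.67e-4, tolerance = 1e-2)
  # "racemization over a few hours" at 135 C: ee half-life ~ 35 min
  hl <- log(2) / (2 * eyring_rate(31.2, celsius_to_kelvin(135))$k)
  expect_equal(hl / 60, 35, tolerance = 0.03)
  expect_equal(eyring_rate(0, 350)$k, 2.083661e10 * 350)
  expect_error(eyring_rate(10, -5), "positive")
})

test_that("eyring_rate and barrier_from_rate are exact inverses", {
  for (dg in seq(1, 45, by = 4)) {
    for (T in seq(250, 500, by = 50)) {
      expect_equal(barrier_from_rate(eyring_rate(dg, T)), dg,
                   tolerance = 1e-9)
    }
  }
  T <- 408.15
  expect_equal(barrier_from_rate(2.083661e10 * T, T), 0)
  expect_error(barrier_from_rate(-1, 300), "positive")
})

test_that("ee decays first-order with rate 2k and conserves total concentration", {
  k <- 5e-4
  d <- ee_decay(0.9, k, c(0, 100, 1000))
  expect_equal(d$ee[1], 0.9)
  expect_equal(d$half_life, log(2) / (2 * k))
  expect_equal(ee_decay(0.9, k, d$half_life)$ee, 0.45)
  # sign preserved, strictly decreasing magnitude
  t <- seq(0, 5000, by = 250)
  neg <- ee_decay(-0.8, k, t)$ee
  expect_true(all(neg < 0))
  expect_true(all(diff(abs(neg)) < 0))
  # species picture: ee decay at 2k keeps A_R + A_S constant when each
  # enantiomer interconverts with one-way rate k
  A0 <- c(R = 0.95, S = 0.05)
  ee_t <- ee_decay(0.9, k, t)$ee
  AR <- (1 + ee_t) / 2; AS <- (1 - ee_t) / 2
  expect_equal(AR + AS, rep(1, length(t)))
})

test_that("rates are recovered from time courses by log-linear regression", {
  tc <- racemization_timecourse(c(0, 1000, 2000), ee = exp(-(0:2)),
                                temperature = 408.15)
  r <- fit_rate_from_timecourse(tc)
  expect_equal(r$k, 5e-4)

  truth <- eyring_rate(31.2, 408.15)$k
  sim <- gen_racemization(408.15, dg = 31.2, n_points = 10, n_halflives = 3)
  fit <- fit_rate_from_timecourse(sim$timecourses[[1]])
  expect_equal(fit$k, truth, tolerance = 1e-9)

  # noise floor handling: sub-floor points dropped with a warning
  tc2 <- racemization_timecourse(c(0, 10, 20, 30), ee = c(0.5, 0.3, 0.2, 1e-7),
                                 temperature = 400)
  expect_warning(fit_rate_from_timecourse(tc2), "floor")
  tc3 <- racemization_timecourse(c(0, 10, 20), ee = c(0.5, 1e-7, 1e-8),
                                 temperature = 400)
  expect_error(suppressWarnings(fit_rate_from_timecourse(tc3)),
               "insufficient")
})

test_that("fitted rates are statistically calibrated under 1% ee noise", {
  truth <- eyring_rate(31.2, 408.15)$k
  within3 <- 0L
  set.seed(202)
  for (i in 1:200) {
    sim <- gen_racemization(408.15, dg = 31.2, n_points = 12,
                            n_halflives = 5, noise_sd = 0.01,
                            seed = sample.int(1e6, 1))
    # floor drops are the documented clipping behaviour, tested above
    f <- suppressWarnings(fit_rate_from_timecourse(sim$timecourses[[1]]))
    if (abs(f$k - truth) <= 3 * f$se) within3 <- within3 + 1L
  }
  expect_gte(within3 / 200, 0.95)
})

test_that("Eyring regression recovers dH/dS and propagates dG uncertainty", {
  dH <- 25; dS <- -0.015
  temps <- c(390, 400, 410)
  rates <- lapply(temps, function(T) eyring_rate(dH - T * dS, T))
  fit <- eyring_regression(rates, t_ref = 400)
  expect_equal(fit$dH, dH, tolerance = 1e-6)
  expect_equal(fit$dS, dS, tolerance = 1e-6)
  expect_equal(fit$dG, dH - 400 * dS, tolerance = 1e-6)
  expect_equal(fit$mode, "multi-temperature")

  single <- eyring_regression(eyring_rate(31.2, 408.15))
  expect_equal(single$dG, 31.2, tolerance = 1e-9)
  expect_equal(single$mode, "single-temperature")
  expect_true(is.na(single$dH))

  # constant-dG data (dS = 0): fitted dH equals dG, dS vanishes
  const <- lapply(temps, function(T) eyring_rate(28, T))
  cfit <- eyring_regression(const, t_ref = 400)
  expect_equal(cfit$dH, 28, tolerance = 1e-6)
  expect_equal(cfit$dS, 0, tolerance = 1e-8)

  dup <- list(eyring_rate(30, 400), eyring_rate(30.5, 400))
  expect_error(eyring_regression(dup), "rank error")
})

test_that("multi-temperature dG recovery is unbiased with calibrated intervals", {
  truth <- 31.2
  biases <- numeric(200); covered <- logical(200)
  set.seed(303)
  for (i in 1:200) {
    sim <- gen_racemization(c(398.15, 408.15, 418.15), dg = truth,
                            n_points = 12, n_halflives = 5,
                            noise_sd = 0.01, seed = sample.int(1e6, 1))
    rates <- suppressWarnings(
      lapply(sim$timecourses, fit_rate_from_timecourse,
             weights = "inverse-variance"))
    fit <- eyring_regression(rates, t_ref = 408.15)
    biases[i] <- fit$dG - truth
    covered[i] <- abs(fit$dG - truth) <= 2 * fit$dG_se
  }
  expect_lt(abs(mean(biases)), 0.05)
  expect_gte(mean(covered), 0.90)
})

test_that("non-racemization observations give monotone barrier lower bounds", {
  b <- min_barrier_from_no_racemization(418.15, 36000, 0.02)
  expect_equal(round(b), 37)
  expect_equal(b, 37.295, tolerance = 1e-4)
  # doubling the duration raises the bound by exactly R T ln 2
  b2 <- min_barrier_from_no_racemization(418.15, 72000, 0.02)
  expect_equal(b2 - b, 1.987204e-3 * 418.15 * log(2), tolerance = 1e-12)
  # monotone decreasing in the detection threshold
  dets <- c(0.005, 0.01, 0.02, 0.05, 0.2, 0.8)
  bounds <- vapply(dets, function(d)
    min_barrier_from_no_racemization(418.15, 36000, d), numeric(1))
  expect_true(all(diff(bounds) < 0))
  expect_error(min_barrier_from_no_racemization(418.15, 36000, 1.2),
               "detection")
})

test_that("time-course files parse with temperature metadata and peak areas", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# T_K=408.15", "t_s,ee", "0,1", "100,0.9", "200,0.81"), path)
  tc <- read_timecourse(path)
  expect_equal(tc$temperature, 408.15)
  expect_equal(tc$ee, c(1, 0.9, 0.81))

  writeLines(c("# T_K=400", "t_s,area_major,area_minor",
               "0,100,0", "50,90,10"), path)
  tc2 <- read_timecourse(path)
  expect_equal(tc2$ee, c(1, 0.8))
})
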