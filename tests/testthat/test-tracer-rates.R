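# Hand-computed oracles for the radiotracer rate calculus:
# leucine: 566.9 DPM / (2.22e12 DPM/Ci x 144.2 Ci/mmol) = 1.7708e-12 mmol,
#   over 1.7 mL and 2.5 h -> 10.0 pmol leu L-1 d-1, x 1.92 kg C mol-1
#   -> 19.2 ug C m-3 d-1.
# bicarbonate: f = 482.6 / (0.25 x 40 x 2.22e6) = 2.1739e-5 of the pool,
#   x 2.3 mmol L-1 x 12 ug umol-1 x 1e3 / 3 d -> 200 ug C m-3 d-1.

test_that("net DPM is blank-subtracted, clamped, with replicate scatter", {
  nd <- net_dpm(c(600, 610, 590), c(100, 100))
  expect_equal(nd$net, 500)
  expect_equal(nd$sd, sd(c(600, 610, 590)))
  expect_warning(nd0 <- net_dpm(c(90, 95), c(100, 100)), "clamped")
  expect_equal(nd0$net, 0)
  expect_error(net_dpm(numeric(0), 100), "at least one")
  expect_error(net_dpm(c(100, -5), 100), "non-negative")
})

test_that("leucine incubation converts to PHP by the hand oracle", {
  inc <- leucine_incubation(rep(666.9, 3), c(100, 100))
  r <- php_rate(inc, cf = 1.92)
  expect_equal(r$net_dpm, 566.9)
  expect_equal(r$rate, 19.2, tolerance = 1e-4)
  expect_equal(r$sd, 0)
  # zero net -> zero rate
  z <- php_rate(leucine_incubation(rep(100, 3), c(100, 100)), 1.92)
  expect_equal(z$rate, 0)
  # homogeneity: doubling net DPM doubles the rate
  r2 <- php_rate(leucine_incubation(rep(100 + 2 * 566.9, 3), c(100, 100)),
                 1.92)
  expect_equal(r2$rate, 2 * r$rate)
  expect_error(leucine_incubation(rep(600, 3), c(100, 100),
                                  incubation_time = 0), "positive")
})

test_that("bicarbonate incubation converts to ABD by the hand oracle", {
  inc <- bicarbonate_incubation(rep(582.6, 3), c(100, 100), dic = 2.3)
  r <- abd_rate(inc)
  expect_equal(r$rate, 200, tolerance = 1e-4)
  expect_equal(abd_rate(bicarbonate_incubation(rep(100, 3), c(100, 100),
                                               dic = 2.3))$rate, 0)
  # linear in DIC at fixed DPM
  r2 <- abd_rate(bicarbonate_incubation(rep(582.6, 3), c(100, 100),
                                        dic = 4.6))
  expect_equal(r2$rate, 2 * r$rate)
  # missing DIC errors unless the caller opts into the basin default
  no_dic <- bicarbonate_incubation(rep(582.6, 3), c(100, 100))
  expect_error(abd_rate(no_dic), "basin default")
  expect_equal(abd_rate(no_dic, require_dic = FALSE)$dic,
               abd_constants()$dic_default)
})

test_that("replicate scatter propagates linearly to rate sd", {
  reps <- c(650, 670, 680.7)
  inc <- leucine_incubation(reps, c(100, 100))
  r <- php_rate(inc, 1.92)
  expect_equal(r$sd / r$rate, sd(reps) / (mean(reps) - 100))
  expect_equal(r$se, r$sd / sqrt(3))
})

test_that("kinetic isotope-dilution fit recovers Kt+Sn from exact data", {
  # noise-free series constructed from the linearization itself:
  # f = t Vmax / (KtSn + hot + A), truth KtSn = 1.4, hot = 5 -> ID 1.28
  hot <- 5; ktsn <- 1.4; vmax <- 0.5; t <- 2.5
  cold <- c(0, 2.5, 5, 10, 20, 40)
  f <- t * vmax / (ktsn + hot + cold)
  ser <- dilution_series(hot, cold, net_dpm = f * 1e5, added_dpm = 1e5,
                         incubation_time = t)
  est <- estimate_isotope_dilution(ser)
  expect_equal(est$id, 1.28, tolerance = 1e-10)
  expect_equal(est$kt_plus_sn, 1.4, tolerance = 1e-9)
  expect_equal(est$v_max, vmax, tolerance = 1e-9)
  # no ambient pool -> ID exactly 1
  f0 <- t * vmax / (0 + hot + cold)
  est0 <- estimate_isotope_dilution(
    dilution_series(hot, cold, net_dpm = f0 * 1e5, added_dpm = 1e5,
                    incubation_time = t))
  expect_equal(est0$id, 1.0, tolerance = 1e-9)
})

test_that("isotope-dilution estimate is invariant to rescaling velocities", {
  hot <- 5; cold <- c(0, 2.5, 5, 10, 20, 40)
  f <- 2.5 * 0.5 / (1.4 + hot + cold)
  base <- estimate_isotope_dilution(
    dilution_series(hot, cold, f * 1e5, 1e5, 2.5))
  for (k in c(0.2, 3)) {
    scaled <- estimate_isotope_dilution(
      dilution_series(hot, cold, k * f * 1e5, 1e5, 2.5))
    expect_equal(scaled$id, base$id, tolerance = 1e-9)
  }
})

test_that("negative fitted ambient pool clamps ID to 1 with a warning", {
  hot <- 5; cold <- c(0, 10, 20, 40)
  f <- 2.5 * 0.5 / (-2 + hot + cold) # impossible negative KtSn
  expect_warning(
    est <- estimate_isotope_dilution(
      dilution_series(hot, cold, f * 1e5, 1e5, 2.5)),
    "clamped")
  expect_equal(est$id, 1)
  expect_error(dilution_series(5, c(10, 10, 10), 1:3 * 100, 1e5), "distinct")
})

test_that("noisy dilution series recover the observed deep-water band", {
  # matched truth ID 1.28; 2% multiplicative noise on velocities
  set.seed(42)
  hot <- 5; cold <- c(0, 2.5, 5, 10, 20, 40)
  f <- 2.5 * 0.5 / (1.4 + hot + cold)
  ids <- replicate(200, suppressWarnings(estimate_isotope_dilution(
    dilution_series(hot, cold, f * exp(rnorm(6, 0, 0.02)) * 1e5, 1e5, 2.5)
  )$id))
  expect_equal(mean(ids), 1.28, tolerance = 0.02)
  expect_true(all(ids >= 1.0))
  # the bulk of the estimates fall inside the band observed at sea
  expect_gt(mean(ids >= 1.0 & ids <= 1.33), 0.7)
})

test_that("time-course linearity fit behaves on exact and noisy lines", {
  tl <- fit_linearity(c(0, 24, 48, 72), 0.42857 + 4.3393 * c(0, 24, 48, 72))
  expect_equal(tl$correlation, 1.0)
  expect_equal(tl$slope, 4.3393)
  flat <- fit_linearity(1:4, rep(7, 4))
  expect_equal(flat$slope, 0)
  set.seed(1)
  x <- seq(0, 72, by = 8)
  y <- 2 + 5 * x + rnorm(length(x), 0, 3)
  noisy_fit <- fit_linearity(x, y)
  slope_se <- summary(lm(y ~ x))$coefficients[2, 2]
  expect_lt(abs(noisy_fit$slope - 5), 2 * slope_se)
  expect_error(fit_linearity(c(1, 2), c(1, 2)), ">= 3")
})
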