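make_profile <- function(depths, rates, bottom, sds = NULL, flags = NULL) {
  s <- tibble::tibble(depth_m = depths, abd = rates)
  if (!is.null(sds)) s$abd_sd <- sds
  if (!is.null(flags)) s$flags <- flags
  station_profile("T", bottom, s)
}

test_that("trapezoid with bottom extension matches hand-integrated stations", {
  st4 <- make_profile(c(200, 400, 2500, 3500), c(114, 231, 59, 48), 3571)
  expect_equal(integrate_profile(st4, "abd")$value, 395.9, tolerance = 1e-3)
  st2 <- make_profile(c(200, 400, 1500, 2633), c(268, 198, 204, 142), 2640)
  expect_equal(integrate_profile(st2, "abd")$value, 464.7, tolerance = 1e-3)
})

test_that("uniform profile integrates to a rectangle", {
  st <- make_profile(c(200, 700, 1200), rep(100, 3), 1200)
  expect_equal(integrate_profile(st, "abd")$value, 100)
  # single point: pure bottom extension
  one <- make_profile(500, 100, 1500)
  expect_warning(r <- integrate_profile(one, "abd"), "no upward")
  expect_equal(r$value, 100 * 1000 / 1e3)
})

test_that("trapezoid equals a dense piecewise-linear Riemann oracle", {
  skip_if_not_installed("pracma")
  set.seed(99)
  for (rep in 1:5) {
    z <- sort(sample(200:3400, 6))
    r <- runif(6, 10, 400)
    bottom <- max(z) + sample(10:300, 1)
    p <- make_profile(z, r, bottom)
    dense_z <- seq(min(z), bottom, by = 1)
    dense_r <- approx(c(z, bottom), c(r, r[length(r)]), xout = dense_z)$y
    oracle <- pracma::trapz(dense_z, dense_r) / 1e3
    expect_equal(integrate_profile(p, "abd", z_top = min(z))$value, oracle,
                 tolerance = 1e-3)
  }
})

test_that("integration is additive over a split at a shared sample", {
  z <- c(200, 600, 1400, 2600); r <- c(300, 180, 220, 90); bottom <- 2700
  full <- integrate_profile(make_profile(z, r, bottom), "abd")$value
  # upper piece ends exactly at the 1400 m sample (bottom = deepest sample,
  # zero-width extension); lower piece starts there
  upper <- integrate_profile(make_profile(z[1:3], r[1:3], 1400), "abd")$value
  lower <- integrate_profile(make_profile(z[3:4], r[3:4], bottom), "abd",
                             z_top = 1400)$value
  expect_equal(upper + lower, full)
})

test_that("pointwise larger profiles integrate to larger values", {
  z <- c(200, 1000, 2500); bottom <- 3000
  lo <- integrate_profile(make_profile(z, c(50, 60, 70), bottom), "abd")$value
  hi <- integrate_profile(make_profile(z, c(55, 80, 71), bottom), "abd")$value
  expect_gt(hi, lo)
})

test_that("flagged samples are excluded and recorded; ND rows are skipped", {
  z <- c(200, 500, 1000, 2000, 3000, 3400)
  r <- c(140, 370, 290, 245, 207, 730)
  fl <- c("", "", "", "", "", "DHAL-influenced")
  p <- make_profile(z, r, 3625, flags = fl)
  out <- integrate_profile(p, "abd")
  expect_equal(out$value, 864.4, tolerance = 1e-3)
  expect_equal(out$excluded[[1]], 3400)
  expect_equal(out$n_points, 5)
  # without the exclusion flag the interface sample inflates the integral
  # hand value with the interface sample in: 1086.7 mg C m-2 d-1
  inflated <- integrate_profile(p, "abd", exclude_flags = character(0))$value
  expect_equal(inflated, 1086.65, tolerance = 1e-3)
  # ND values are skipped silently from the usable set
  pn <- make_profile(c(200, 800, 1500), c(100, NA, 100), 1500)
  expect_equal(integrate_profile(pn, "abd")$value,
               integrate_profile(make_profile(c(200, 1500), c(100, 100),
                                              1500), "abd")$value)
  expect_error(integrate_profile(make_profile(300, 10, 400), "abd",
                                 z_top = 500), "no usable")
})

test_that("delta-method sd matches closed forms and the hand quadrature", {
  z4 <- c(200, 400, 2500, 3500); r4 <- c(114, 231, 59, 48)
  p0 <- make_profile(z4, r4, 3571, sds = rep(0, 4))
  expect_equal(propagate_integral_sd(p0, "abd"), 0)
  # single point, sd s, thickness h -> s x h / 1e3
  p1 <- make_profile(500, 100, 1500, sds = 7)
  expect_equal(suppressWarnings(propagate_integral_sd(p1, "abd")),
               7 * 1000 / 1e3)
  # hand quadrature with weights 100, 1150, 1550, 571
  p4 <- make_profile(z4, r4, 3571, sds = c(14, 21, 9, 6))
  hand <- sqrt(sum((c(100, 1150, 1550, 571) * c(14, 21, 9, 6))^2)) / 1e3
  expect_equal(propagate_integral_sd(p4, "abd"), hand)
  expect_equal(hand, 28.1, tolerance = 1e-2)
  # missing sds -> NA
  pna <- make_profile(z4, r4, 3571, sds = c(14, NA, 9, 6))
  expect_true(is.na(propagate_integral_sd(pna, "abd")))
})

test_that("profile container enforces ordering and geometry", {
  expect_error(station_profile("X", 1000,
                               tibble::tibble(depth_m = c(500, 300))),
               "ascending")
  expect_error(station_profile("X", 400,
                               tibble::tibble(depth_m = c(200, 500))),
               "bottom")
})
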