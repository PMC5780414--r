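# Per-depth oracles are hand arithmetic on the bundled station table, e.g.
# ST7/3000 m: PGE = 125.3 / (125.3 + 662) = 0.1592; ST1/200 m:
# csPCD = (19.4 + 967) x 1e3 / 240e3 = 4.11 fg C cell-1 d-1.

test_that("carbon demand adds production and respiration, propagating ND", {
  expect_equal(carbon_demand(19.4, 967), 986.4)
  expect_equal(carbon_demand(125.3, 662), 787.3)
  expect_equal(carbon_demand(0, 0), 0)
  expect_true(is.na(carbon_demand(NA, 662)))
  expect_error(carbon_demand(-1, 5), ">= 0")
})

test_that("growth efficiency matches hand arithmetic and edge cases", {
  expect_equal(growth_efficiency(125.3, 662), 0.1592, tolerance = 1e-3)
  expect_equal(growth_efficiency(5.5, 1577), 0.00347, tolerance = 1e-2)
  expect_equal(growth_efficiency(0, 10), 0)
  expect_warning(g <- growth_efficiency(0, 0), "undefined")
  expect_true(is.na(g))
})

test_that("growth efficiency is scale-invariant", {
  for (k in c(0.1, 2, 40)) {
    expect_equal(growth_efficiency(k * 12.7, k * 1761),
                 growth_efficiency(12.7, 1761))
  }
})

test_that("cell-specific rates follow the unit ladder", {
  expect_equal(round(cell_specific(986.4, 240e3), 2), 4.11)
  expect_equal(round(cell_specific(207, 53e3), 2), 3.91)
  expect_equal(cell_specific(0, 1e5), 0)
  expect_error(cell_specific(10, 0), "positive")
  # round trip: cs x pa recovers the volumetric rate
  pcd <- carbon_demand(19.4, 967)
  expect_equal(cell_specific(pcd, 240e3) * 240e3 / 1e3, pcd)
})

test_that("ABD share of carbon demand in percent", {
  expect_equal(abd_fraction_of_pcd(48, 953.8), 5.0, tolerance = 1e-2)
  expect_equal(abd_fraction_of_pcd(370, 675.0), 54.8, tolerance = 1e-3)
  expect_equal(abd_fraction_of_pcd(0, 100), 0)
  expect_warning(p <- abd_fraction_of_pcd(1, 0), "undefined")
  expect_true(is.na(p))
})

test_that("generation times bracket the cell-carbon range", {
  gt <- generation_time_range(3.91, c(10, 20))
  expect_equal(unname(gt), c(2.56, 5.12), tolerance = 1e-3)
  gt_slow <- generation_time_range(0.38, c(10, 20))
  expect_equal(unname(gt_slow), c(26.3, 52.6), tolerance = 1e-3)
  expect_equal(unname(generation_time_range(10, c(10, 10))), c(1, 1))
  expect_warning(gt0 <- generation_time_range(0), "unbounded")
  expect_true(all(is.na(gt0)))
})

test_that("per-protein fixation converts to per-cell rates", {
  expect_equal(scm1_cell_specific_rate(39, 3e7, 0.6, 0.60), 5.6,
               tolerance = 1e-2)
  expect_equal(scm1_cell_specific_rate(39, 3e7, 0.6, 0.40), 3.7,
               tolerance = 2e-2)
  expect_equal(scm1_cell_specific_rate(0, 3e7, 0.6, 0.5), 0)
  expect_error(scm1_cell_specific_rate(39, 3e7, 0.6, 1.2), "0, 1")
})

test_that("derived metric table reproduces the campaign extrema", {
  m <- derive_metrics(med_samples())
  med <- m[m$station_id != "ST1" & m$flags == "", ] # Mediterranean rows
  expect_equal(round(min(med$cs_abd, na.rm = TRUE), 2), 0.38)
  expect_equal(round(max(med$cs_abd, na.rm = TRUE), 2), 3.91)
  expect_equal(round(max(m$cs_pcd, na.rm = TRUE), 2), 19.87)
  expect_equal(round(min(m$cs_pcd, na.rm = TRUE), 2), 1.72)
  expect_equal(round(100 * max(m$pge, na.rm = TRUE)), 16)
  expect_equal(round(100 * min(m$pge, na.rm = TRUE), 1), 0.3)
  # ND stays ND: the ST2/400 m PHP gap propagates
  expect_true(is.na(m$pcd[m$station_id == "ST2" & m$depth_m == 400]))
})
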