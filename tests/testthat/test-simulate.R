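test_that("scenarios are reproducible and template-shaped", {
  a <- make_scenario("mediterranean-deep", seed = 5)
  b <- make_scenario("mediterranean-deep", seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, make_scenario("mediterranean-deep", seed = 6)))
  u <- make_scenario("uniform")
  expect_true(all(u$true_abd == u$true_abd[1]))
  expect_error(make_scenario("abyssal-vent"), "arg")
})

test_that("mediterranean template draws stay inside the basin envelopes", {
  draws <- lapply(1:200, function(s) make_scenario("mediterranean-deep",
                                                   seed = s))
  abd <- unlist(lapply(draws, `[[`, "true_abd"))
  pr <- unlist(lapply(draws, `[[`, "true_pr"))
  php <- unlist(lapply(draws, `[[`, "true_php"))
  pa <- unlist(lapply(draws, `[[`, "true_pa"))
  expect_true(all(abd >= 48 & abd <= 411))
  expect_true(all(pr >= 204 & pr <= 1761))
  expect_true(all(php >= 3.8 & php <= 125.3))
  expect_true(all(pa >= 48e3 & pa <= 460e3))
})

test_that("simulation is deterministic given the seed", {
  s1 <- simulate_campaign(make_scenario("mediterranean-deep", seed = 3))
  s2 <- simulate_campaign(make_scenario("mediterranean-deep", seed = 3))
  expect_identical(s1$incubations, s2$incubations)
  expect_identical(s1$abundance, s2$abundance)
  expect_identical(s1$dilution, s2$dilution)
})

test_that("zero-noise campaigns invert exactly for every variable", {
  for (tpl in c("uniform", "mediterranean-deep", "atlantic-cold")) {
    sc <- make_scenario(tpl, overrides = list(noise = list(replicate_cv = 0)),
                        seed = 11)
    rec <- recover_campaign(simulate_campaign(sc))
    r <- rec$samples[order(rec$samples$depth_m), ]
    expect_equal(r$php, sc$true_php, tolerance = 1e-10)
    expect_equal(r$abd, sc$true_abd, tolerance = 1e-10)
    expect_equal(r$pr, sc$true_pr, tolerance = 1e-10)
    expect_equal(r$pa, sc$true_pa, tolerance = 1e-10)
    # the matched-truth dilution series returns the configured ID exactly
    expect_equal(rec$isotope_dilution$id,
                 (sc$assay$kt_plus_sn + sc$assay$dilution_hot) /
                   sc$assay$dilution_hot, tolerance = 1e-9)
    # and the integral of the recovered profile equals the truth integral
    rep <- recovery_report(sc, rec$samples)
    expect_lt(abs(rep$rmse_rel[rep$variable == "abd_integral"]), 1e-10)
  }
})

test_that("recovery report flags bias and mismatched grids", {
  sc <- make_scenario("uniform", seed = 2)
  perfect <- tibble::tibble(depth_m = sc$depth_m, php = sc$true_php,
                            pr = sc$true_pr, abd = sc$true_abd,
                            pa = sc$true_pa)
  rep0 <- recovery_report(sc, perfect)
  expect_true(all(rep0$bias_rel == 0))
  expect_true(all(rep0$rmse_rel == 0))
  inflated <- dplyr::mutate(perfect, abd = abd * 1.1)
  rep1 <- recovery_report(sc, inflated)
  expect_equal(rep1$bias_rel[rep1$variable == "abd"], 0.1, tolerance = 1e-9)
  bad <- dplyr::mutate(perfect, depth_m = depth_m + 5)
  expect_error(recovery_report(sc, bad), "grid")
})

test_that("blank-dominated depths exercise the clamp path", {
  sc <- make_scenario("uniform",
                      overrides = list(true_abd = rep(0, 3),
                                       noise = list(replicate_cv = 0.3)),
                      seed = 13)
  rec <- suppressWarnings(recover_campaign(simulate_campaign(sc)))
  expect_true(all(rec$samples$abd >= 0))
})
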