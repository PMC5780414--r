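#' Build a ground-truth campaign scenario
#'
#' Constructs the truth a simulated sampling campaign is generated from:
#' a depth grid with bottom depth and temperatures, true volumetric rate
#' profiles (PHP, PR, ABD), true cell abundances, the DIC pool, the assay
#' geometry, and the counting-noise model. Three templates are provided:
#'
#' * `"mediterranean-deep"` — warm homothermal deep water; per-depth truths
#'   drawn uniformly inside the deep Mediterranean envelopes
#'   (ABD 48-411, PR 204-1761, PHP 3.8-125.3 ug C m-3 d-1,
#'   PA 48e3-460e3 cells mL-1).
#' * `"atlantic-cold"` — cold deep water with exponentially decaying rates.
#' * `"uniform"` — constant profiles, the analytic edge case.
#'
#' The default noise model is lognormal with a fixed 5% replicate CV
#' (mean-matched, so estimators stay unbiased) on top of a 100 DPM blank;
#' replicate CVs of deep-water count data typically exceed the Poisson floor
#' because pipetting and filtration dominate, but a `"poisson"` counting
#' model is available.
#'
#' @param template One of `"mediterranean-deep"`, `"atlantic-cold"`,
#'   `"uniform"`.
#' @param overrides Named list replacing any scenario field (e.g.
#'   `list(noise = list(replicate_cv = 0))` for a noise-free campaign;
#'   partial `noise`/`assay` lists are merged field-wise).
#' @param seed Integer; the same (template, overrides, seed) always yields
#'   the identical scenario and, through [simulate_campaign()], identical
#'   observations.
#' @return An object of class `abd_scenario`.
#' @export
make_scenario <- function(template = c("mediterranean-deep", "atlantic-cold",
                                       "uniform"),
                          overrides = list(), seed = 1) {
  template <- match.arg(template)
  base <- switch(
    template,
    "mediterranean-deep" = {
      depth <- c(200, 500, 1000, 2000, 3000)
      draws <- withr_seed(seed, function() {
        list(abd = stats::runif(length(depth), 48, 411),
             pr = stats::runif(length(depth), 204, 1761),
             php = stats::runif(length(depth), 3.8, 125.3),
             pa = stats::runif(length(depth), 48e3, 460e3))
      })
      list(station_id = "SIM-MED", depth_m = depth, bottom_depth = 3600,
           temp_c = c(14.6, 14.1, 13.8, 13.8, 13.9),
           true_php = draws$php, true_pr = draws$pr, true_abd = draws$abd,
           true_pa = draws$pa, dic = 2.3)
    },
    "atlantic-cold" = {
      depth <- c(200, 750, 2000, 2700)
      list(station_id = "SIM-ATL", depth_m = depth, bottom_depth = 2735,
           temp_c = c(14.1, 11.7, 4.6, 3.1),
           true_php = 20 * exp(-(depth - 200) / 1200),
           true_pr = 950 * exp(-(depth - 200) / 1800),
           true_abd = 400 * exp(-(depth - 200) / 450),
           true_pa = 2.4e5 * exp(-(depth - 200) / 2200), dic = 2.2)
    },
    "uniform" = {
      depth <- c(200, 700, 1200)
      list(station_id = "SIM-UNI", depth_m = depth, bottom_depth = 1250,
           temp_c = rep(14, 3),
           true_php = rep(20, 3), true_pr = rep(600, 3),
           true_abd = rep(100, 3), true_pa = rep(1e5, 3), dic = 2.3)
    }
  )
  sc <- c(base, list(
    template = template,
    assay = list(
      leu_volume = 1.7e-3, leu_sa = 144.2, leu_time = 2.5, leu_hot = 20,
      bic_volume = 40, bic_added = 0.25, bic_sa = 56.0, bic_time = 72,
      ets_assay_temp = 18,
      dilution_hot = 5, dilution_cold = c(0, 2.5, 5, 10, 20, 40),
      dilution_added_dpm = 1e5, kt_plus_sn = 1.4,
      cf = 1.92
    ),
    noise = list(replicate_cv = 0.05, blank_dpm_mean = 100,
                 counting_model = "lognormal-cv",
                 n_rep = 3L, n_blank = 2L, n_pa = 2L, n_ets = 2L),
    seed = seed
  ))
  for (nm in names(overrides)) {
    if (nm %in% c("noise", "assay") && is.list(overrides[[nm]])) {
      sc[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    } else {
      sc[[nm]] <- overrides[[nm]]
    }
  }
  stopifnot(length(sc$depth_m) == length(sc$true_abd),
            all(sc$true_php >= 0), all(sc$true_pr >= 0),
            all(sc$true_abd >= 0), all(sc$true_pa > 0),
            sc$noise$replicate_cv >= 0)
  structure(sc, class = "abd_scenario")
}

# Run `fn` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

# Mean-matched multiplicative counting noise.
noisy <- function(n, mean, cv, model = "lognormal-cv") {
  if (cv == 0 || mean == 0) return(rep(mean, n))
  if (model == "poisson") {
    # cv is ignored; variance = mean, the counting floor
    return(stats::rpois(n, mean))
  }
  sigma <- sqrt(log(1 + cv^2))
  mean * exp(stats::rnorm(n, -sigma^2 / 2, sigma))
}

#' Forward-simulate the raw observations of a campaign
#'
#' Generates, for every depth of a scenario, the raw observations whose
#' expected values are the exact analytic inverses of the rate calculus at
#' the scenario truth: triplicate leucine and bicarbonate DPM with
#' duplicate positive blanks, duplicate ETS assay values at the assay
#' temperature, duplicate cell counts, and one leucine dilution series per
#' station generated from the configured true Kt + Sn. At zero noise the
#' pipeline therefore recovers every truth exactly; under noise, unbiasedly.
#'
#' @param scenario An [make_scenario()] object.
#' @param constants An [abd_constants()] bundle (must match the one used to
#'   invert).
#' @return A list of class `abd_campaign_sim`: `incubations` (long tibble,
#'   one row per replicate measurement), `abundance`, `dilution`, and the
#'   `scenario`.
#' @export
simulate_campaign <- function(scenario, constants = abd_constants()) {
  stopifnot(inherits(scenario, "abd_scenario"))
  nz <- scenario$noise
  as_ <- scenario$assay
  withr_seed(scenario$seed + 1L, function() {
    rows <- list()
    abun <- list()
    for (i in seq_along(scenario$depth_m)) {
      z <- scenario$depth_m[i]
      ti <- scenario$temp_c[i]
      common <- list(station_id = scenario$station_id, depth_m = z)

      leu_tpl <- leucine_incubation(1, 0, sample_volume = as_$leu_volume,
                                    hot_leucine = as_$leu_hot,
                                    specific_activity = as_$leu_sa,
                                    incubation_time = as_$leu_time)
      net_leu <- scenario$true_php[i] /
        php_dpm_to_rate(leu_tpl, as_$cf, constants)
      bic_tpl <- bicarbonate_incubation(1, 0, sample_volume = as_$bic_volume,
                                        added_activity = as_$bic_added,
                                        specific_activity = as_$bic_sa,
                                        dic = scenario$dic,
                                        incubation_time = as_$bic_time)
      net_bic <- scenario$true_abd[i] /
        abd_dpm_to_rate(bic_tpl, scenario$dic, constants)
      # true PR at in situ temperature, expressed back at assay temperature
      ets_true <- arrhenius_correct(
        scenario$true_pr[i] /
          (constants$pr_to_ets * constants$c_to_o2_molar *
             constants$carbon_molar_mass),
        t_assay = ti, t_insitu = as_$ets_assay_temp,
        ea = constants$ea_ets, gas_constant = constants$gas_constant)

      emit <- function(assay, role, values, ...) {
        tibble::tibble(
          station_id = scenario$station_id, depth_m = z, assay = assay,
          role = role, replicate = seq_along(values), value = values, ...
        )
      }
      cv <- nz$replicate_cv
      mdl <- nz$counting_model
      rows[[length(rows) + 1L]] <- dplyr::bind_rows(
        emit("leu", "sample",
             noisy(nz$n_rep, net_leu + nz$blank_dpm_mean, cv, mdl),
             unit = "dpm", volume = as_$leu_volume,
             specific_activity = as_$leu_sa, incubation_h = as_$leu_time,
             hot_nM = as_$leu_hot),
        emit("leu", "blank", noisy(nz$n_blank, nz$blank_dpm_mean, cv, mdl),
             unit = "dpm", volume = as_$leu_volume,
             specific_activity = as_$leu_sa, incubation_h = as_$leu_time,
             hot_nM = as_$leu_hot),
        emit("bic", "sample",
             noisy(nz$n_rep, net_bic + nz$blank_dpm_mean, cv, mdl),
             unit = "dpm", volume = as_$bic_volume,
             added_activity = as_$bic_added,
             specific_activity = as_$bic_sa, incubation_h = as_$bic_time,
             dic_mmol_l = scenario$dic),
        emit("bic", "blank", noisy(nz$n_blank, nz$blank_dpm_mean, cv, mdl),
             unit = "dpm", volume = as_$bic_volume,
             added_activity = as_$bic_added,
             specific_activity = as_$bic_sa, incubation_h = as_$bic_time,
             dic_mmol_l = scenario$dic),
        emit("ets", "sample", noisy(nz$n_ets, ets_true, cv, "lognormal-cv"),
             unit = "umol_o2_m3_d", t_assay_c = as_$ets_assay_temp,
             t_insitu_c = ti)
      )
      abun[[length(abun) + 1L]] <- tibble::tibble(
        station_id = scenario$station_id, depth_m = z,
        replicate = seq_len(nz$n_pa),
        pa_cells_ml = noisy(nz$n_pa, scenario$true_pa[i], cv, "lognormal-cv")
      )
    }
    # one dilution series per station: f = t * vmax / (Kt + Sn + hot + A)
    vmax <- 0.5 # nmol L-1 h-1; cancels out of the ID estimate
    f_true <- as_$leu_time * vmax /
      (as_$kt_plus_sn + as_$dilution_hot + as_$dilution_cold)
    f_obs <- f_true * noisy(length(f_true), 1, nz$replicate_cv, "lognormal-cv")
    dilution <- tibble::tibble(
      station_id = scenario$station_id,
      hot_nM = as_$dilution_hot, cold_nM = as_$dilution_cold,
      net_dpm = f_obs * as_$dilution_added_dpm,
      added_dpm = as_$dilution_added_dpm,
      incubation_h = as_$leu_time
    )
    structure(
      list(incubations = dplyr::bind_rows(rows),
           abundance = dplyr::bind_rows(abun),
           dilution = dilution, scenario = scenario),
      class = "abd_campaign_sim"
    )
  })
}

#' Invert a simulated campaign back to rate profiles
#'
#' Runs the full rate calculus on the raw observations of a simulated
#' campaign: [php_rate()] and [abd_rate()] on the tracer incubations,
#' [pr_from_ets()] per ETS replicate, replicate means for cell abundance,
#' and [estimate_isotope_dilution()] on the dilution series.
#'
#' @param sim An [simulate_campaign()] result (or a compatible list of
#'   tibbles read back from files).
#' @param constants An [abd_constants()] bundle.
#' @param cf Leucine conversion factor; defaults to the one the scenario
#'   used if available, else base x mean ID from `constants`.
#' @return A list: `samples` (tibble station_id, depth_m, php, php_sd, pr,
#'   pr_sd, abd, abd_sd, pa, pa_sd), `isotope_dilution` (one-row tibble per
#'   station).
#' @export
recover_campaign <- function(sim, constants = abd_constants(), cf = NULL) {
  if (is.null(cf)) {
    cf <- if (!is.null(sim$scenario)) sim$scenario$assay$cf else
      leucine_conversion_factor(constants$leu_to_carbon_base,
                                constants$mean_isotope_dilution_leu)
  }
  rates <- compute_rates(sim$incubations, constants = constants, cf = cf)
  pa <- dplyr::summarise(
    dplyr::group_by(sim$abundance, .data$station_id, .data$depth_m),
    pa = mean(.data$pa_cells_ml),
    pa_sd = ifelse(dplyr::n() > 1, stats::sd(.data$pa_cells_ml), 0),
    .groups = "drop")
  samples <- dplyr::left_join(rates, pa, by = c("station_id", "depth_m"))
  id <- NULL
  if (!is.null(sim$dilution) && nrow(sim$dilution)) {
    id <- dplyr::bind_rows(lapply(
      split(sim$dilution, sim$dilution$station_id), function(d) {
        est <- estimate_isotope_dilution(dilution_series(
          hot_conc = d$hot_nM[1], cold_conc = d$cold_nM,
          net_dpm = d$net_dpm, added_dpm = d$added_dpm,
          incubation_time = d$incubation_h[1]))
        tibble::tibble(station_id = d$station_id[1], id = est$id,
                       kt_plus_sn = est$kt_plus_sn, v_max = est$v_max)
      }))
  }
  list(samples = samples, isotope_dilution = id)
}

#' Parameter-recovery report
#'
#' Compares recovered per-depth estimates against the scenario truth,
#' per variable: relative bias, relative RMSE, and the coverage of nominal
#' +/-2 sd intervals, where the nominal sd is the noise-model sd of the
#' estimator (truth x replicate CV / sqrt(number of replicates)). A final
#' row compares the depth-integrated ABD of the recovered profile against
#' the truth's integral.
#'
#' @param scenario The [make_scenario()] truth.
#' @param recovered The `samples` tibble of [recover_campaign()] (or any
#'   tibble with matching `depth_m` and rate columns).
#' @param constants An [abd_constants()] bundle.
#' @return A tibble: `variable`, `n`, `bias_rel`, `rmse_rel`, `coverage`.
#' @export
recovery_report <- function(scenario, recovered,
                            constants = abd_constants()) {
  stopifnot(inherits(scenario, "abd_scenario"), is.data.frame(recovered))
  recovered <- recovered[order(recovered$depth_m), ]
  if (!isTRUE(all.equal(recovered$depth_m, scenario$depth_m))) {
    stop("recovered depth grid does not match the scenario", call. = FALSE)
  }
  cv <- scenario$noise$replicate_cv
  nz <- scenario$noise
  as_ <- scenario$assay
  # Nominal estimator sd under the noise model. For the tracer rates the
  # blank subtraction contributes: sd(net) = sqrt((net+b)^2 cv^2 / n_rep +
  # b^2 cv^2 / n_blank), scaled linearly to rate units; for ETS-PR and PA
  # it is the plain replicate-mean sd, truth x cv / sqrt(n).
  tracer_sd <- function(truth, scale) {
    net <- truth / scale
    b <- nz$blank_dpm_mean
    scale * sqrt((net + b)^2 * cv^2 / nz$n_rep + b^2 * cv^2 / nz$n_blank)
  }
  leu_scale <- php_dpm_to_rate(
    leucine_incubation(1, 0, sample_volume = as_$leu_volume,
                       hot_leucine = as_$leu_hot,
                       specific_activity = as_$leu_sa,
                       incubation_time = as_$leu_time), as_$cf, constants)
  bic_scale <- abd_dpm_to_rate(
    bicarbonate_incubation(1, 0, sample_volume = as_$bic_volume,
                           added_activity = as_$bic_added,
                           specific_activity = as_$bic_sa,
                           dic = scenario$dic,
                           incubation_time = as_$bic_time),
    scenario$dic, constants)
  spec <- list(
    php = list(truth = scenario$true_php,
               sd = tracer_sd(scenario$true_php, leu_scale)),
    pr = list(truth = scenario$true_pr,
              sd = scenario$true_pr * cv / sqrt(nz$n_ets)),
    abd = list(truth = scenario$true_abd,
               sd = tracer_sd(scenario$true_abd, bic_scale)),
    pa = list(truth = scenario$true_pa,
              sd = scenario$true_pa * cv / sqrt(nz$n_pa))
  )
  rows <- lapply(names(spec), function(v) {
    if (!v %in% names(recovered)) return(NULL)
    est <- recovered[[v]]
    truth <- spec[[v]]$truth
    ok <- truth > 0
    rel <- (est[ok] - truth[ok]) / truth[ok]
    cover <- if (cv > 0) {
      mean(abs(est[ok] - truth[ok]) <= 2 * spec[[v]]$sd[ok])
    } else NA_real_
    tibble::tibble(variable = v, n = sum(ok), bias_rel = mean(rel),
                   rmse_rel = sqrt(mean(rel^2)), coverage = cover)
  })
  out <- dplyr::bind_rows(rows)
  if ("abd" %in% names(recovered)) {
    truth_prof <- station_profile(
      scenario$station_id, scenario$bottom_depth,
      tibble::tibble(depth_m = scenario$depth_m, abd = scenario$true_abd))
    est_prof <- station_profile(
      scenario$station_id, scenario$bottom_depth,
      tibble::tibble(depth_m = recovered$depth_m, abd = recovered$abd))
    it <- integrate_profile(truth_prof, "abd",
                            z_top = min(scenario$depth_m))$value
    ie <- integrate_profile(est_prof, "abd",
                            z_top = min(scenario$depth_m))$value
    out <- dplyr::bind_rows(out, tibble::tibble(
      variable = "abd_integral", n = 1L, bias_rel = (ie - it) / it,
      rmse_rel = abs(ie - it) / it, coverage = NA_real_))
  }
  out
}
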