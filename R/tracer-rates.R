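#' Blank-corrected net disintegrations
#'
#' Subtracts the mean of the killed-control DPM from the mean of the live
#' replicates, clamping at zero: incorporation is a physical non-negative,
#' and blank-dominated deep samples occasionally count below their controls.
#' A clamp is reported via warning so it is never silent.
#'
#' @param replicate_dpm Live-sample DPM values.
#' @param blank_dpm Killed-control DPM values.
#' @return A list with `net` (mean difference, clamped at 0), `sd` (standard
#'   deviation of the live replicates; 0 for a single replicate), and `n`
#'   (number of live replicates).
#' @examples
#' net_dpm(c(600, 610, 590), c(100, 100))$net # 500
#' @export
net_dpm <- function(replicate_dpm, blank_dpm) {
  check_dpm(replicate_dpm, blank_dpm)
  net <- mean(replicate_dpm) - mean(blank_dpm)
  if (net < 0) {
    warning("net DPM below zero (blank exceeds sample); clamped to 0",
            call. = FALSE)
    net <- 0
  }
  s <- if (length(replicate_dpm) > 1L) stats::sd(replicate_dpm) else 0
  list(net = net, sd = s, n = length(replicate_dpm))
}

#' Prokaryotic heterotrophic production from a leucine incubation
#'
#' Converts blank-corrected [3H]-leucine incorporation into a carbon
#' production rate. Net DPM become moles of leucine through the specific
#' activity, are normalised by incubated volume and time, and scale to
#' carbon by the dilution-inflated conversion factor (1.92 kg C mol-1 leu at
#' the mean ID of 1.28). Uncertainty is the replicate DPM scatter passed
#' through the same (linear) chain.
#'
#' @param inc A [leucine_incubation()].
#' @param cf Leucine-to-carbon conversion factor, kg C mol-1.
#' @param constants An [abd_constants()] bundle.
#' @return A list with `rate` and `sd` (ug C m-3 d-1), `se` (sd / sqrt(n)),
#'   and `net_dpm`.
#' @examples
#' inc <- leucine_incubation(c(666.9, 666.9, 666.9), c(100, 100))
#' php_rate(inc, cf = 1.92)$rate # 19.2
#' @export
php_rate <- function(inc, cf, constants = abd_constants()) {
  stopifnot(inherits(inc, "leucine_incubation"))
  if (!is.numeric(cf) || cf <= 0) stop("`cf` must be positive", call. = FALSE)
  nd <- net_dpm(inc$replicate_dpm, inc$blank_dpm)
  scale <- php_dpm_to_rate(inc, cf, constants)
  list(rate = nd$net * scale, sd = nd$sd * scale,
       se = nd$sd * scale / sqrt(nd$n), net_dpm = nd$net)
}

# ug C m-3 d-1 per net DPM; shared with the forward simulator's inverse.
php_dpm_to_rate <- function(inc, cf, constants = abd_constants()) {
  dpm_per_ci <- constants$dpm_per_uci * 1e6
  mmol_leu_per_dpm <- 1 / (dpm_per_ci * inc$specific_activity)
  days <- inc$incubation_time / 24
  # mmol L-1 d-1 -> ug C m-3 d-1: cf kg C mol-1 = 1e6 ug C mmol-1, x 1e3 L m-3
  mmol_leu_per_dpm / (inc$sample_volume * days) * cf * 1e6 * 1e3
}

#' Dark bicarbonate assimilation from a 14C incubation
#'
#' The fraction of added label recovered in biomass, times the ambient DIC
#' pool (the full isotope-dilution correction: the tracer is a vanishing
#' fraction of a ~500-fold larger pool), per incubation day. Uncertainty is
#' replicate scatter through the linear chain.
#'
#' @param inc A [bicarbonate_incubation()].
#' @param constants An [abd_constants()] bundle; supplies the basin default
#'   DIC only if the record carries none and `require_dic = FALSE`.
#' @param require_dic If `TRUE` (default), a record without DIC errors,
#'   instructing the caller to supply the basin default explicitly.
#' @return A list with `rate`, `sd`, `se` (ug C m-3 d-1), `net_dpm`, and the
#'   `dic` used.
#' @examples
#' inc <- bicarbonate_incubation(c(582.6, 582.6, 582.6), c(100, 100),
#'                               dic = 2.3)
#' abd_rate(inc)$rate # 200
#' @export
abd_rate <- function(inc, constants = abd_constants(), require_dic = TRUE) {
  stopifnot(inherits(inc, "bicarbonate_incubation"))
  dic <- inc$dic
  if (is.null(dic)) {
    if (require_dic) {
      stop("incubation carries no DIC; supply one (e.g. the basin default ",
           "constants$dic_default = ", constants$dic_default,
           " mmol L-1) or set require_dic = FALSE", call. = FALSE)
    }
    dic <- constants$dic_default
  }
  nd <- net_dpm(inc$replicate_dpm, inc$blank_dpm)
  scale <- abd_dpm_to_rate(inc, dic, constants)
  list(rate = nd$net * scale, sd = nd$sd * scale,
       se = nd$sd * scale / sqrt(nd$n), net_dpm = nd$net, dic = dic)
}

# ug C m-3 d-1 per net DPM at a given DIC (mmol L-1).
abd_dpm_to_rate <- function(inc, dic, constants = abd_constants()) {
  added_dpm <- inc$added_activity * inc$sample_volume * constants$dpm_per_uci
  days <- inc$incubation_time / 24
  # fraction fixed x DIC(mmol L-1) x 1e3 umol mmol-1 x 12 ug umol-1 / d,
  # then x 1e3 L m-3.
  (1 / added_dpm) * dic * 1e3 * constants$carbon_molar_mass / days * 1e3
}

#' Isotope dilution by the kinetic (Pollard-Moriarty) method
#'
#' Fits the linearisation of saturable substrate uptake in which the
#' incubation time over the fraction of added label incorporated, t/f, is
#' linear in the added unlabelled substrate concentration A:
#' t/f = (Kt + Sn + hot + A) / Vmax. The slope recovers 1/Vmax, the
#' intercept (Kt + Sn + hot)/Vmax, and the isotope dilution follows as
#' ID = (Kt + Sn + hot) / hot = intercept / (slope x hot).
#'
#' @param series A [dilution_series()].
#' @return A list with `id`, `v_max` (nmol L-1 h-1 on the concentration
#'   scale of the series), `kt_plus_sn` (nmol L-1), and the fitted `slope`
#'   and `intercept` of the t/f-vs-A line.
#' @export
estimate_isotope_dilution <- function(series) {
  stopifnot(inherits(series, "dilution_series"))
  f <- series$net_dpm / series$added_dpm
  if (any(!is.finite(f)) || any(f <= 0)) {
    stop("all incorporated fractions must be finite and positive",
         call. = FALSE)
  }
  if (stats::var(series$cold_conc) == 0) {
    stop("degenerate dilution series: zero variance in cold concentrations",
         call. = FALSE)
  }
  t_over_f <- series$incubation_time / f
  fit <- stats::lm(t_over_f ~ series$cold_conc)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (slope <= 0) {
    stop("non-positive fitted slope: series is inconsistent with saturable ",
         "uptake", call. = FALSE)
  }
  v_max <- 1 / slope
  kt_plus_sn <- intercept / slope - series$hot_conc
  id <- (kt_plus_sn + series$hot_conc) / series$hot_conc
  if (kt_plus_sn < 0) {
    warning("fitted Kt + Sn is negative; isotope dilution clamped to 1",
            call. = FALSE)
    id <- 1
    kt_plus_sn <- 0
  }
  list(id = id, v_max = v_max, kt_plus_sn = kt_plus_sn,
       slope = slope, intercept = intercept)
}

#' Time-course linearity fit
#'
#' Ordinary least-squares line through an incorporation time course, with
#' the Pearson correlation the caller compares against an acceptance
#' threshold (0.98 by convention) before trusting a single-endpoint
#' incubation.
#'
#' @param times Incubation times, hours (>= 3 points).
#' @param responses Incorporation responses (DPM or rate units).
#' @return A list with `slope`, `intercept`, `correlation`.
#' @export
fit_linearity <- function(times, responses) {
  if (length(times) < 3L || length(responses) != length(times)) {
    stop("need >= 3 aligned time points", call. = FALSE)
  }
  fit <- stats::lm(responses ~ times)
  r <- if (stats::var(responses) == 0) NA_real_ else stats::cor(times, responses)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       correlation = r)
}
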