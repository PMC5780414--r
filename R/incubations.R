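#' Radiotracer and respiration assay records
#'
#' Lightweight validated containers for the raw observations the rate
#' calculus inverts: triplicate live incubations against duplicate killed
#' blanks, with the assay geometry (volume, specific activity, incubation
#' time) attached. Defaults are the micro-method leucine protocol (1.7 mL,
#' 20 nmol L-1 hot leucine at 144.2 Ci mmol-1, 2.5 h) and the gas-tight
#' bicarbonate protocol (40 mL, 0.25 uCi mL-1 at 56.0 mCi mmol-1, 72 h).
#'
#' @param replicate_dpm Numeric vector of live-sample DPM (typically n = 3).
#' @param blank_dpm Numeric vector of killed-control DPM (typically n = 2).
#' @param sample_volume Incubated volume; litres for leucine, millilitres
#'   for bicarbonate (the conventions of the respective protocols).
#' @param hot_leucine Added labelled leucine, nmol L-1.
#' @param specific_activity Stock specific activity; Ci mmol-1 for leucine,
#'   mCi mmol-1 for bicarbonate.
#' @param incubation_time Incubation length, hours.
#' @return A validated list of class `leucine_incubation`.
#' @name incubation-records
NULL

check_dpm <- function(replicate_dpm, blank_dpm) {
  if (length(replicate_dpm) < 1L || length(blank_dpm) < 1L) {
    stop("need at least one replicate and one blank DPM value", call. = FALSE)
  }
  if (!is.numeric(replicate_dpm) || !is.numeric(blank_dpm) ||
      any(!is.finite(c(replicate_dpm, blank_dpm))) ||
      any(c(replicate_dpm, blank_dpm) < 0)) {
    stop("DPM values must be finite and non-negative", call. = FALSE)
  }
  invisible(TRUE)
}

#' @rdname incubation-records
#' @export
leucine_incubation <- function(replicate_dpm, blank_dpm,
                               sample_volume = 1.7e-3,
                               hot_leucine = 20,
                               specific_activity = 144.2,
                               incubation_time = 2.5) {
  check_dpm(replicate_dpm, blank_dpm)
  if (sample_volume <= 0 || specific_activity <= 0 || incubation_time <= 0 ||
      hot_leucine <= 0) {
    stop("volume, specific activity, hot leucine and time must be positive",
         call. = FALSE)
  }
  structure(
    list(replicate_dpm = replicate_dpm, blank_dpm = blank_dpm,
         sample_volume = sample_volume, hot_leucine = hot_leucine,
         specific_activity = specific_activity,
         incubation_time = incubation_time),
    class = "leucine_incubation"
  )
}

#' @rdname incubation-records
#' @param added_activity Final added activity, uCi per mL of sample.
#' @param dic Ambient dissolved inorganic carbon, mmol L-1; `NULL` means the
#'   caller must supply the basin default at rate time.
#' @export
bicarbonate_incubation <- function(replicate_dpm, blank_dpm,
                                   sample_volume = 40,
                                   added_activity = 0.25,
                                   specific_activity = 56.0,
                                   dic = NULL,
                                   incubation_time = 72) {
  check_dpm(replicate_dpm, blank_dpm)
  if (sample_volume <= 0 || added_activity <= 0 || specific_activity <= 0 ||
      incubation_time <= 0) {
    stop("volume, activities and time must be positive", call. = FALSE)
  }
  if (!is.null(dic) && (!is.numeric(dic) || dic <= 0)) {
    stop("`dic` must be positive (mmol L-1) when supplied", call. = FALSE)
  }
  structure(
    list(replicate_dpm = replicate_dpm, blank_dpm = blank_dpm,
         sample_volume = sample_volume, added_activity = added_activity,
         specific_activity = specific_activity, dic = dic,
         incubation_time = incubation_time),
    class = "bicarbonate_incubation"
  )
}

#' @rdname incubation-records
#' @param hot_conc Fixed labelled leucine concentration, nmol L-1.
#' @param cold_conc Added unlabelled leucine per observation, nmol L-1
#'   (vectorised; needs >= 3 distinct levels for the kinetic fit).
#' @param net_dpm Blank-corrected incorporated DPM per observation.
#' @param added_dpm Total DPM of label added per vial (scalar or vector).
#' @export
dilution_series <- function(hot_conc = 5,
                            cold_conc = c(0, 2.5, 5, 10, 20, 40),
                            net_dpm,
                            added_dpm,
                            incubation_time = 2.5) {
  if (any(cold_conc < 0)) stop("cold concentrations must be >= 0",
                               call. = FALSE)
  if (length(unique(cold_conc)) < 3L) {
    stop("need at least 3 distinct cold-leucine levels", call. = FALSE)
  }
  if (length(net_dpm) != length(cold_conc)) {
    stop("`net_dpm` must align with `cold_conc`", call. = FALSE)
  }
  if (hot_conc <= 0 || incubation_time <= 0 || any(added_dpm <= 0)) {
    stop("hot concentration, time and added DPM must be positive",
         call. = FALSE)
  }
  structure(
    list(hot_conc = hot_conc, cold_conc = cold_conc,
         net_dpm = net_dpm, added_dpm = rep_len(added_dpm, length(cold_conc)),
         incubation_time = incubation_time),
    class = "dilution_series"
  )
}

#' @rdname incubation-records
#' @param ets_assay_rate Potential respiration at assay temperature,
#'   umol O2 m-3 d-1.
#' @param assay_temperature,insitu_temperature Degrees Celsius.
#' @param filtered_volume Litres filtered (metadata; 10-20 L typical).
#' @export
ets_measurement <- function(ets_assay_rate, assay_temperature,
                            insitu_temperature, filtered_volume = 15) {
  if (any(ets_assay_rate < 0)) stop("`ets_assay_rate` must be >= 0",
                                    call. = FALSE)
  for (t in c(assay_temperature, insitu_temperature)) {
    if (!is.finite(t) || t < -2 || t > 40) {
      stop("temperatures must lie in the physical range -2..40 C",
           call. = FALSE)
    }
  }
  structure(
    list(ets_assay_rate = ets_assay_rate,
         assay_temperature = assay_temperature,
         insitu_temperature = insitu_temperature,
         filtered_volume = filtered_volume),
    class = "ets_measurement"
  )
}
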