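#' Arrhenius temperature correction
#'
#' Rescales a rate measured at the assay temperature to the in situ
#' temperature, assuming Arrhenius kinetics with a fixed activation energy:
#' factor = exp((Ea / R) * (1 / T_assay - 1 / T_insitu)) with temperatures
#' in kelvin. The factor is below one whenever the water is colder than the
#' assay bath.
#'
#' @param rate Rate at assay temperature (any unit; >= 0).
#' @param t_assay,t_insitu Temperatures in degrees Celsius.
#' @param ea Activation energy, kcal mol-1.
#' @param gas_constant kcal mol-1 K-1.
#' @return The corrected rate, same unit as `rate`.
#' @examples
#' arrhenius_correct(100, 18, 13.5) # ~65.1
#' @export
arrhenius_correct <- function(rate, t_assay, t_insitu, ea = 15.8,
                              gas_constant = 1.9872e-3) {
  if (any(rate < 0)) stop("`rate` must be >= 0", call. = FALSE)
  if (any(c(t_assay, t_insitu) <= -273.15)) {
    stop("temperatures must exceed absolute zero", call. = FALSE)
  }
  ta <- t_assay + 273.15
  ti <- t_insitu + 273.15
  rate * exp((ea / gas_constant) * (1 / ta - 1 / ti))
}

#' Prokaryotic respiration from an ETS assay
#'
#' Potential electron-transport-system activity measured at assay
#' temperature is (i) Arrhenius-corrected to in situ temperature,
#' (ii) scaled by the PR:ETS ratio to an actual oxygen consumption, and
#' (iii) converted to carbon units with the remineralization O2:C
#' stoichiometry and the molar mass of carbon.
#'
#' @param m An [ets_measurement()] (assay rate in umol O2 m-3 d-1).
#' @param constants An [abd_constants()] bundle (Ea, PR:ETS, C:O2, molar
#'   mass).
#' @return A list with `pr` (ug C m-3 d-1) and `pr_o2` (umol O2 m-3 d-1
#'   after correction and the PR:ETS scaling).
#' @examples
#' m <- ets_measurement(100, assay_temperature = 18, insitu_temperature = 18)
#' pr_from_ets(m)$pr # 100 * 0.68 * (122/172) * 12 = 578.8
#' @export
pr_from_ets <- function(m, constants = abd_constants()) {
  stopifnot(inherits(m, "ets_measurement"))
  corrected <- arrhenius_correct(m$ets_assay_rate, m$assay_temperature,
                                 m$insitu_temperature, ea = constants$ea_ets,
                                 gas_constant = constants$gas_constant)
  pr_o2 <- corrected * constants$pr_to_ets
  pr_c <- pr_o2 * constants$c_to_o2_molar * constants$carbon_molar_mass
  list(pr = pr_c, pr_o2 = pr_o2)
}
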