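#' Per-depth community carbon metrics
#'
#' Closed-form derived quantities of the aphotic carbon budget. All are
#' vectorised and propagate `NA` ("not determined") inputs to `NA` outputs
#' rather than zeros.
#'
#' * `carbon_demand()` — prokaryotic carbon demand, PCD = PHP + PR.
#' * `growth_efficiency()` — PGE = PHP / (PHP + PR), a fraction in 0..1.
#' * `cell_specific()` — a volumetric rate per cell, fg C cell-1 d-1.
#' * `abd_fraction_of_pcd()` — percent of the carbon demand covered by dark
#'   bicarbonate assimilation.
#' * `generation_time_range()` — days to double a cell's carbon at the
#'   cell-specific assimilation rate, over a cell-carbon content range.
#'
#' @param php,pr Volumetric rates, ug C m-3 d-1.
#' @return `carbon_demand()`: ug C m-3 d-1.
#' @examples
#' carbon_demand(19.4, 967) # 986.4
#' growth_efficiency(125.3, 662) # ~0.159
#' cell_specific(986.4, 240e3) # ~4.11 fg C cell-1 d-1
#' @name depth-metrics
NULL

#' @rdname depth-metrics
#' @export
carbon_demand <- function(php, pr) {
  stopifnot(is.numeric(php) | all(is.na(php)), is.numeric(pr) | all(is.na(pr)))
  if (any(php < 0, na.rm = TRUE) || any(pr < 0, na.rm = TRUE)) {
    stop("rates must be >= 0", call. = FALSE)
  }
  php + pr
}

#' @rdname depth-metrics
#' @export
growth_efficiency <- function(php, pr) {
  pcd <- carbon_demand(php, pr)
  out <- php / pcd
  zero <- !is.na(pcd) & pcd == 0
  if (any(zero)) {
    warning("PHP + PR is zero; growth efficiency undefined, returning NA",
            call. = FALSE)
    out[zero] <- NA_real_
  }
  out
}

#' @rdname depth-metrics
#' @param rate Volumetric rate, ug C m-3 d-1.
#' @param pa Prokaryotic abundance, cells mL-1 (> 0).
#' @export
cell_specific <- function(rate, pa) {
  if (any(pa <= 0, na.rm = TRUE)) {
    stop("`pa` must be positive (cells mL-1)", call. = FALSE)
  }
  # ug m-3 -> fg m-3 is 1e9; cells mL-1 -> cells m-3 is 1e6.
  rate * 1e9 / (pa * 1e6)
}

#' @rdname depth-metrics
#' @param abd Dark bicarbonate assimilation, ug C m-3 d-1.
#' @param pcd Prokaryotic carbon demand, ug C m-3 d-1.
#' @export
abd_fraction_of_pcd <- function(abd, pcd) {
  out <- 100 * abd / pcd
  zero <- !is.na(pcd) & pcd == 0
  if (any(zero)) {
    warning("zero carbon demand; ABD fraction undefined, returning NA",
            call. = FALSE)
    out[zero] <- NA_real_
  }
  out
}

#' @rdname depth-metrics
#' @param cs_abd Cell-specific assimilation, fg C cell-1 d-1 (> 0 for a
#'   finite generation time).
#' @param cell_carbon_range Two-element numeric, low/high fg C per cell.
#' @export
generation_time_range <- function(cs_abd,
                                  cell_carbon_range = c(10, 20)) {
  stopifnot(length(cell_carbon_range) == 2L,
            cell_carbon_range[1] <= cell_carbon_range[2],
            all(cell_carbon_range > 0))
  if (length(cs_abd) != 1L || is.na(cs_abd) || cs_abd <= 0) {
    warning("non-positive cell-specific rate; generation time unbounded",
            call. = FALSE)
    return(c(min = NA_real_, max = NA_real_))
  }
  c(min = cell_carbon_range[1] / cs_abd,
    max = cell_carbon_range[2] / cs_abd)
}

#' Cell-specific fixation rate from a per-protein rate
#'
#' Converts a carbon-fixation rate normalised to biomass protein (as
#' reported for the cultured ammonia-oxidising archaeon Nitrosopumilus
#' maritimus SCM1: 39 nmol C d-1 per ug protein at 3e7 cells mL-1 and
#' 0.6 ug mL-1 dry mass) into a per-cell rate, given the protein share of
#' dry mass.
#'
#' @param fixation nmol C d-1 per ug protein (>= 0).
#' @param cell_density Cells mL-1 (> 0).
#' @param dry_mass ug dry biomass mL-1 (> 0).
#' @param protein_fraction Protein share of dry mass, in (0, 1].
#' @param constants An [abd_constants()] bundle (carbon molar mass).
#' @return fg C cell-1 d-1.
#' @examples
#' scm1_cell_specific_rate(39, 3e7, 0.6, 0.60) # ~5.6
#' scm1_cell_specific_rate(39, 3e7, 0.6, 0.40) # ~3.7
#' @export
scm1_cell_specific_rate <- function(fixation, cell_density, dry_mass,
                                    protein_fraction,
                                    constants = abd_constants()) {
  if (any(fixation < 0)) stop("`fixation` must be >= 0", call. = FALSE)
  if (cell_density <= 0 || dry_mass <= 0) {
    stop("cell density and dry mass must be positive", call. = FALSE)
  }
  if (protein_fraction <= 0 || protein_fraction > 1) {
    stop("`protein_fraction` must lie in (0, 1]", call. = FALSE)
  }
  protein_per_cell <- dry_mass / cell_density * protein_fraction # ug cell-1
  # nmol = 1e-3 umol, umol C x 12 ug umol-1 -> ug C per ug protein per day
  ug_c_per_ug_protein <- fixation * 1e-3 * constants$carbon_molar_mass
  ug_c_per_cell <- ug_c_per_ug_protein * protein_per_cell
  ug_c_per_cell * 1e9 # fg C cell-1 d-1
}

#' Derive the full per-depth metric set for a campaign table
#'
#' Applies [carbon_demand()], [growth_efficiency()], [cell_specific()] and
#' [abd_fraction_of_pcd()] across a samples table (one row per station and
#' depth, as returned by [med_samples()] or [load_campaign()]).
#'
#' @param samples A tibble with columns `php`, `pr`, `abd`
#'   (ug C m-3 d-1), their `_sd` companions, and `pa` (cells mL-1).
#' @param constants An [abd_constants()] bundle.
#' @return The input with columns `pcd`, `pge`, `cs_pcd`, `cs_abd`,
#'   `abd_of_pcd` appended; first-order sds `cs_pcd_sd`, `cs_abd_sd`
#'   (rate sd scaled per cell) when the `_sd` columns are present.
#' @export
derive_metrics <- function(samples, constants = abd_constants()) {
  stopifnot(is.data.frame(samples))
  need <- c("php", "pr", "abd", "pa")
  missing <- setdiff(need, names(samples))
  if (length(missing)) {
    stop("samples table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- dplyr::mutate(
    tibble::as_tibble(samples),
    pcd = carbon_demand(.data$php, .data$pr),
    pge = .data$php / .data$pcd,
    cs_pcd = cell_specific(.data$pcd, .data$pa),
    cs_abd = cell_specific(.data$abd, .data$pa),
    abd_of_pcd = 100 * .data$abd / .data$pcd
  )
  if (all(c("php_sd", "pr_sd") %in% names(samples))) {
    out$cs_pcd_sd <- cell_specific(sqrt(out$php_sd^2 + out$pr_sd^2), out$pa)
  }
  if ("abd_sd" %in% names(samples)) {
    out$cs_abd_sd <- cell_specific(out$abd_sd, out$pa)
  }
  out
}
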