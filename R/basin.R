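#' Dark-to-photic production ratio
#'
#' Depth-integrated dark bicarbonate assimilation as a percentage of the
#' photic-zone primary production of the same region. In the deep
#' Mediterranean this ratio spans roughly 85% (Alboran, against the
#' modelled PhPP) to 424% (Levantine, against the in situ PhPP).
#'
#' @param abd_integral Integrated dark assimilation, mg C m-2 d-1.
#' @param phpp Integrated phototrophic primary production, mg C m-2 d-1
#'   (> 0).
#' @return Percent.
#' @examples
#' abd_to_phpp_ratio(632, 149) # ~424
#' @export
abd_to_phpp_ratio <- function(abd_integral, phpp) {
  out <- 100 * abd_integral / phpp
  bad <- !is.na(phpp) & phpp <= 0
  if (any(bad)) {
    warning("non-positive PhPP; ratio undefined, returning NA", call. = FALSE)
    out[bad] <- NA_real_
  }
  out
}

#' Extrema of a metric with provenance
#'
#' Minimum and maximum of a metric over a set of per-depth rows, honouring
#' exclusion flags, and reporting which station and depth attain each.
#'
#' @param rows Tibble with `station_id`, `depth_m`, `flags`, and the metric.
#' @param metric Column name to summarise.
#' @param exclude_flags Flags whose rows are dropped first.
#' @param digits Optional rounding applied to the reported extrema (the
#'   rounding rule of the report); `NULL` leaves values unrounded.
#' @return A list: `min`, `max`, `argmin`, `argmax` (each arg a list with
#'   `station_id`, `depth_m`), `n` rows used.
#' @export
summarize_range <- function(rows, metric, exclude_flags = "DHAL-influenced",
                            digits = NULL) {
  stopifnot(is.data.frame(rows), metric %in% names(rows))
  if (!"flags" %in% names(rows)) rows$flags <- ""
  rows$flags[is.na(rows$flags)] <- ""
  if (length(exclude_flags)) {
    tags <- strsplit(rows$flags, ",", fixed = TRUE)
    keep <- !vapply(tags, function(tg) any(trimws(tg) %in% exclude_flags),
                    logical(1))
    rows <- rows[keep, ]
  }
  rows <- rows[!is.na(rows[[metric]]), ]
  if (nrow(rows) == 0L) {
    stop("no rows with `", metric, "` present after exclusions",
         call. = FALSE)
  }
  i_min <- which.min(rows[[metric]])
  i_max <- which.max(rows[[metric]])
  fmt <- function(x) if (is.null(digits)) x else round(x, digits)
  list(
    min = fmt(rows[[metric]][i_min]),
    max = fmt(rows[[metric]][i_max]),
    argmin = list(station_id = rows$station_id[i_min],
                  depth_m = rows$depth_m[i_min]),
    argmax = list(station_id = rows$station_id[i_max],
                  depth_m = rows$depth_m[i_max]),
    n = nrow(rows)
  )
}

#' Regenerate the station report tables
#'
#' Computes, from per-depth rates and abundances, the two standard report
#' tables of a deep-water campaign: the per-depth budget table (PHP, PR,
#' ABD, PCD, PGE, ABD:PCD) and the cell-specific table (PA, csPCD, csABD),
#' with report rounding (two decimals on the cell-specific columns). Values
#' are computed, never copied from any source table.
#'
#' @param profiles List of [station_profile()] objects whose samples carry
#'   `php`, `pr`, `abd`, `pa` (+ `_sd` columns as available).
#' @param constants An [abd_constants()] bundle.
#' @return A list of tibbles `budget` and `cell_specific`, each one row per
#'   station x depth, station-ordered.
#' @export
render_station_tables <- function(profiles, constants = abd_constants()) {
  if (length(profiles) == 0L) {
    return(list(budget = tibble::tibble(), cell_specific = tibble::tibble()))
  }
  samples <- dplyr::bind_rows(lapply(profiles, function(p) {
    dplyr::mutate(p$samples, station_id = p$station_id, .before = 1)
  }))
  m <- derive_metrics(samples, constants)
  budget_cols <- intersect(
    c("station_id", "depth_m", "salinity", "temp_c", "php", "php_sd",
      "pr", "pr_sd", "abd", "abd_sd", "pcd", "pge", "abd_of_pcd", "flags"),
    names(m))
  budget <- m[budget_cols]
  cs <- tibble::tibble(
    station_id = m$station_id, depth_m = m$depth_m,
    pa_1e3_ml = m$pa / 1e3,
    cs_pcd = round(m$cs_pcd, 2),
    cs_abd = round(m$cs_abd, 2)
  )
  if ("cs_pcd_sd" %in% names(m)) cs$cs_pcd_sd <- round(m$cs_pcd_sd, 2)
  if ("cs_abd_sd" %in% names(m)) cs$cs_abd_sd <- round(m$cs_abd_sd, 2)
  if ("flags" %in% names(m)) cs$flags <- m$flags
  list(budget = budget, cell_specific = cs)
}

#' Regional summary of integrated dark production against photic production
#'
#' Joins station ABD integrals to regional photic primary production
#' (PhPP) climatology and reports the dark:photic ratio against both the in
#' situ and the model PhPP column. Both ratio columns are always printed:
#' published basin-scale ranges mix the two denominators, so the full
#' matrix is the honest report.
#'
#' @param integrals Tibble from [integrate_campaign()] filtered to one
#'   variable (usually `"abd"`).
#' @param phpp Tibble with `station_id`, `sub_basin`, `phpp_insitu`,
#'   `phpp_model` (mg C m-2 d-1), e.g. [med_phpp()].
#' @return A tibble with the integrals, PhPP columns, and `ratio_insitu`,
#'   `ratio_model` (percent; `NA` where the PhPP is absent).
#' @export
regional_summary <- function(integrals, phpp) {
  stopifnot(is.data.frame(integrals), is.data.frame(phpp))
  out <- dplyr::left_join(tibble::as_tibble(integrals),
                          tibble::as_tibble(phpp), by = "station_id")
  out$ratio_insitu <- ifelse(
    !is.na(out$phpp_insitu) & out$phpp_insitu > 0,
    abd_to_phpp_ratio(out$value, out$phpp_insitu), NA_real_)
  out$ratio_model <- ifelse(
    !is.na(out$phpp_model) & out$phpp_model > 0,
    abd_to_phpp_ratio(out$value, out$phpp_model), NA_real_)
  out
}
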