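#' Bundled deep Mediterranean campaign fixture
#'
#' Processed per-station data for seven deep stations spanning the Atlantic
#' approach (ST1) and the Mediterranean Sea west to east (ST2-ST7): station
#' geometry, per-depth hydrography, volumetric rates (PHP, PR, ABD in
#' ug C m-3 d-1 with replicate sds), prokaryotic abundance, and the regional
#' photic primary production (PhPP) climatology used for dark:photic ratios.
#' The ST6 3,400 m sample sits on a brine-lake (DHAL) interface and is
#' flagged `DHAL-influenced`; station-level summaries and integrals exclude
#' it by default.
#'
#' `med_cell_specific_published()` carries the as-published cell-specific
#' table for regression comparison only; the package always recomputes
#' those columns.
#'
#' @return Tibbles (`med_stations()`, `med_samples()`, `med_phpp()`,
#'   `med_cell_specific_published()`); `med_campaign()` returns a named
#'   list of [station_profile()] objects.
#' @examples
#' profiles <- med_campaign()
#' integrate_profile(profiles$ST4, "abd")$value # ~396 mg C m-2 d-1
#' @name med-fixture
NULL

extdata_path <- function(file) {
  system.file("extdata", file, package = "darkcarbon", mustWork = TRUE)
}

read_fixture <- function(file) {
  readr::read_csv(extdata_path(file), show_col_types = FALSE,
                  progress = FALSE)
}

#' @rdname med-fixture
#' @export
med_stations <- function() read_fixture("med_stations.csv")

#' @rdname med-fixture
#' @export
med_samples <- function() {
  s <- read_fixture("med_samples.csv")
  s$flags[is.na(s$flags)] <- ""
  dplyr::rename(s, pa = "pa_cells_ml")
}

#' @rdname med-fixture
#' @export
med_phpp <- function() read_fixture("med_phpp.csv")

#' @rdname med-fixture
#' @export
med_cell_specific_published <- function() {
  read_fixture("med_cell_specific_published.csv")
}

#' @rdname med-fixture
#' @export
med_campaign <- function() {
  stations <- med_stations()
  samples <- med_samples()
  profiles <- lapply(seq_len(nrow(stations)), function(i) {
    st <- stations[i, ]
    station_profile(
      station_id = st$station_id,
      bottom_depth = st$bottom_depth_m,
      samples = samples[samples$station_id == st$station_id,
                        setdiff(names(samples), "station_id")],
      coordinates = c(lat = st$lat, lon = st$lon)
    )
  })
  stats::setNames(profiles, stations$station_id)
}
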