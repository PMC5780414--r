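#' Convert a long-format incubation table into volumetric rates
#'
#' The campaign interchange format is one row per replicate measurement:
#' columns `station_id`, `depth_m`, `assay` (`leu`, `bic`, `ets`), `role`
#' (`sample`, `blank`), `replicate`, `value`, plus the assay-specific
#' geometry columns (`volume`, `specific_activity`, `added_activity`,
#' `incubation_h`, `t_assay_c`, `t_insitu_c`, `dic_mmol_l`). This routine
#' groups by station and depth and applies [php_rate()], [abd_rate()] and
#' [pr_from_ets()] (the latter per ETS replicate, then mean and sd).
#'
#' @param incubations Long-format tibble as above.
#' @param constants An [abd_constants()] bundle.
#' @param cf Leucine-to-carbon conversion factor, kg C mol-1.
#' @return Tibble: `station_id`, `depth_m`, and the available rate columns
#'   `php`, `php_sd`, `pr`, `pr_sd`, `abd`, `abd_sd` (ug C m-3 d-1).
#' @export
compute_rates <- function(incubations, constants = abd_constants(),
                          cf = leucine_conversion_factor(
                            constants$leu_to_carbon_base,
                            constants$mean_isotope_dilution_leu)) {
  stopifnot(is.data.frame(incubations))
  need <- c("station_id", "depth_m", "assay", "role", "value")
  missing <- setdiff(need, names(incubations))
  if (length(missing)) {
    stop("incubation table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  one_depth <- function(d) {
    out <- tibble::tibble(station_id = d$station_id[1],
                          depth_m = d$depth_m[1])
    leu <- d[d$assay == "leu", ]
    if (nrow(leu)) {
      inc <- leucine_incubation(
        replicate_dpm = leu$value[leu$role == "sample"],
        blank_dpm = leu$value[leu$role == "blank"],
        sample_volume = leu$volume[1],
        specific_activity = leu$specific_activity[1],
        incubation_time = leu$incubation_h[1])
      r <- php_rate(inc, cf, constants)
      out$php <- r$rate
      out$php_sd <- r$sd
    }
    bic <- d[d$assay == "bic", ]
    if (nrow(bic)) {
      inc <- bicarbonate_incubation(
        replicate_dpm = bic$value[bic$role == "sample"],
        blank_dpm = bic$value[bic$role == "blank"],
        sample_volume = bic$volume[1],
        added_activity = bic$added_activity[1],
        specific_activity = bic$specific_activity[1],
        dic = if ("dic_mmol_l" %in% names(bic) && !is.na(bic$dic_mmol_l[1]))
          bic$dic_mmol_l[1] else NULL,
        incubation_time = bic$incubation_h[1])
      r <- abd_rate(inc, constants, require_dic = FALSE)
      out$abd <- r$rate
      out$abd_sd <- r$sd
    }
    ets <- d[d$assay == "ets" & d$role == "sample", ]
    if (nrow(ets)) {
      prs <- vapply(seq_len(nrow(ets)), function(j) {
        pr_from_ets(ets_measurement(ets$value[j], ets$t_assay_c[j],
                                    ets$t_insitu_c[j]), constants)$pr
      }, numeric(1))
      out$pr <- mean(prs)
      out$pr_sd <- if (length(prs) > 1) stats::sd(prs) else 0
    }
    out
  }
  keys <- interaction(incubations$station_id, incubations$depth_m,
                      drop = TRUE)
  res <- dplyr::bind_rows(lapply(split(incubations, keys), one_depth))
  dplyr::arrange(res, .data$station_id, .data$depth_m)
}

#' Load a campaign from station and sample tables
#'
#' Reads the two CSV schemas of the package — `stations.csv` (`station_id`,
#' `lat`, `lon`, `bottom_depth_m`, `sub_basin`, ...) and `samples.csv`
#' (`station_id`, `depth_m`, hydrography, rates with `_sd` companions,
#' `pa_cells_ml`, `flags`) — validates them, and assembles one
#' [station_profile()] per station. Empty cells are "not determined" and
#' become `NA`, never zero. Malformed rows are reported with their line
#' numbers.
#'
#' @param samples_csv,stations_csv File paths.
#' @return Named list of [station_profile()] objects.
#' @export
load_campaign <- function(samples_csv, stations_csv) {
  stations <- readr::read_csv(stations_csv, show_col_types = FALSE,
                              progress = FALSE)
  samples <- readr::read_csv(samples_csv, show_col_types = FALSE,
                             progress = FALSE)
  for (col in c("station_id", "bottom_depth_m")) {
    if (!col %in% names(stations)) {
      stop("stations file lacks column `", col, "`", call. = FALSE)
    }
  }
  for (col in c("station_id", "depth_m")) {
    if (!col %in% names(samples)) {
      stop("samples file lacks column `", col, "`", call. = FALSE)
    }
  }
  bad <- which(is.na(samples$depth_m) | samples$depth_m < 0)
  if (length(bad)) {
    stop("samples file: negative or missing depth on data line(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  orphan <- setdiff(unique(samples$station_id), stations$station_id)
  if (length(orphan)) {
    stop("samples reference unknown station(s): ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  if ("pa_cells_ml" %in% names(samples)) {
    samples <- dplyr::rename(samples, pa = "pa_cells_ml")
  }
  if (!"flags" %in% names(samples)) samples$flags <- ""
  samples$flags[is.na(samples$flags)] <- ""
  profiles <- lapply(seq_len(nrow(stations)), function(i) {
    st <- stations[i, ]
    rows <- samples[samples$station_id == st$station_id, ]
    rows <- rows[order(rows$depth_m), ]
    if (anyDuplicated(rows$depth_m)) {
      stop("station ", st$station_id, ": duplicated sampling depths",
           call. = FALSE)
    }
    station_profile(st$station_id, st$bottom_depth_m,
                    rows[setdiff(names(rows), "station_id")],
                    coordinates = if (all(c("lat", "lon") %in% names(st))) {
                      c(lat = st$lat, lon = st$lon)
                    })
  })
  stats::setNames(profiles, stations$station_id)
}

#' Run configuration
#'
#' Assembles the configuration a pipeline run is reproducible from:
#' input paths, constants overrides, integration top, exclusion flags,
#' rounding, and seed. Serialisable to YAML; the full constants block is
#' echoed into every output header for provenance.
#'
#' @param samples_csv,stations_csv Input paths.
#' @param incubations_csv Optional raw-incubation long CSV; when given, the
#'   pipeline computes rates from it instead of trusting pre-computed rate
#'   columns.
#' @param output_dir Where outputs are written.
#' @param constants List of [abd_constants()] overrides.
#' @param z_top Integration top, m.
#' @param exclude_flags Flags excluded from integrals and summaries.
#' @param seed Integer seed (recorded; the pipeline itself is
#'   deterministic).
#' @return A list of class `run_config`.
#' @export
run_config <- function(samples_csv, stations_csv, incubations_csv = NULL,
                       output_dir = ".", constants = list(), z_top = 200,
                       exclude_flags = "DHAL-influenced", seed = 1L) {
  structure(list(samples_csv = samples_csv, stations_csv = stations_csv,
                 incubations_csv = incubations_csv, output_dir = output_dir,
                 constants = constants, z_top = z_top,
                 exclude_flags = exclude_flags, seed = seed),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @param config A `run_config` (for writing) .
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw[!vapply(raw, is.null, logical(1))])
}

write_output_csv <- function(df, path, constants) {
  for (col in names(df)[vapply(df, is.list, logical(1))]) {
    df[[col]] <- vapply(df[[col]], paste, character(1), collapse = ";")
  }
  hdr <- c("# darkcarbon output", "# constants:",
           paste0("#   ", names(constants), " = ",
                  vapply(constants, function(x)
                    paste(format(x, digits = 12), collapse = "-"),
                    character(1))))
  writeLines(hdr, path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Run the full station-to-report pipeline
#'
#' End to end: load the campaign, (optionally) convert raw incubations to
#' rates, derive the per-depth metric table, integrate each rate profile
#' over the dark column, and join the regional photic-production table if
#' supplied. Writes `metrics.csv`, `integrals.csv` and (when PhPP is given)
#' `regional.csv` under the configured output directory, each headed by the
#' constants block; identical config and inputs give identical outputs.
#'
#' @param config A [run_config()].
#' @param constants An [abd_constants()] bundle built after applying
#'   `config$constants` overrides (assembled internally).
#' @param phpp Optional tibble in the shape of [med_phpp()].
#' @return Invisibly, a list with `profiles`, `metrics`, `integrals`, and
#'   `regional` (possibly `NULL`).
#' @export
run_pipeline <- function(config, phpp = NULL) {
  stopifnot(inherits(config, "run_config"))
  constants <- do.call(abd_constants, config$constants)
  profiles <- load_campaign(config$samples_csv, config$stations_csv)
  samples <- dplyr::bind_rows(lapply(profiles, function(p) {
    dplyr::mutate(p$samples, station_id = p$station_id, .before = 1)
  }))
  if (!is.null(config$incubations_csv)) {
    inc <- readr::read_csv(config$incubations_csv, show_col_types = FALSE,
                           progress = FALSE)
    rates <- compute_rates(inc, constants)
    keep <- setdiff(names(samples),
                    c("php", "php_sd", "pr", "pr_sd", "abd", "abd_sd"))
    samples <- dplyr::left_join(samples[keep], rates,
                                by = c("station_id", "depth_m"))
    profiles <- lapply(profiles, function(p) {
      p$samples <- samples[samples$station_id == p$station_id,
                           setdiff(names(samples), "station_id")]
      p
    })
  }
  metrics <- derive_metrics(samples, constants)
  integrals <- integrate_campaign(profiles, z_top = config$z_top,
                                  exclude_flags = config$exclude_flags)
  regional <- NULL
  if (!is.null(phpp)) {
    regional <- regional_summary(integrals[integrals$variable == "abd", ],
                                 phpp)
  }
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_output_csv(metrics, file.path(config$output_dir, "metrics.csv"),
                     constants)
    write_output_csv(integrals,
                     file.path(config$output_dir, "integrals.csv"),
                     constants)
    if (!is.null(regional)) {
      write_output_csv(regional,
                       file.path(config$output_dir, "regional.csv"),
                       constants)
    }
  }
  invisible(list(profiles = profiles, metrics = metrics,
                 integrals = integrals, regional = regional))
}

#' Write and re-read a simulated campaign as interchange CSVs
#'
#' File-level round trip for the simulator: the raw observation tables are
#' written in the same long format [compute_rates()] consumes, so that
#' simulation -> analysis is a pure file-level hand-off.
#'
#' @param sim An [simulate_campaign()] result.
#' @param dir Directory for `incubations.csv`, `abundance.csv`,
#'   `dilution.csv`.
#' @return `write_campaign()`: invisibly, the directory.
#'   `read_campaign()`: a list compatible with [recover_campaign()]
#'   (without the scenario).
#' @export
write_campaign <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(sim$incubations, file.path(dir, "incubations.csv"))
  readr::write_csv(sim$abundance, file.path(dir, "abundance.csv"))
  readr::write_csv(sim$dilution, file.path(dir, "dilution.csv"))
  invisible(dir)
}

#' @rdname write_campaign
#' @export
read_campaign <- function(dir) {
  rd <- function(f) readr::read_csv(file.path(dir, f),
                                    show_col_types = FALSE, progress = FALSE)
  list(incubations = rd("incubations.csv"), abundance = rd("abundance.csv"),
       dilution = rd("dilution.csv"), scenario = NULL)
}
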