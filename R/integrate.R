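#' Station profile container
#'
#' A station's ordered depth samples plus geometry. Depths are metres below
#' surface, positive down, strictly ascending, none deeper than the bottom.
#'
#' @param station_id Identifier.
#' @param bottom_depth Seabed depth, m.
#' @param samples Tibble with at least `depth_m`; rate columns (`php`, `pr`,
#'   `abd`, with `_sd` companions), `pa`, hydrography and a `flags` column
#'   (comma-separated analysis tags, `""` for none) as available.
#' @param coordinates Optional named numeric `c(lat = , lon = )`.
#' @return An object of class `station_profile`.
#' @export
station_profile <- function(station_id, bottom_depth, samples,
                            coordinates = NULL) {
  stopifnot(is.data.frame(samples), "depth_m" %in% names(samples))
  samples <- tibble::as_tibble(samples)
  if (is.unsorted(samples$depth_m, strictly = TRUE)) {
    stop("samples must be strictly ascending in depth", call. = FALSE)
  }
  if (any(samples$depth_m < 0)) stop("depths must be >= 0", call. = FALSE)
  if (max(samples$depth_m) > bottom_depth) {
    stop("deepest sample exceeds bottom depth", call. = FALSE)
  }
  if (!"flags" %in% names(samples)) samples$flags <- ""
  samples$flags[is.na(samples$flags)] <- ""
  structure(
    list(station_id = station_id, bottom_depth = bottom_depth,
         coordinates = coordinates, samples = samples),
    class = "station_profile"
  )
}

#' @export
print.station_profile <- function(x, ...) {
  cat(sprintf("<station_profile> %s: %d depths (%g-%g m), bottom %g m\n",
              x$station_id, nrow(x$samples), min(x$samples$depth_m),
              max(x$samples$depth_m), x$bottom_depth))
  invisible(x)
}

# Rows of a profile usable for a variable: value present, not excluded.
usable_rows <- function(profile, variable, exclude_flags) {
  s <- profile$samples
  val <- s[[variable]]
  excluded <- rep(FALSE, nrow(s))
  if (length(exclude_flags)) {
    tags <- strsplit(s$flags, ",", fixed = TRUE)
    excluded <- vapply(tags, function(tg) any(trimws(tg) %in% exclude_flags),
                       logical(1))
  }
  list(use = !is.na(val) & !excluded,
       excluded_depths = s$depth_m[excluded & !is.na(val)])
}

# Trapezoid weights for depths z over [z_1, bottom], with the deepest rate
# extended unchanged to the seabed. Total weight of sample i is the metres of
# water column it represents; the integral is sum(w * r).
trapezoid_weights <- function(z, bottom_depth) {
  n <- length(z)
  w <- numeric(n)
  if (n == 1L) {
    w[1] <- bottom_depth - z[1]
    return(w)
  }
  gaps <- diff(z)
  w[1] <- gaps[1] / 2
  if (n > 2L) w[2:(n - 1)] <- (gaps[-length(gaps)] + gaps[-1]) / 2
  w[n] <- gaps[length(gaps)] / 2 + (bottom_depth - z[n])
  w
}

#' Depth-integrate a rate profile over the dark water column
#'
#' Trapezoidal integration of a discrete rate profile from the top of the
#' aphotic layer to the seabed, assuming the rate at the bottom equals that
#' of the deepest sampled depth (constant bottom extension). Samples with a
#' missing value or a matching exclusion flag are skipped and recorded; no
#' extrapolation is made above the shallowest usable sample.
#'
#' @param profile A [station_profile()].
#' @param variable Column to integrate: `"abd"`, `"php"` or `"pr"`
#'   (ug C m-3 d-1).
#' @param z_top Top of the integration interval, m (default 200, the
#'   conventional top of the dark column).
#' @param exclude_flags Character vector of flags whose samples are dropped
#'   (default `"DHAL-influenced"`, the brine-lake-interface tag).
#' @return A one-row tibble: `station_id`, `variable`, `value` and `sd`
#'   (mg C m-2 d-1; `sd` is the delta-method quadrature of per-depth sds
#'   through the trapezoid weights, `NA` when sds are absent), `z_top`,
#'   `z_bottom`, `n_points`, and `excluded` (list-column of dropped depths).
#' @examples
#' st <- station_profile("U", 1200,
#'   tibble::tibble(depth_m = c(200, 1200), abd = c(100, 100),
#'                  abd_sd = c(0, 0)))
#' integrate_profile(st, "abd")$value # 100 mg C m-2 d-1
#' @export
integrate_profile <- function(profile, variable, z_top = 200,
                              exclude_flags = "DHAL-influenced") {
  stopifnot(inherits(profile, "station_profile"))
  if (!variable %in% names(profile$samples)) {
    stop("profile has no `", variable, "` column", call. = FALSE)
  }
  u <- usable_rows(profile, variable, exclude_flags)
  s <- profile$samples[u$use, ]
  s <- s[s$depth_m >= z_top, ]
  if (nrow(s) == 0L) {
    stop("no usable samples at or below z_top = ", z_top, " m", call. = FALSE)
  }
  if (min(s$depth_m) > z_top) {
    warning(sprintf(
      "shallowest usable %s sample (%g m) is below z_top = %g m; ",
      variable, min(s$depth_m), z_top),
      "integration starts there (no upward extrapolation)", call. = FALSE)
  }
  w <- trapezoid_weights(s$depth_m, profile$bottom_depth)
  value <- sum(w * s[[variable]]) / 1e3 # ug m-2 -> mg m-2
  sd_col <- paste0(variable, "_sd")
  sd_val <- NA_real_
  if (sd_col %in% names(s) && !anyNA(s[[sd_col]])) {
    sd_val <- sqrt(sum((w * s[[sd_col]])^2)) / 1e3
  }
  tibble::tibble(
    station_id = profile$station_id, variable = variable,
    value = value, sd = sd_val,
    z_top = max(z_top, min(s$depth_m)), z_bottom = profile$bottom_depth,
    n_points = nrow(s), excluded = list(u$excluded_depths)
  )
}

#' Delta-method uncertainty of a depth integral
#'
#' First-order propagation of independent per-depth standard deviations
#' through the trapezoid-plus-bottom-extension weights:
#' sd = sqrt(sum((w_i sd_i)^2)) / 1e3, in mg C m-2 d-1. Convenience wrapper
#' around the `sd` column of [integrate_profile()].
#'
#' @inheritParams integrate_profile
#' @return The integral sd in mg C m-2 d-1 (`NA` if any per-depth sd is
#'   missing).
#' @export
propagate_integral_sd <- function(profile, variable, z_top = 200,
                                  exclude_flags = "DHAL-influenced") {
  integrate_profile(profile, variable, z_top, exclude_flags)$sd
}

#' Integrate every station and variable of a campaign
#'
#' @param profiles A list of [station_profile()] objects.
#' @param variables Rate columns to integrate where present.
#' @inheritParams integrate_profile
#' @return A tibble, one row per station x available variable.
#' @export
integrate_campaign <- function(profiles, variables = c("abd", "php", "pr"),
                               z_top = 200,
                               exclude_flags = "DHAL-influenced") {
  rows <- list()
  for (p in profiles) {
    for (v in intersect(variables, names(p$samples))) {
      ok <- tryCatch({
        rows[[length(rows) + 1L]] <-
          integrate_profile(p, v, z_top, exclude_flags)
        TRUE
      }, error = function(e) FALSE)
      if (!ok) next
    }
  }
  dplyr::bind_rows(rows)
}
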