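#' Read a raw water-chemistry sample table
#'
#' Reads one row per sample. Required columns: `site_id`, `date`
#' (ISO-8601) and `totp` (ug P l^-1). Nitrogen columns may be any of
#' `no3_no2` (nitrate + nitrite), `no3` (treated as nitrate only) and
#' `nh4` (ammonia + ammonium), all ug N l^-1. Silica is `si` (ug Si l^-1)
#' or `sio2` (ug SiO2 l^-1). Optional: `depth` (m) and
#' `detection_limit_<analyte>` columns.
#'
#' @param path CSV file path.
#' @return A tibble of raw samples.
#' @export
read_samples <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("site_id", "date", "totp")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop("sample table lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!any(c("no3_no2", "no3", "nh4") %in% names(x))) {
    stop("sample table has no nitrogen column (no3_no2, no3 or nh4)",
         call. = FALSE)
  }
  if (!any(c("si", "sio2") %in% names(x))) {
    stop("sample table has no silica column (si or sio2)", call. = FALSE)
  }
  x$date <- as.Date(x$date)
  x$site_id <- as.character(x$site_id)
  x
}

#' Read a site metadata table
#'
#' Columns: `site_id`, `country`, `lat`, `lon`, optionally `area_km2`
#' (catchment area, must be positive when present) and `runoff`
#' (l km^-2 d^-1), the latter needed only for flux-based ICEP.
#'
#' @param path CSV file path.
#' @return A tibble of site records.
#' @export
read_sites <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"site_id" %in% names(x)) {
    stop("site table lacks required column site_id", call. = FALSE)
  }
  x$site_id <- as.character(x$site_id)
  if ("area_km2" %in% names(x) &&
      any(!is.na(x$area_km2) & x$area_km2 <= 0)) {
    stop("catchment areas must be > 0 where present", call. = FALSE)
  }
  x
}

#' Dissolved inorganic nitrogen from available species
#'
#' DIN is the sum of nitrate(+nitrite) and ammonia(+ammonium). Monitoring
#' programmes differ in which species they report, so available species
#' are summed and a missing species contributes nothing; when every
#' species is missing, DIN is `NA` (the record is unusable for N
#' metrics).
#'
#' @param no3_no2 Nitrate + nitrite (or nitrate alone), ug N l^-1.
#' @param nh4 Ammonia + ammonium, ug N l^-1.
#' @return DIN, ug N l^-1; `NA` where both inputs are missing.
#' @examples
#' compute_din(400, 50)   # 450
#' compute_din(583, NA)   # 583
#' @export
compute_din <- function(no3_no2, nh4) {
  stopifnot(is.numeric(no3_no2) || all(is.na(no3_no2)),
            is.numeric(nh4) || all(is.na(nh4)))
  n <- max(length(no3_no2), length(nh4))
  no3_no2 <- rep_len(as.numeric(no3_no2), n)
  nh4 <- rep_len(as.numeric(nh4), n)
  if (any(c(no3_no2, nh4) < 0, na.rm = TRUE)) {
    stop("nitrogen concentrations must be >= 0", call. = FALSE)
  }
  out <- rowSums(cbind(no3_no2, nh4), na.rm = TRUE)
  out[is.na(no3_no2) & is.na(nh4)] <- NA_real_
  out
}

#' Harmonize raw samples into clean analysis records
#'
#' Applies, in order: the depth filter (surface samples only), the study
#' window, below-detection substitution, nitrogen summation to DIN,
#' SiO2-to-Si conversion where Si itself was not reported, and averaging
#' of duplicate site-date records. The output has one row per site and
#' date with columns `site_id`, `date`, `din`, `totp`, `si` in ug l^-1.
#'
#' @param samples Raw sample tibble from [read_samples()].
#' @param window Length-2 Date (or coercible) vector, the inclusive study
#'   window; default 2017-01-01 to 2024-12-31.
#' @param bdl_policy Below-detection handling: `"half_limit"` substitutes
#'   half the reported detection limit where a `detection_limit_<analyte>`
#'   column flags a value below it; `"as_is"` keeps reported values.
#' @param max_depth Maximum sample depth in m when a `depth` column is
#'   present; default 1 (surface samples).
#' @return A tibble of harmonized per-sample records.
#' @export
harmonize_samples <- function(samples,
                              window = as.Date(c("2017-01-01", "2024-12-31")),
                              bdl_policy = c("half_limit", "as_is"),
                              max_depth = 1) {
  bdl_policy <- match.arg(bdl_policy)
  window <- as.Date(window)
  stopifnot(length(window) == 2L, window[1] <= window[2])
  x <- samples
  if ("depth" %in% names(x)) {
    x <- dplyr::filter(x, is.na(.data$depth) | .data$depth < max_depth)
  }
  x <- dplyr::filter(x, .data$date >= window[1], .data$date <= window[2])

  for (col in c("no3_no2", "no3", "nh4", "totp", "si", "sio2")) {
    if (!col %in% names(x)) next
    v <- x[[col]]
    if (any(!is.na(v) & v < 0)) {
      stop("negative concentrations in column ", col, call. = FALSE)
    }
    lim_col <- paste0("detection_limit_", col)
    if (bdl_policy == "half_limit" && lim_col %in% names(x)) {
      lim <- x[[lim_col]]
      below <- !is.na(v) & !is.na(lim) & v < lim
      v[below] <- lim[below] / 2
      x[[col]] <- v
    }
  }

  if (any(c("no3_no2", "no3", "nh4") %in% names(x))) {
    no3 <- if ("no3_no2" %in% names(x)) x$no3_no2
           else if ("no3" %in% names(x)) x$no3
           else rep(NA_real_, nrow(x))
    nh4 <- if ("nh4" %in% names(x)) x$nh4 else rep(NA_real_, nrow(x))
    x$din <- compute_din(no3, nh4)
  } else if (!"din" %in% names(x)) {
    stop("no nitrogen columns (no3_no2, no3, nh4) and no precomputed din",
         call. = FALSE)
  }

  si <- if ("si" %in% names(x)) x$si else rep(NA_real_, nrow(x))
  if ("sio2" %in% names(x)) {
    use_sio2 <- is.na(si) & !is.na(x$sio2)
    si[use_sio2] <- si_from_sio2(x$sio2[use_sio2])
  }
  x$si <- si

  x |>
    dplyr::group_by(.data$site_id, .data$date) |>
    dplyr::summarise(
      din = mean_or_na(.data$din),
      totp = mean_or_na(.data$totp),
      si = mean_or_na(.data$si),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$site_id, .data$date)
}

mean_or_na <- function(v) {
  if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
}

#' Quality-control site retention
#'
#' A site is retained only if every calendar year of the study window has
#' at least `min_obs` samples with usable (non-missing) DIN, TotP and Si
#' jointly. The boundary is inclusive: exactly `min_obs` observations
#' retain the site.
#'
#' @param samples Harmonized sample tibble from [harmonize_samples()].
#' @param window Inclusive study window (length-2 Date vector).
#' @param min_obs Minimum usable observations per calendar year
#'   (default 6).
#' @return The input filtered to retained sites, with attribute
#'   `"dropped"` listing dropped site ids and the offending year counts.
#' @export
qc_retain <- function(samples,
                      window = as.Date(c("2017-01-01", "2024-12-31")),
                      min_obs = 6) {
  window <- as.Date(window)
  if (nrow(samples) == 0L) {
    warning("qc_retain: empty input", call. = FALSE)
    out <- samples
    attr(out, "dropped") <- tibble::tibble(site_id = character(),
                                           year = integer(),
                                           n_usable = integer())
    return(out)
  }
  years <- seq(as.integer(format(window[1], "%Y")),
               as.integer(format(window[2], "%Y")))
  usable <- samples |>
    dplyr::filter(!is.na(.data$din), !is.na(.data$totp), !is.na(.data$si)) |>
    dplyr::mutate(year = as.integer(format(.data$date, "%Y"))) |>
    dplyr::count(.data$site_id, .data$year, name = "n_usable")
  counts <- tidyr::expand_grid(site_id = unique(samples$site_id),
                               year = years) |>
    dplyr::left_join(usable, by = c("site_id", "year")) |>
    dplyr::mutate(n_usable = tidyr::replace_na(.data$n_usable, 0L))
  bad <- dplyr::filter(counts, .data$n_usable < min_obs)
  keep <- setdiff(unique(samples$site_id), unique(bad$site_id))
  out <- dplyr::filter(samples, .data$site_id %in% keep)
  attr(out, "dropped") <- bad
  out
}
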