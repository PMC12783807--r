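#' Per-sample stoichiometric metrics
#'
#' Computes, for each harmonized sample, the molar triplet, the
#' Redfield-scaled ternary percentages with depletion zone, the trophic
#' assessment of the depleted nutrient, and critical concentrations with
#' exceedance ratios. All downstream aggregation operates on these
#' per-sample values; raw concentrations are never re-entered into the
#' equations after averaging, except where a summary is explicitly
#' defined on aggregated concentrations (see [site_summary()]).
#'
#' @param samples Harmonized tibble with `site_id`, `date`, `din`,
#'   `totp`, `si` (ug l^-1).
#' @param const Constants list from [element_constants()].
#' @param threshold Depletion threshold in percent (default 20).
#' @return The input with metric columns appended: molar `din_umol`,
#'   `totp_umol`, `si_umol`; `n_pct`, `p_pct`, `si_pct`, `zone`;
#'   `np_ratio`, `basis`, `tsi`, `tsi_class`; `din_0`, `totp_0`,
#'   `d_din`, `d_totp`.
#' @export
sample_metrics <- function(samples, const = element_constants(),
                           threshold = 20) {
  ok <- !is.na(samples$din) & !is.na(samples$totp) & !is.na(samples$si)
  x <- samples[ok, , drop = FALSE]
  m <- molar_triplet(x$din, x$totp, x$si, const)
  pct <- redfield_percentages(m$din, m$totp, m$si, const)
  tro <- select_basis_and_classify(m$din, m$totp)
  ice <- assess_icep(x$din, x$totp, x$si, runoff = NULL, const = const)
  dplyr::bind_cols(
    x,
    tibble::tibble(din_umol = m$din, totp_umol = m$totp, si_umol = m$si),
    pct,
    tibble::tibble(zone = classify_zone(pct$n_pct, pct$p_pct, pct$si_pct,
                                        threshold)),
    tro,
    ice[, c("din_0", "totp_0", "d_din", "d_totp")]
  )
}

metric_cols <- function() {
  c("din", "totp", "si", "din_umol", "totp_umol", "si_umol",
    "n_pct", "p_pct", "si_pct", "np_ratio", "tsi",
    "din_0", "totp_0", "d_din", "d_totp")
}

#' Aggregate per-sample metrics up the monitoring ladder
#'
#' Implements the two-step averaging used for multi-year monitoring
#' summaries. Annual ladder: the annual value is the mean of that year's
#' samples and the overall value is the mean of the annual values (so
#' years with different sampling effort carry equal weight). Monthly
#' ladder: the value for calendar month m is the mean over years of the
#' within-year mean of that month's samples. `mode = "pooled"` instead
#' pools all samples of a calendar month across years in one mean; with a
#' balanced design both orders coincide.
#'
#' @param metrics Per-sample metric tibble from [sample_metrics()].
#' @param cols Metric columns to aggregate (default [metric_cols()]
#'   intersected with what is present).
#' @param mode `"two_step"` (within year first, default) or `"pooled"`.
#' @return A list with `annual` (site x year), `overall` (one row per
#'   site) and `monthly` (site x calendar month, months without samples
#'   absent) tibbles of mean metric values, plus `n` columns giving the
#'   sample counts behind each row.
#' @export
aggregate_metrics <- function(metrics, cols = NULL,
                              mode = c("two_step", "pooled")) {
  mode <- match.arg(mode)
  if (is.null(cols)) cols <- intersect(metric_cols(), names(metrics))
  stopifnot(length(cols) > 0, all(cols %in% names(metrics)))
  x <- metrics |>
    dplyr::mutate(
      year = as.integer(format(.data$date, "%Y")),
      month = as.integer(format(.data$date, "%m"))
    )

  annual <- x |>
    dplyr::group_by(.data$site_id, .data$year) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(cols), mean),
                     n = dplyr::n(), .groups = "drop")

  overall <- annual |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(cols), mean),
                     n = sum(.data$n), n_years = dplyr::n(),
                     .groups = "drop")

  monthly <- if (mode == "two_step") {
    x |>
      dplyr::group_by(.data$site_id, .data$year, .data$month) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(cols), mean),
                       n = dplyr::n(), .groups = "drop") |>
      dplyr::group_by(.data$site_id, .data$month) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(cols), mean),
                       n = sum(.data$n), n_years = dplyr::n(),
                       .groups = "drop")
  } else {
    x |>
      dplyr::group_by(.data$site_id, .data$month) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(cols), mean),
                       n = dplyr::n(),
                       n_years = dplyr::n_distinct(.data$year),
                       .groups = "drop")
  }

  missing_months <- monthly |>
    dplyr::count(.data$site_id) |>
    dplyr::filter(.data$n < 12L)
  if (nrow(missing_months)) {
    warning(nrow(missing_months), " site(s) lack samples in some calendar ",
            "months; those months are absent from the monthly table",
            call. = FALSE)
  }

  list(annual = annual, overall = overall, monthly = monthly)
}

#' Map calendar months to seasons
#'
#' March-May is spring, June-August summer, September-November autumn and
#' December-February winter.
#'
#' @param month Integer month 1-12.
#' @return Factor with levels `spring`, `summer`, `autumn`, `winter`.
#' @export
month_season <- function(month) {
  stopifnot(is.numeric(month), all(month %in% 1:12 | is.na(month)))
  s <- dplyr::case_when(
    month %in% 3:5 ~ "spring",
    month %in% 6:8 ~ "summer",
    month %in% 9:11 ~ "autumn",
    month %in% c(12, 1, 2) ~ "winter"
  )
  factor(s, levels = c("spring", "summer", "autumn", "winter"))
}

#' Minimum monthly Redfield Si percentage per site
#'
#' Scans the monthly ternary percentages for each site's most Si-depleted
#' calendar month — the seasonal-drawdown signal that overall averages
#' hide. Ties take the earliest calendar month. The depletion flag marks
#' minima below the threshold.
#'
#' @param monthly Monthly tibble from [aggregate_metrics()], containing
#'   `site_id`, `month` and `si_pct`.
#' @param threshold Depletion threshold in percent (default 20).
#' @return One row per site: `min_si_pct`, `min_si_month`,
#'   `min_si_season`, `si_depleted_month`.
#' @export
seasonal_min_si <- function(monthly, threshold = 20) {
  stopifnot(all(c("site_id", "month", "si_pct") %in% names(monthly)))
  if (nrow(monthly) == 0L) {
    stop("no monthly values available", call. = FALSE)
  }
  monthly |>
    dplyr::filter(!is.na(.data$si_pct)) |>
    dplyr::group_by(.data$site_id) |>
    dplyr::arrange(.data$month, .by_group = TRUE) |>
    dplyr::summarise(
      min_si_pct = min(.data$si_pct),
      min_si_month = .data$month[which.min(.data$si_pct)],
      .groups = "drop"
    ) |>
    dplyr::mutate(
      min_si_season = month_season(.data$min_si_month),
      si_depleted_month = .data$min_si_pct < threshold
    )
}
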