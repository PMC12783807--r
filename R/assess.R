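#' Site-level summary of all stoichiometric metrics
#'
#' Builds one row per site from the aggregation ladder: overall mean
#' concentrations and ternary percentages, the depletion zone of the
#' overall composition, the trophic assessment of the depleted nutrient
#' computed from the overall mean concentrations, critical concentrations
#' and exceedance ratios from the overall means, the monthly exceedance
#' range (month-specific Si for the monthly critical values), and the
#' minimum monthly Redfield Si percentage with its month and season.
#'
#' @param agg Output of [aggregate_metrics()].
#' @param const Constants list from [element_constants()].
#' @param threshold Depletion threshold in percent (default 20).
#' @return One row per site.
#' @export
site_summary <- function(agg, const = element_constants(), threshold = 20) {
  ov <- agg$overall
  zone <- classify_zone(ov$n_pct, ov$p_pct, ov$si_pct, threshold)
  tro <- select_basis_and_classify(to_molar(ov$din, "N", const),
                                   to_molar(ov$totp, "P", const))
  ice <- assess_icep(ov$din, ov$totp, ov$si, runoff = NULL, const = const)

  mo <- agg$monthly
  mo_ice <- assess_icep(mo$din, mo$totp, mo$si, runoff = NULL, const = const)
  mo_rng <- dplyr::bind_cols(mo[, c("site_id", "month")], mo_ice) |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      d_din_month_min = min(.data$d_din), d_din_month_max = max(.data$d_din),
      d_totp_month_min = min(.data$d_totp),
      d_totp_month_max = max(.data$d_totp),
      .groups = "drop"
    )
  minsi <- seasonal_min_si(mo, threshold)

  tibble::tibble(
    site_id = ov$site_id,
    n = ov$n, n_years = ov$n_years,
    din = ov$din, totp = ov$totp, si = ov$si,
    n_pct = ov$n_pct, p_pct = ov$p_pct, si_pct = ov$si_pct,
    zone = zone
  ) |>
    dplyr::bind_cols(tro, ice[, c("din_0", "totp_0", "d_din", "d_totp",
                                  "icep_basis")]) |>
    dplyr::left_join(mo_rng, by = "site_id") |>
    dplyr::left_join(minsi, by = "site_id")
}

#' Run the full river-mouth stoichiometry assessment
#'
#' End-to-end pipeline: read (or accept) raw samples, harmonize fractions
#' and units, apply quality control, compute per-sample metrics,
#' aggregate up the monitoring ladder and summarise per site. Optionally
#' writes `site_summary.csv`, `monthly_metrics.csv` and
#' `run_manifest.json` (configuration, row counts and dropped-site
#' reasons) to an output directory.
#'
#' @param samples Path to a samples CSV or a tibble in the raw-sample
#'   dialect (see [read_samples()]).
#' @param sites Optional path to a site metadata CSV or a tibble.
#' @param window Inclusive study window, length-2 Date vector.
#' @param min_obs QC minimum usable observations per calendar year.
#' @param redfield_si Redfield Si coefficient (default 20).
#' @param threshold Depletion threshold in percent.
#' @param bdl_policy Below-detection policy, see [harmonize_samples()].
#' @param out_dir Output directory; `NULL` skips writing.
#' @return Invisibly, a list: `samples` (harmonized, QC-passed),
#'   `metrics` (per-sample), `agg` (ladder), `summary` (per site),
#'   `dropped` (QC failures), `manifest`.
#' @export
run_assessment <- function(samples, sites = NULL,
                           window = as.Date(c("2017-01-01", "2024-12-31")),
                           min_obs = 6, redfield_si = 20, threshold = 20,
                           bdl_policy = "half_limit", out_dir = NULL) {
  const <- element_constants(redfield_si)
  raw <- if (is.character(samples)) read_samples(samples) else samples
  site_meta <- if (is.character(sites)) read_sites(sites) else sites

  harm <- harmonize_samples(raw, window = window, bdl_policy = bdl_policy)
  kept <- qc_retain(harm, window = window, min_obs = min_obs)
  dropped <- attr(kept, "dropped")
  if (nrow(kept) == 0L) {
    stop("no sites retained after quality control", call. = FALSE)
  }
  metrics <- sample_metrics(kept, const, threshold)
  agg <- aggregate_metrics(metrics)
  summ <- site_summary(agg, const, threshold)
  if (!is.null(site_meta)) {
    summ <- dplyr::left_join(summ, site_meta, by = "site_id")
  }

  cfg <- list(window = as.character(window), min_obs = min_obs,
              redfield_si = redfield_si, threshold = threshold,
              bdl_policy = bdl_policy)
  manifest <- list(
    config = cfg,
    config_hash = rlang::hash(cfg),
    n_input_rows = nrow(raw),
    n_harmonized_rows = nrow(harm),
    n_retained_rows = nrow(kept),
    n_sites_retained = dplyr::n_distinct(kept$site_id),
    n_sites_dropped = dplyr::n_distinct(dropped$site_id),
    dropped_sites = dropped
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(format_sig(summ), file.path(out_dir, "site_summary.csv"))
    monthly_long <- agg$monthly |>
      tidyr::pivot_longer(dplyr::all_of(intersect(metric_cols(),
                                                  names(agg$monthly))),
                          names_to = "metric", values_to = "value")
    readr::write_csv(format_sig(monthly_long),
                     file.path(out_dir, "monthly_metrics.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(samples = kept, metrics = metrics, agg = agg,
                 summary = summ, dropped = dropped, manifest = manifest))
}

#' Read a YAML run configuration
#'
#' Recognised keys: `window.start`, `window.end`, `qc.min_obs_per_year`,
#' `bdl.policy`, `redfield.si_term`, `threshold`. Missing keys fall back
#' to the [run_assessment()] defaults. The returned list can be spliced
#' into a call with `do.call`.
#'
#' @param path YAML file path.
#' @return A named list of `run_assessment()` arguments.
#' @examples
#' cfg_file <- tempfile(fileext = ".yaml")
#' writeLines("window:\n  start: 2018-01-01\n  end: 2020-12-31\nqc:\n  min_obs_per_year: 4", cfg_file)
#' read_run_config(cfg_file)
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$window)) {
    args$window <- as.Date(c(y$window$start, y$window$end))
  }
  if (!is.null(y$qc$min_obs_per_year)) args$min_obs <- y$qc$min_obs_per_year
  if (!is.null(y$bdl$policy)) args$bdl_policy <- y$bdl$policy
  if (!is.null(y$redfield$si_term)) args$redfield_si <- y$redfield$si_term
  if (!is.null(y$threshold)) args$threshold <- y$threshold
  args
}

# round numeric columns to 6 significant digits for file output
format_sig <- function(df, digits = 6) {
  dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
                                  ~ signif(.x, digits)))
}
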