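#' Configuration for the synthetic monitoring-data generator
#'
#' Captures the statistical structure of Nordic river-mouth monitoring
#' records: monthly sampling over several years, a north-south gradient
#' in N and P concentrations (higher in the south), latitude-independent
#' silica, a seasonal silica drawdown with a spring trough (diatom
#' uptake), and right-skewed lognormal measurement-plus-environment
#' noise.
#'
#' @param n_sites Number of sites.
#' @param years Calendar years sampled (default 2017-2024).
#' @param samples_per_month Samples per site per month (default 1).
#' @param lat_range Site latitude range, degrees north (default 55-70).
#' @param din_range Site-median DIN at the southern and northern edge of
#'   the latitude range, ug l^-1 (default 2000 down to 50, log-linear in
#'   latitude).
#' @param totp_range Site-median TotP at the southern and northern edge,
#'   ug l^-1 (default 120 down to 5).
#' @param si_median Latitude-independent median Si, ug l^-1
#'   (default 2700).
#' @param site_sdlog Site-level lognormal spread (sd of log medians)
#'   around the gradient / Si median (default 0.3).
#' @param si_trough_month Calendar month of the seasonal Si minimum
#'   (default 5, May).
#' @param si_drawdown Fractional depth of the Si trough, in [0, 1)
#'   (default 0.3: May Si is 30% below the site median).
#' @param noise_cv Per-sample lognormal coefficient of variation
#'   (default 0.4).
#' @param missingness Probability that any one analyte value is missing
#'   (default 0).
#' @param runoff_median Median site runoff, l km^-2 d^-1 (default 1.1e6,
#'   about 400 mm yr^-1); set `NA` to omit runoff.
#' @param seed RNG seed; fully determines the output.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_sites = 50,
                         years = 2017:2024,
                         samples_per_month = 1,
                         lat_range = c(55, 70),
                         din_range = c(2000, 50),
                         totp_range = c(120, 5),
                         si_median = 2700,
                         site_sdlog = 0.3,
                         si_trough_month = 5,
                         si_drawdown = 0.3,
                         noise_cv = 0.4,
                         missingness = 0,
                         runoff_median = 1.1e6,
                         seed = 1L) {
  stopifnot(n_sites >= 1, length(years) >= 1, samples_per_month >= 1,
            si_median > 0, all(din_range > 0), all(totp_range > 0),
            si_drawdown >= 0, si_drawdown < 1,
            noise_cv >= 0, missingness >= 0, missingness < 1,
            si_trough_month %in% 1:12)
  structure(
    list(n_sites = n_sites, years = as.integer(years),
         samples_per_month = samples_per_month, lat_range = lat_range,
         din_range = din_range, totp_range = totp_range,
         si_median = si_median, site_sdlog = site_sdlog,
         si_trough_month = si_trough_month, si_drawdown = si_drawdown,
         noise_cv = noise_cv, missingness = missingness,
         runoff_median = runoff_median, seed = as.integer(seed)),
    class = "synth_config"
  )
}

# seasonal multiplier: 1 at the month opposite the trough, 1 - depth at it
season_factor <- function(month, trough, depth) {
  1 - depth * (1 + cos(2 * pi * (month - trough) / 12)) / 2
}

# lognormal sdlog giving coefficient of variation cv
cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

#' Generate a synthetic monitoring dataset
#'
#' Draws site latitudes uniformly, sets site-median DIN and TotP
#' log-linearly decreasing with latitude (with lognormal site scatter),
#' site-median Si independent of latitude, then simulates monthly samples
#' with a sinusoidal Si drawdown and per-sample lognormal noise whose
#' median is the (season-adjusted) site median. A truth table records
#' each site's analytic depletion zone, trophic basis and minimum-Si
#' month, computed from the medians, so recovery tests have an exact
#' target.
#'
#' @param cfg A [synth_config()].
#' @param const Constants list from [element_constants()], used for the
#'   analytic truth only.
#' @return A list of tibbles: `samples` (ingest-dialect rows `site_id`,
#'   `date`, `no3_no2`, `nh4`, `totp`, `si`), `sites` (`site_id`,
#'   `country`, `lat`, `lon`, `area_km2`, `runoff`) and `truth`
#'   (`site_id`, medians, `true_zone`, `true_basis`, `true_min_si_month`).
#' @export
synth_generate <- function(cfg = synth_config(), const = element_constants()) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  ns <- cfg$n_sites
  lat <- sort(stats::runif(ns, cfg$lat_range[1], cfg$lat_range[2]))
  frac <- (lat - cfg$lat_range[1]) / diff(cfg$lat_range)
  site_scatter <- function(n) exp(stats::rnorm(n, 0, cfg$site_sdlog))
  din_med <- exp(log(cfg$din_range[1]) +
                   frac * (log(cfg$din_range[2]) - log(cfg$din_range[1]))) *
    site_scatter(ns)
  totp_med <- exp(log(cfg$totp_range[1]) +
                    frac * (log(cfg$totp_range[2]) - log(cfg$totp_range[1]))) *
    site_scatter(ns)
  si_med <- cfg$si_median * site_scatter(ns)

  sites <- tibble::tibble(
    site_id = sprintf("S%03d", seq_len(ns)),
    country = ifelse(lat > 62, "NO_FI", "SE"),
    lat = lat,
    lon = stats::runif(ns, 10, 28),
    area_km2 = round(exp(stats::runif(ns, log(50), log(20000)))),
    runoff = if (is.na(cfg$runoff_median)) NA_real_ else
      cfg$runoff_median * site_scatter(ns)
  )

  months <- tidyr::expand_grid(
    site = seq_len(ns),
    year = cfg$years,
    month = 1:12,
    rep = seq_len(cfg$samples_per_month)
  )
  nsamp <- nrow(months)
  sdlog <- cv_to_sdlog(cfg$noise_cv)
  noise <- function() exp(stats::rnorm(nsamp, 0, sdlog))
  sf <- season_factor(months$month, cfg$si_trough_month, cfg$si_drawdown)
  din <- din_med[months$site] * noise()
  totp <- totp_med[months$site] * noise()
  si <- si_med[months$site] * sf * noise()
  # split DIN into nitrate+nitrite and ammonium parts (~90/10)
  no3_share <- stats::rbeta(nsamp, 18, 2)
  day <- 1 + (months$rep - 1) * pmin(27 %/% cfg$samples_per_month, 27)

  samples <- tibble::tibble(
    site_id = sites$site_id[months$site],
    date = as.Date(sprintf("%d-%02d-%02d", months$year, months$month, day)),
    no3_no2 = din * no3_share,
    nh4 = din * (1 - no3_share),
    totp = totp,
    si = si
  )
  if (cfg$missingness > 0) {
    for (col in c("no3_no2", "nh4", "totp", "si")) {
      drop <- stats::runif(nsamp) < cfg$missingness
      samples[[col]][drop] <- NA_real_
    }
  }

  truth <- synth_truth(sites$site_id, din_med, totp_med, si_med, cfg, const)
  list(samples = samples, sites = sites, truth = truth)
}

# analytic truth from site medians (no simulation noise involved)
synth_truth <- function(site_id, din_med, totp_med, si_med, cfg, const) {
  m <- molar_triplet(din_med, totp_med, si_med, const)
  pct <- redfield_percentages(m$din, m$totp, m$si, const)
  zone <- classify_zone(pct$n_pct, pct$p_pct, pct$si_pct)
  basis <- factor(ifelse(m$din / m$totp >= 16, "TotP", "DIN"),
                  levels = c("TotP", "DIN"))
  # monthly si_pct is minimised where the seasonal factor is smallest;
  # with no drawdown all months tie and the earliest month wins
  sf <- season_factor(1:12, cfg$si_trough_month, cfg$si_drawdown)
  min_month <- which.min(sf)
  tibble::tibble(
    site_id = site_id,
    din_med = din_med, totp_med = totp_med, si_med = si_med,
    n_pct = pct$n_pct, p_pct = pct$p_pct, si_pct = pct$si_pct,
    true_zone = zone,
    true_basis = basis,
    true_min_si_month = min_month
  )
}

#' Design a site median triplet with a requested zone and trophic class
#'
#' Inverse design for tests: places the depleted elements at 10% and
#' splits the remainder evenly among the others (balanced requests use
#' the centroid), converts those percentages to a Redfield-scaled molar
#' direction, then scales the whole triplet so the depleted-nutrient TSI
#' falls at the midpoint of the requested class (or so Si is near
#' 2700 ug l^-1 when no class is requested). The result is verified
#' against the forward equations and an error is raised if the request
#' cannot be realised.
#'
#' @param zone Target depletion zone, one of the levels of
#'   [classify_zone()].
#' @param tsi_class Optional target trophic class, one of
#'   `ultra_oligotrophic`, `oligotrophic`, `mesotrophic`, `eutrophic`,
#'   `hypereutrophic`.
#' @param const Constants list from [element_constants()].
#' @return One-row tibble with `din`, `totp`, `si` in ug l^-1 plus the
#'   realised `zone`, `basis`, `tsi` and `tsi_class`.
#' @export
make_redfield_site <- function(zone, tsi_class = NULL,
                               const = element_constants()) {
  zone <- match.arg(zone, zone_levels())
  if (!is.null(tsi_class)) {
    tsi_class <- match.arg(tsi_class, tsi_class_levels())
  }
  dep <- switch(zone,
    balanced = character(), N_depleted = "N", P_depleted = "P",
    Si_depleted = "Si", NP_depleted = c("N", "P"),
    NSi_depleted = c("N", "Si"), PSi_depleted = c("P", "Si"))
  pct <- c(N = 100 / 3, P = 100 / 3, Si = 100 / 3)
  if (length(dep)) {
    pct[dep] <- 10
    pct[setdiff(names(pct), dep)] <- (100 - 10 * length(dep)) /
      (3 - length(dep))
  }
  # molar direction (k = 1): scaled units proportional to percentages
  dir <- c(din = const$redfield_n * pct[["N"]],
           totp = const$redfield_p * pct[["P"]],
           si = const$redfield_si * pct[["Si"]])
  basis_p <- (dir[["din"]] / dir[["totp"]]) >= 16
  targets <- c(ultra_oligotrophic = 25, oligotrophic = 35, mesotrophic = 45,
               eutrophic = 55, hypereutrophic = 65)
  k <- if (is.null(tsi_class)) {
    (2700 / const$mass_si) / dir[["si"]]
  } else if (basis_p) {
    exp((targets[[tsi_class]] - 4.15) / 14.42) / (31 * dir[["totp"]])
  } else {
    1000 * exp((targets[[tsi_class]] - 54.45) / 14.43) / (14 * dir[["din"]])
  }
  m <- dir * k
  got_pct <- redfield_percentages(m[["din"]], m[["totp"]], m[["si"]], const)
  got_zone <- classify_zone(got_pct$n_pct, got_pct$p_pct, got_pct$si_pct)
  got_tro <- select_basis_and_classify(m[["din"]], m[["totp"]])
  if (as.character(got_zone) != zone ||
      (!is.null(tsi_class) && as.character(got_tro$tsi_class) != tsi_class)) {
    stop("requested zone/class combination is not realisable: ",
         zone, if (!is.null(tsi_class)) paste0(" + ", tsi_class),
         call. = FALSE)
  }
  tibble::tibble(
    din = from_molar(m[["din"]], "N", const),
    totp = from_molar(m[["totp"]], "P", const),
    si = from_molar(m[["si"]], "Si", const),
    zone = got_zone,
    basis = got_tro$basis,
    tsi = got_tro$tsi,
    tsi_class = got_tro$tsi_class
  )
}
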