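#' Index of coastal eutrophication potential, phosphorus form
#'
#' ICEP(P) = (PFlx/31 - SiFlx/(28 x 20)) x 106 x 12, in kg C km^-2 d^-1:
#' the carbon-equivalent excess of the P flux over what the Si flux could
#' balance through diatom growth. Applicable when molar N:P > 16
#' (P-depleted rivers). Zero marks the balance point below which no
#' harmful-bloom potential is indicated.
#'
#' @param pflx,siflx Daily fluxes of P and Si per unit catchment area,
#'   kg km^-2 d^-1; equal-length non-negative vectors.
#' @param const Constants list from [element_constants()].
#' @return ICEP in kg C km^-2 d^-1.
#' @examples
#' icep_p(pflx = 31, siflx = 560)  # balanced -> 0
#' @export
icep_p <- function(pflx, siflx, const = element_constants()) {
  check_flux(pflx, siflx)
  (pflx / const$mass_p -
     siflx / (const$mass_si * const$redfield_si)) * const$carbon_factor
}

#' Index of coastal eutrophication potential, nitrogen form
#'
#' ICEP(N) = (NFlx/(14 x 16) - SiFlx/(28 x 20)) x 106 x 12, in
#' kg C km^-2 d^-1. Applicable when molar N:P < 16 (N-depleted rivers).
#'
#' @param nflx,siflx Daily fluxes of N and Si per unit catchment area,
#'   kg km^-2 d^-1; equal-length non-negative vectors.
#' @inheritParams icep_p
#' @return ICEP in kg C km^-2 d^-1.
#' @examples
#' icep_n(nflx = 224, siflx = 560)  # balanced -> 0
#' @export
icep_n <- function(nflx, siflx, const = element_constants()) {
  check_flux(nflx, siflx)
  (nflx / (const$mass_n * const$redfield_n) -
     siflx / (const$mass_si * const$redfield_si)) * const$carbon_factor
}

check_flux <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (any(c(a, b) < 0, na.rm = TRUE)) {
    stop("fluxes must be >= 0", call. = FALSE)
  }
  invisible(NULL)
}

#' Critical DIN and TotP concentrations from the Si concentration
#'
#' Setting ICEP to zero and using flux = concentration x runoff gives the
#' nutrient concentrations at which inputs are exactly balanced by Si:
#' DIN_0 = (14 x 16)/(28 x 20) x Si = 0.4 x Si and
#' TotP_0 = 31/(28 x 20) x Si (approximately 0.055 x Si). All three
#' concentrations share the same mass units (ug l^-1 here); measured
#' values above the critical ones imply positive ICEP regardless of
#' runoff.
#'
#' @param si Si concentration, ug l^-1; non-negative vector.
#' @param const Constants list from [element_constants()].
#' @return A tibble with columns `din_0` and `totp_0`, ug l^-1.
#' @examples
#' critical_concentrations(1000)  # din_0 = 400, totp_0 = 55.36
#' @export
critical_concentrations <- function(si, const = element_constants()) {
  stopifnot(is.numeric(si))
  if (any(si < 0, na.rm = TRUE)) {
    stop("Si concentrations must be >= 0", call. = FALSE)
  }
  denom <- const$mass_si * const$redfield_si
  tibble::tibble(
    din_0 = (const$mass_n * const$redfield_n / denom) * si,
    totp_0 = (const$mass_p / denom) * si
  )
}

#' Exceedance ratio of a measured over a critical concentration
#'
#' D = measured / critical; values above 1 indicate the nutrient exceeds
#' what the available Si could balance (positive ICEP). A zero critical
#' concentration (no Si) returns `Inf` with a warning: the sample carries
#' unbounded eutrophication potential on this scale.
#'
#' @param measured,critical Concentrations in the same units (ug l^-1);
#'   equal-length vectors, `measured >= 0`, `critical >= 0`.
#' @return Dimensionless exceedance ratios.
#' @examples
#' exceedance(583, 0.4 * 2702)
#' @export
exceedance <- function(measured, critical) {
  stopifnot(is.numeric(measured), is.numeric(critical))
  if (any(measured < 0, na.rm = TRUE) || any(critical < 0, na.rm = TRUE)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  zero_crit <- !is.na(critical) & critical == 0 &
    !is.na(measured) & measured > 0
  if (any(zero_crit)) {
    warning("critical concentration is zero (no Si): exceedance is Inf",
            call. = FALSE)
  }
  measured / critical
}

#' Full ICEP / critical-concentration assessment for concentration rows
#'
#' Computes critical concentrations and exceedance ratios from mass
#' concentrations, selects the N or P branch with the same molar-N:P rule
#' as the trophic module (ratio >= 16 takes the P branch), and, when a
#' runoff is supplied, converts concentrations to fluxes and evaluates the
#' branch ICEP. Without runoff the ICEP column is `NA`: concentration data
#' are usable on their own through the critical concentrations.
#'
#' @param din,totp,si Mass concentrations, ug l^-1.
#' @param runoff Optional runoff in l km^-2 d^-1 (so concentration in
#'   ug l^-1 times runoff gives ug km^-2 d^-1, converted internally to
#'   kg km^-2 d^-1); `NA` or `NULL` disables flux-based ICEP.
#' @param const Constants list from [element_constants()].
#' @return A tibble with columns `din_0`, `totp_0`, `d_din`, `d_totp`,
#'   `icep`, `icep_basis`.
#' @export
assess_icep <- function(din, totp, si, runoff = NULL,
                        const = element_constants()) {
  n <- max(length(din), length(totp), length(si))
  din <- rep_len(din, n); totp <- rep_len(totp, n); si <- rep_len(si, n)
  crit <- critical_concentrations(si, const)
  d_din <- exceedance(din, crit$din_0)
  d_totp <- exceedance(totp, crit$totp_0)
  np <- (din / const$mass_n) / (totp / const$mass_p)
  use_p <- np >= 16
  if (is.null(runoff) || all(is.na(runoff))) {
    icep <- rep(NA_real_, n)
  } else {
    runoff <- rep_len(runoff, n)
    # ug/l x l km^-2 d^-1 = ug km^-2 d^-1; 1e-9 converts to kg
    icep <- ifelse(use_p,
                   icep_p(totp * runoff * 1e-9, si * runoff * 1e-9, const),
                   icep_n(din * runoff * 1e-9, si * runoff * 1e-9, const))
  }
  tibble::tibble(
    din_0 = crit$din_0,
    totp_0 = crit$totp_0,
    d_din = d_din,
    d_totp = d_totp,
    icep = icep,
    icep_basis = factor(ifelse(use_p, "P", "N"), levels = c("N", "P"))
  )
}
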