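#' Element constants for nutrient stoichiometry
#'
#' Returns the molar masses and Redfield coefficients used by every equation
#' in the package. Integer molar masses (N = 14, P = 31, Si = 28 g mol^-1)
#' are used throughout the index equations so that the critical-concentration
#' factors 0.4 (DIN) and 31/560 (TotP) are reproduced exactly; the
#' silica-dioxide conversion alone uses the precise masses 28.08 and
#' 60.08 g mol^-1.
#'
#' @param redfield_si Redfield Si coefficient relative to N:P = 16:1.
#'   The default 20 gives the 16:1:20 reference used for SDG-style
#'   reporting; 16, 17 and 40 are other published choices (marine to
#'   freshwater diatom stoichiometry).
#'
#' @return A named list with components `mass_n`, `mass_p`, `mass_si`
#'   (integer g mol^-1), `mass_si_precise`, `mass_sio2` (g mol^-1),
#'   `redfield_n`, `redfield_p`, `redfield_si` (molar coefficients) and
#'   `carbon_factor` (106 x 12, g C per Redfield-mole unit).
#' @examples
#' element_constants()$mass_p
#' element_constants(redfield_si = 40)$redfield_si
#' @export
element_constants <- function(redfield_si = 20) {
  stopifnot(is.numeric(redfield_si), length(redfield_si) == 1L,
            is.finite(redfield_si), redfield_si > 0)
  list(
    mass_n = 14,
    mass_p = 31,
    mass_si = 28,
    mass_si_precise = 28.08,
    mass_sio2 = 60.08,
    redfield_n = 16,
    redfield_p = 1,
    redfield_si = redfield_si,
    carbon_factor = 106 * 12
  )
}

element_mass <- function(element, const = element_constants()) {
  element <- match.arg(element, c("N", "P", "Si"), several.ok = FALSE)
  switch(element, N = const$mass_n, P = const$mass_p, Si = const$mass_si)
}

#' Convert a mass concentration to a molar concentration
#'
#' @param mass_conc Concentration in ug l^-1 of the element (not of an
#'   oxide); may be a vector, `NA` allowed.
#' @param element One of `"N"`, `"P"`, `"Si"`.
#' @param const Constants list from [element_constants()].
#' @return Concentration in umol l^-1.
#' @examples
#' to_molar(31, "P")   # 1 umol/l
#' to_molar(2702, "Si")
#' @seealso [from_molar()]
#' @export
to_molar <- function(mass_conc, element, const = element_constants()) {
  stopifnot(is.numeric(mass_conc))
  if (any(mass_conc < 0, na.rm = TRUE)) {
    stop("mass concentrations must be >= 0", call. = FALSE)
  }
  mass_conc / element_mass(element, const)
}

#' Convert a molar concentration back to a mass concentration
#'
#' Inverse of [to_molar()]; `from_molar(to_molar(x, e), e)` round-trips to
#' within floating-point precision.
#'
#' @inheritParams to_molar
#' @param molar_conc Concentration in umol l^-1.
#' @return Concentration in ug l^-1.
#' @export
from_molar <- function(molar_conc, element, const = element_constants()) {
  stopifnot(is.numeric(molar_conc))
  if (any(molar_conc < 0, na.rm = TRUE)) {
    stop("molar concentrations must be >= 0", call. = FALSE)
  }
  molar_conc * element_mass(element, const)
}

#' Convert silica reported as SiO2 to elemental Si
#'
#' Uses the precise molar masses 28.08 (Si) and 60.08 (SiO2) g mol^-1,
#' the convention of Nordic monitoring programmes that report dissolved
#' silica as the oxide.
#'
#' @param sio2 SiO2 concentration, ug l^-1; vectorised, `NA` allowed.
#' @return Si concentration, ug l^-1.
#' @examples
#' si_from_sio2(60.08)  # one mole-mass of SiO2 -> 28.08
#' @export
si_from_sio2 <- function(sio2) {
  stopifnot(is.numeric(sio2))
  if (any(sio2 < 0, na.rm = TRUE)) {
    stop("SiO2 concentrations must be >= 0", call. = FALSE)
  }
  sio2 * 28.08 / 60.08
}

#' Assemble a molar DIN/TotP/Si triplet from mass concentrations
#'
#' @param din,totp,si Mass concentrations in ug l^-1 (elemental basis);
#'   equal-length vectors.
#' @param const Constants list from [element_constants()].
#' @return A tibble with columns `din`, `totp`, `si` in umol l^-1.
#' @export
molar_triplet <- function(din, totp, si, const = element_constants()) {
  tibble::tibble(
    din = to_molar(din, "N", const),
    totp = to_molar(totp, "P", const),
    si = to_molar(si, "Si", const)
  )
}
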