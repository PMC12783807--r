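#' Redfield-scaled ternary percentages
#'
#' Scales a molar DIN/TotP/Si triplet by the Redfield coefficients
#' (N/16, P/1, Si/si_term) and expresses each scaled component as a
#' percentage of their sum, so that a sample with molar N:P:Si exactly
#' 16:1:20 plots at the centre of the ternary diagram (33.3/33.3/33.3).
#'
#' @param din,totp,si Molar concentrations, umol l^-1; equal-length
#'   vectors, all components >= 0 and at least one > 0 per sample.
#' @param const Constants list from [element_constants()]; its
#'   `redfield_si` sets the Si scaling term (default 20).
#' @return A tibble with columns `n_pct`, `p_pct`, `si_pct` summing to 100.
#' @examples
#' redfield_percentages(16, 1, 20)       # centre: 33.3/33.3/33.3
#' redfield_percentages(32, 1, 20)       # N-enriched: 50/25/25
#' @export
redfield_percentages <- function(din, totp, si, const = element_constants()) {
  stopifnot(is.numeric(din), is.numeric(totp), is.numeric(si))
  n <- max(length(din), length(totp), length(si))
  din <- rep_len(din, n); totp <- rep_len(totp, n); si <- rep_len(si, n)
  if (any(c(din, totp, si) < 0, na.rm = TRUE)) {
    stop("molar concentrations must be >= 0", call. = FALSE)
  }
  sn <- din / const$redfield_n
  sp <- totp / const$redfield_p
  ss <- si / const$redfield_si
  denom <- sn + sp + ss
  bad <- !is.na(denom) & denom == 0
  if (any(bad)) {
    stop("all-zero triplet: ternary composition undefined", call. = FALSE)
  }
  tibble::tibble(
    n_pct = 100 * sn / denom,
    p_pct = 100 * sp / denom,
    si_pct = 100 * ss / denom
  )
}

zone_levels <- function() {
  c("N_depleted", "P_depleted", "Si_depleted",
    "NP_depleted", "NSi_depleted", "PSi_depleted", "balanced")
}

#' Classify a ternary composition into nutrient-depletion zones
#'
#' An element is depleted when its Redfield percentage is strictly below
#' the threshold ("less than 20%"); a percentage exactly at the threshold
#' counts as not depleted. The zone names the depleted set: singletons,
#' pairs (e.g. joint N and P depletion, the diamond at the top of the
#' ternary diagram), or `balanced` when no element is depleted.
#'
#' @param n_pct,p_pct,si_pct Ternary percentages; vectors recycled to a
#'   common length. Each sample's three values must sum to 100.
#' @param threshold Depletion threshold in percent, inside (0, 100/3):
#'   above 100/3 all three components could be "depleted" at once, which
#'   the percentages make impossible.
#' @return A factor with levels `N_depleted`, `P_depleted`, `Si_depleted`,
#'   `NP_depleted`, `NSi_depleted`, `PSi_depleted`, `balanced`.
#' @examples
#' classify_zone(33.3, 33.3, 33.4)   # balanced
#' classify_zone(70, 10, 20)         # P_depleted (Si at 20 is not depleted)
#' classify_zone(15, 15, 70)         # NP_depleted
#' @export
classify_zone <- function(n_pct, p_pct, si_pct, threshold = 20) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  if (!is.finite(threshold) || threshold <= 0 || threshold >= 100 / 3) {
    stop("threshold must lie strictly between 0 and 100/3 percent",
         call. = FALSE)
  }
  n <- max(length(n_pct), length(p_pct), length(si_pct))
  n_pct <- rep_len(n_pct, n); p_pct <- rep_len(p_pct, n)
  si_pct <- rep_len(si_pct, n)
  total <- n_pct + p_pct + si_pct
  if (any(abs(total - 100) > 0.01, na.rm = TRUE)) {
    stop("ternary percentages must sum to 100", call. = FALSE)
  }
  dep_n <- n_pct < threshold
  dep_p <- p_pct < threshold
  dep_si <- si_pct < threshold
  zone <- dplyr::case_when(
    dep_n & dep_p ~ "NP_depleted",
    dep_n & dep_si ~ "NSi_depleted",
    dep_p & dep_si ~ "PSi_depleted",
    dep_n ~ "N_depleted",
    dep_p ~ "P_depleted",
    dep_si ~ "Si_depleted",
    !is.na(dep_n) ~ "balanced",
    TRUE ~ NA_character_
  )
  factor(zone, levels = zone_levels())
}

#' Map ternary percentages to planar coordinates
#'
#' Standard barycentric-to-Cartesian mapping onto an equilateral triangle
#' of unit side. By default the N vertex is at top, P at bottom-left and
#' Si at bottom-right, which places the joint N+P depletion region along
#' the upper-left edge region of the plot; the vertex order is
#' configurable.
#'
#' @inheritParams classify_zone
#' @param order Character vector of length 3, a permutation of
#'   `c("N", "P", "Si")`, read as (top, bottom-left, bottom-right).
#' @return A tibble with columns `x`, `y`; the centroid of the triangle is
#'   at (0.5, sqrt(3)/6) and the top vertex at (0.5, sqrt(3)/2).
#' @examples
#' ternary_xy(100, 0, 0)                # N apex
#' ternary_xy(100 / 3, 100 / 3, 100 / 3)  # centroid
#' @export
ternary_xy <- function(n_pct, p_pct, si_pct, order = c("N", "P", "Si")) {
  if (length(order) != 3L || !setequal(order, c("N", "P", "Si"))) {
    stop("`order` must be a permutation of c(\"N\", \"P\", \"Si\")",
         call. = FALSE)
  }
  n <- max(length(n_pct), length(p_pct), length(si_pct))
  frac <- list(
    N = rep_len(n_pct, n) / 100,
    P = rep_len(p_pct, n) / 100,
    Si = rep_len(si_pct, n) / 100
  )
  top <- frac[[order[1]]]; left <- frac[[order[2]]]; right <- frac[[order[3]]]
  tibble::tibble(
    x = right + top / 2,
    y = top * sqrt(3) / 2
  )
}

#' Ternary frame coordinates for plotting
#'
#' Triangle outline and vertex labels matching [ternary_xy()].
#'
#' @inheritParams ternary_xy
#' @return A list with `frame` (closed triangle path) and `labels`
#'   (vertex label positions and text).
#' @keywords internal
ternary_frame <- function(order = c("N", "P", "Si")) {
  verts <- tibble::tibble(
    x = c(0.5, 0, 1, 0.5),
    y = c(sqrt(3) / 2, 0, 0, sqrt(3) / 2)
  )
  labs <- tibble::tibble(
    x = c(0.5, -0.03, 1.03),
    y = c(sqrt(3) / 2 + 0.05, -0.04, -0.04),
    label = order
  )
  list(frame = verts, labels = labs)
}
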