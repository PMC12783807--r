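tsi_palette <- function() {
  c(ultra_oligotrophic = "#90EE90", oligotrophic = "#006400",
    mesotrophic = "#FFD700", eutrophic = "#FF8C00",
    hypereutrophic = "#CC0000")
}

#' Ternary diagram of site compositions coloured by trophic class
#'
#' Redfield-scaled ternary scatter of overall site compositions, with the
#' 16:1:20 reference composition at the centroid and the depletion
#' threshold drawn as chords. N at top, P bottom-left, Si bottom-right by
#' default, so joint N+P depletion plots in the region near the lower
#' edge's opposite (the N-P side of the diagram).
#'
#' @param summary Site summary from [site_summary()].
#' @param threshold Depletion threshold to draw, percent.
#' @param order Vertex order, see [ternary_xy()].
#' @return A ggplot object.
#' @export
plot_ternary <- function(summary, threshold = 20,
                         order = c("Si", "N", "P")) {
  fr <- ternary_frame(order)
  xy <- ternary_xy(summary$n_pct, summary$p_pct, summary$si_pct, order)
  pts <- dplyr::bind_cols(summary[, c("site_id", "tsi_class")], xy)
  thr <- threshold
  chord <- function(which_vertex) {
    # points where the named component equals the threshold
    base <- c(N = 0, P = 0, Si = 0)
    a <- base; a[which_vertex] <- thr
    rest <- setdiff(names(base), which_vertex)
    a1 <- a; a1[rest[1]] <- 100 - thr
    a2 <- a; a2[rest[2]] <- 100 - thr
    p1 <- ternary_xy(a1[["N"]], a1[["P"]], a1[["Si"]], order)
    p2 <- ternary_xy(a2[["N"]], a2[["P"]], a2[["Si"]], order)
    tibble::tibble(x = p1$x, y = p1$y, xend = p2$x, yend = p2$y,
                   comp = which_vertex)
  }
  chords <- dplyr::bind_rows(lapply(c("N", "P", "Si"), chord))
  ggplot2::ggplot() +
    ggplot2::geom_path(data = fr$frame, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_segment(data = chords,
                          ggplot2::aes(.data$x, .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(.data$x, .data$y,
                                     colour = .data$tsi_class), size = 2) +
    ggplot2::geom_text(data = fr$labels,
                       ggplot2::aes(.data$x, .data$y, label = .data$label)) +
    ggplot2::scale_colour_manual(values = tsi_palette(), drop = FALSE,
                                 name = "Trophic class") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' DIN versus TotP scatter with trophic-class boundary lines
#'
#' Overall mean concentrations per site on log axes, with vertical lines
#' at the TotP concentrations where TSI(TotP) crosses its class
#' boundaries, horizontal lines for TSI(DIN), and the molar Redfield
#' N:P = 16 line (dotted).
#'
#' @param summary Site summary from [site_summary()].
#' @param const Constants list from [element_constants()].
#' @return A ggplot object.
#' @export
plot_din_totp <- function(summary, const = element_constants()) {
  bounds <- c(30, 40, 50, 60)
  # invert the TSI equations at each class boundary (ug/l)
  totp_b <- exp((bounds - 4.15) / 14.42)
  din_b <- 1000 * exp((bounds - 54.45) / 14.43)
  # molar N:P = 16 in mass units: DIN = 16 * (14/31) * TotP
  np_line <- tibble::tibble(
    totp = range(summary$totp),
    din = 16 * const$mass_n * range(summary$totp) / const$mass_p
  )
  ggplot2::ggplot(summary, ggplot2::aes(.data$totp, .data$din)) +
    ggplot2::geom_vline(xintercept = totp_b, colour = "grey40") +
    ggplot2::geom_hline(yintercept = din_b, colour = "grey40") +
    ggplot2::geom_line(data = np_line, linetype = "dotted") +
    ggplot2::geom_point(colour = "steelblue", size = 2) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(TotP ~ (mu * g ~ l^-1)),
                  y = expression(DIN ~ (mu * g ~ l^-1))) +
    ggplot2::theme_bw()
}

#' Overall versus minimum monthly Redfield Si percentage by season
#'
#' One point per site: the overall Si percentage against the most
#' Si-depleted calendar month's percentage, coloured by the season of
#' that month. Points below the threshold line are seasonally Si
#' depleted even when the overall average is not.
#'
#' @param summary Site summary from [site_summary()].
#' @param threshold Depletion threshold, percent.
#' @return A ggplot object.
#' @export
plot_min_si <- function(summary, threshold = 20) {
  pal <- c(spring = "#E6C800", summer = "#2166AC",
           autumn = "#E08214", winter = "#6A3D9A")
  ggplot2::ggplot(summary,
                  ggplot2::aes(.data$si_pct, .data$min_si_pct,
                               colour = .data$min_si_season)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70") +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = pal, drop = FALSE,
                                 name = "Season of minimum") +
    ggplot2::labs(x = "Overall Redfield Si (%)",
                  y = "Minimum monthly Redfield Si (%)") +
    ggplot2::theme_bw()
}

#' Exceedance ratios versus measured concentrations
#'
#' Overall exceedance ratio against the overall mean concentration for
#' DIN and TotP, with vertical bars spanning the monthly minimum and
#' maximum ratios. Sites whose overall ratio is below one are drawn in
#' green (no exceedance), others in red.
#'
#' @param summary Site summary from [site_summary()].
#' @return A ggplot object.
#' @export
plot_exceedance <- function(summary) {
  long <- dplyr::bind_rows(
    tibble::tibble(site_id = summary$site_id, nutrient = "DIN",
                   conc = summary$din, d = summary$d_din,
                   dmin = summary$d_din_month_min,
                   dmax = summary$d_din_month_max),
    tibble::tibble(site_id = summary$site_id, nutrient = "TotP",
                   conc = summary$totp, d = summary$d_totp,
                   dmin = summary$d_totp_month_min,
                   dmax = summary$d_totp_month_max)
  ) |>
    dplyr::mutate(status = ifelse(.data$d < 1, "below", "exceeds"))
  ggplot2::ggplot(long, ggplot2::aes(.data$conc, .data$d)) +
    ggplot2::geom_hline(yintercept = 1, colour = "grey40") +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$dmin,
                                         ymax = .data$dmax),
                            colour = "grey60", linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$status), size = 2) +
    ggplot2::scale_colour_manual(
      values = c(below = "forestgreen", exceeds = "firebrick"),
      name = NULL) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~nutrient, scales = "free_x") +
    ggplot2::labs(x = expression(Concentration ~ (mu * g ~ l^-1)),
                  y = "Exceedance ratio") +
    ggplot2::theme_bw()
}
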