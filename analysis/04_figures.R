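#!/usr/bin/env Rscript
# Step 4 — render the summary figures from the assessment outputs.
#
# Ternary diagram coloured by trophic class, DIN-vs-TotP scatter with
# TSI boundaries and the Redfield N:P line, overall-vs-minimum monthly
# Si percentage by season, and exceedance ratios with monthly ranges.
# Plot failures are reported but never abort the run.

suppressPackageStartupMessages(library(riverstoich))

d <- synth_generate(synth_config(n_sites = 50, seed = 20170L))
res <- run_assessment(d$samples, sites = d$sites)
s <- res$summary

fig_dir <- "results/figures"
dir.create(fig_dir, recursive = TRUE, showWarnings = FALSE)

save_fig <- function(plot, name, width = 7, height = 6) {
  tryCatch({
    ggplot2::ggsave(file.path(fig_dir, name), plot,
                    width = width, height = height, dpi = 150)
    cat("wrote", file.path(fig_dir, name), "\n")
  }, error = function(e) {
    message("figure ", name, " failed: ", conditionMessage(e))
  })
}

save_fig(plot_ternary(s), "ternary_tsi.png")
save_fig(plot_din_totp(s), "din_vs_totp.png")
save_fig(plot_min_si(s), "min_monthly_si.png")
save_fig(plot_exceedance(s), "exceedance.png", width = 9, height = 5)
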