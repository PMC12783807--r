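test_that("the generator is fully determined by its seed", {
  a <- synth_generate(synth_config(n_sites = 5, seed = 99))
  b <- synth_generate(synth_config(n_sites = 5, seed = 99))
  expect_identical(a, b)
  c <- synth_generate(synth_config(n_sites = 5, seed = 100))
  expect_false(identical(a$samples, c$samples))
})

test_that("noiseless generation reproduces site medians exactly", {
  cfg <- synth_config(n_sites = 8, noise_cv = 0, si_drawdown = 0, seed = 3)
  d <- synth_generate(cfg)
  merged <- dplyr::left_join(
    d$samples |>
      dplyr::group_by(site_id) |>
      dplyr::summarise(din = mean(no3_no2 + nh4), totp = mean(totp),
                       si = mean(si)),
    d$truth, by = "site_id")
  expect_equal(merged$din, merged$din_med)
  expect_equal(merged$totp, merged$totp_med)
  expect_equal(merged$si, merged$si_med)
  # pipeline zone equals truth zone for every site
  res <- run_assessment(d$samples)
  m <- dplyr::inner_join(res$summary, d$truth, by = "site_id",
                         suffix = c("", ".t"))
  expect_equal(as.character(m$zone), as.character(m$true_zone))
})

test_that("a noiseless May trough puts every site's minimum Si in May", {
  cfg <- synth_config(n_sites = 6, noise_cv = 0, si_drawdown = 0.3,
                      si_trough_month = 5, seed = 4)
  d <- synth_generate(cfg)
  res <- run_assessment(d$samples)
  expect_true(all(res$summary$min_si_month == 5))
  expect_true(all(res$summary$min_si_season == "spring"))
  expect_true(all(d$truth$true_min_si_month == 5))
})

test_that("generated data always pass QC when nothing is missing", {
  d <- synth_generate(synth_config(n_sites = 12, missingness = 0, seed = 5))
  h <- harmonize_samples(d$samples)
  kept <- qc_retain(h)
  expect_setequal(unique(kept$site_id), d$sites$site_id)
})

test_that("site-median Si shows no latitude gradient at defaults", {
  d <- synth_generate(synth_config(n_sites = 50, seed = 6))
  rho <- cor(d$sites$lat, d$truth$si_med, method = "spearman")
  expect_lt(abs(rho), 0.3)
  # while DIN and TotP do decrease northward
  expect_lt(cor(d$sites$lat, d$truth$din_med, method = "spearman"), -0.5)
  expect_lt(cor(d$sites$lat, d$truth$totp_med, method = "spearman"), -0.5)
})

test_that("inverse site design hits requested zones and trophic classes", {
  combos <- expand.grid(zone = c(
    "balanced", "N_depleted", "P_depleted", "Si_depleted",
    "NP_depleted", "NSi_depleted", "PSi_depleted"),
    cls = c("ultra_oligotrophic", "mesotrophic", "hypereutrophic"),
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    s <- make_redfield_site(combos$zone[i], combos$cls[i])
    expect_equal(as.character(s$zone), combos$zone[i])
    expect_equal(as.character(s$tsi_class), combos$cls[i])
    # oracle re-check through the forward equations
    m <- molar_triplet(s$din, s$totp, s$si)
    p <- redfield_percentages(m$din, m$totp, m$si)
    expect_equal(as.character(classify_zone(p$n_pct, p$p_pct, p$si_pct)),
                 combos$zone[i])
  }
  bal <- make_redfield_site("balanced", "mesotrophic")
  expect_gte(bal$tsi, 40); expect_lt(bal$tsi, 50)
  no_class <- make_redfield_site("Si_depleted")
  p <- redfield_percentages(no_class$din / 14, no_class$totp / 31,
                            no_class$si / 28)
  expect_lt(p$si_pct, 20)
})

test_that("degenerate generator configurations are rejected", {
  expect_error(synth_config(n_sites = 0))
  expect_error(synth_config(si_drawdown = 1))
  expect_error(synth_config(si_median = -1))
  expect_error(synth_config(si_trough_month = 13))
})
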