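test_that("every retained site appears exactly once per output table", {
  d <- synth_generate(synth_config(n_sites = 8, seed = 41))
  res <- run_assessment(d$samples, sites = d$sites)
  expect_equal(nrow(res$summary), nrow(d$truth))
  expect_equal(anyDuplicated(res$summary$site_id), 0L)
  expect_setequal(res$summary$site_id, d$truth$site_id)
  expect_equal(dplyr::count(res$agg$monthly, site_id)$n, rep(12L, 8))
})

test_that("reruns on identical inputs produce identical outputs", {
  d <- synth_generate(synth_config(n_sites = 4, seed = 42))
  r1 <- run_assessment(d$samples)
  r2 <- run_assessment(d$samples)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$manifest$config_hash, r2$manifest$config_hash)
})

test_that("the manifest hash changes iff configuration changes", {
  d <- synth_generate(synth_config(n_sites = 4, seed = 43))
  base <- run_assessment(d$samples)
  same <- run_assessment(d$samples)
  other <- run_assessment(d$samples, threshold = 25)
  expect_identical(base$manifest$config_hash, same$manifest$config_hash)
  expect_false(identical(base$manifest$config_hash,
                         other$manifest$config_hash))
})

test_that("single-site single-year input matches per-sample means", {
  x <- monthly_site("solo", years = 2019, din = seq(100, 1200, by = 100),
                    totp = 25, si = 2500)
  res <- run_assessment(x, window = as.Date(c("2019-01-01", "2019-12-31")))
  s <- res$summary
  expect_equal(nrow(s), 1L)
  expect_equal(s$din, mean(seq(100, 1200, by = 100)))
  expect_equal(s$totp, 25)
  expect_equal(s$si, 2500)
  # overall percentages are the mean of the 12 per-sample percentages
  per <- redfield_percentages(x$din / 14, x$totp / 31, x$si / 28)
  expect_equal(s$n_pct, mean(per$n_pct))
  expect_equal(s$si_pct, mean(per$si_pct))
})

test_that("output files are written with the documented names", {
  d <- synth_generate(synth_config(n_sites = 3, seed = 44))
  out <- withr::local_tempdir()
  run_assessment(d$samples, sites = d$sites, out_dir = out)
  expect_true(file.exists(file.path(out, "site_summary.csv")))
  expect_true(file.exists(file.path(out, "monthly_metrics.csv")))
  expect_true(file.exists(file.path(out, "run_manifest.json")))
  written <- readr::read_csv(file.path(out, "site_summary.csv"),
                             show_col_types = FALSE)
  expect_equal(nrow(written), 3L)
  man <- jsonlite::read_json(file.path(out, "run_manifest.json"))
  expect_equal(man$n_sites_retained, 3L)
})

test_that("zero retained sites is an explicit failure", {
  x <- monthly_site("A", years = 2020, months = 1:3)  # fails QC everywhere
  expect_error(run_assessment(x), "no sites retained")
})

test_that("YAML run configuration maps onto assessment arguments", {
  cfg <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("window:", "  start: 2018-01-01", "  end: 2020-12-31",
               "qc:", "  min_obs_per_year: 4",
               "bdl:", "  policy: as_is",
               "redfield:", "  si_term: 40",
               "threshold: 25"), cfg)
  args <- read_run_config(cfg)
  expect_equal(args$window, as.Date(c("2018-01-01", "2020-12-31")))
  expect_equal(args$min_obs, 4)
  expect_equal(args$bdl_policy, "as_is")
  expect_equal(args$redfield_si, 40)
  expect_equal(args$threshold, 25)
  # a config-driven run honours the window and QC settings
  x <- monthly_site("A", years = 2018:2020)
  res <- do.call(run_assessment, c(list(samples = x), args))
  expect_equal(nrow(res$summary), 1L)
})

test_that("plot builders return ggplot objects without error", {
  d <- synth_generate(synth_config(n_sites = 6, seed = 45))
  s <- run_assessment(d$samples)$summary
  expect_s3_class(plot_ternary(s), "ggplot")
  expect_s3_class(plot_din_totp(s), "ggplot")
  expect_s3_class(plot_min_si(s), "ggplot")
  expect_s3_class(plot_exceedance(s), "ggplot")
})
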