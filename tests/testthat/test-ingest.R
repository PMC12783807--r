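test_that("DIN sums the available inorganic nitrogen species", {
  expect_equal(compute_din(400, 50), 450)
  expect_equal(compute_din(0, 0), 0)
  expect_equal(compute_din(583, NA), 583)   # missing species contribute 0
  expect_equal(compute_din(NA, 120), 120)
  expect_true(is.na(compute_din(NA, NA)))   # unusable for N metrics
  expect_error(compute_din(-1, 5))
})

test_that("DIN is invariant to species order", {
  a <- runif(20, 0, 1000); b <- runif(20, 0, 200)
  expect_equal(compute_din(a, b), compute_din(b, a))
})

test_that("harmonization converts SiO2 only where Si is absent", {
  x <- raw_rows(
    site_id = "A", date = as.Date("2018-06-01") + 0:2,
    no3_no2 = c(100, 200, 300), nh4 = c(10, NA, 30),
    totp = c(20, 20, 20),
    si = c(1000, NA, NA), sio2 = c(9999, 60.08, NA)
  )
  h <- harmonize_samples(x)
  expect_equal(h$si, c(1000, 28.08, NA_real_))
  expect_equal(h$din, c(110, 200, 330))
})

test_that("harmonization averages duplicate site-date records", {
  x <- raw_rows(
    site_id = "A", date = as.Date(rep("2019-03-10", 2)),
    no3_no2 = c(100, 300), nh4 = c(0, 0),
    totp = c(10, 30), si = c(1000, 3000)
  )
  h <- harmonize_samples(x)
  expect_equal(nrow(h), 1L)
  expect_equal(h$din, 200)
  expect_equal(h$totp, 20)
  expect_equal(h$si, 2000)
})

test_that("harmonization applies window, depth filter and BDL policy", {
  x <- raw_rows(
    site_id = "A",
    date = as.Date(c("2016-12-31", "2017-01-01", "2024-12-31", "2025-01-01")),
    no3_no2 = 100, nh4 = 0, totp = c(5, 1, 1, 5), si = 1000,
    detection_limit_totp = 4, depth = c(0.5, 0.5, 0.5, 0.5)
  )
  h <- harmonize_samples(x)
  expect_equal(as.character(h$date), c("2017-01-01", "2024-12-31"))
  expect_equal(h$totp, c(2, 2))  # below limit 4 -> half the limit
  h2 <- harmonize_samples(x, bdl_policy = "as_is")
  expect_equal(h2$totp, c(1, 1))
  # deep samples are excluded
  x$depth <- c(0.5, 5, 0.5, 0.5)
  expect_equal(nrow(harmonize_samples(x)), 1L)
})

test_that("QC retains sites with at least min_obs usable samples every year", {
  full <- monthly_site("full")                   # 12 obs each year
  six <- monthly_site("six", months = 1:6)       # exactly 6 each year
  gap <- dplyr::bind_rows(
    monthly_site("gap", years = setdiff(2017:2024, 2019)),
    monthly_site("gap", years = 2019, months = 1:5)  # 5 obs in 2019
  )
  all3 <- dplyr::bind_rows(full, six, gap)
  kept <- qc_retain(all3)
  expect_setequal(unique(kept$site_id), c("full", "six"))
  dropped <- attr(kept, "dropped")
  expect_true(all(dropped$site_id == "gap"))
  expect_equal(dropped$year[dropped$n_usable == 5], 2019)
})

test_that("QC requires DIN, TotP and Si jointly and is idempotent", {
  x <- monthly_site("A")
  x$si[x$date >= as.Date("2020-01-01") & x$date < as.Date("2020-08-01")] <- NA
  kept <- qc_retain(x)   # 2020 has only 5 jointly-usable obs
  expect_equal(nrow(kept), 0L)
  y <- monthly_site("B")
  once <- qc_retain(y)
  twice <- qc_retain(once)
  expect_equal(as.data.frame(twice), as.data.frame(once))
  expect_warning(qc_retain(y[0, ]), "empty")
})

test_that("sample table reader enforces the column contract", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(raw_rows(site_id = "A", date = "2018-01-01",
                            no3_no2 = 1, totp = 2, si = 3), tmp)
  x <- read_samples(tmp)
  expect_s3_class(x$date, "Date")
  readr::write_csv(raw_rows(site_id = "A", date = "2018-01-01", totp = 2,
                            si = 3), tmp)
  expect_error(read_samples(tmp), "nitrogen")
  readr::write_csv(raw_rows(site_id = "A", date = "2018-01-01",
                            no3_no2 = 1, totp = 2), tmp)
  expect_error(read_samples(tmp), "silica")
})
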