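test_that("overall mean is the mean of annual means, not the pooled mean", {
  # year A: 12 samples with metric mean 10; year B: 6 samples, mean 20
  x <- dplyr::bind_rows(
    monthly_site("A", years = 2017, din = 10),
    monthly_site("A", years = 2018, din = 20, months = 1:6)
  )
  agg <- aggregate_metrics(x, cols = "din")
  expect_equal(agg$overall$din, 15)   # pooled mean would be 40/3
  expect_equal(sort(agg$annual$din), c(10, 20))
  pooled <- mean(x$din)
  expect_false(isTRUE(all.equal(agg$overall$din, pooled)))
})

test_that("single-year monthly data collapse to the plain mean", {
  x <- monthly_site("A", years = 2020, din = 1:12)
  agg <- aggregate_metrics(x, cols = "din")
  expect_equal(agg$overall$din, mean(1:12))
  expect_equal(agg$monthly$din, as.numeric(1:12))
})

test_that("constant metrics aggregate to the constant", {
  x <- monthly_site("A", din = 7, totp = 7, si = 7)
  agg <- aggregate_metrics(x, cols = c("din", "totp", "si"))
  expect_true(all(agg$overall[, c("din", "totp", "si")] == 7))
  expect_true(all(agg$monthly$din == 7))
  expect_true(all(agg$annual$din == 7))
})

test_that("aggregation is invariant to row permutation", {
  set.seed(31)
  x <- monthly_site("A", din = rlnorm(96, 6, 0.5),
                    totp = rlnorm(96, 3, 0.5), si = rlnorm(96, 8, 0.3))
  shuffled <- x[sample(nrow(x)), ]
  a1 <- aggregate_metrics(x, cols = c("din", "totp", "si"))
  a2 <- aggregate_metrics(shuffled, cols = c("din", "totp", "si"))
  expect_equal(a1$overall, a2$overall)
  expect_equal(a1$monthly, a2$monthly)
})

test_that("balanced designs make two-step and pooled monthly means agree", {
  set.seed(32)
  x <- monthly_site("A", din = rlnorm(96, 6, 0.5))
  two <- aggregate_metrics(x, cols = "din", mode = "two_step")
  pooled <- aggregate_metrics(x, cols = "din", mode = "pooled")
  expect_equal(two$monthly$din, pooled$monthly$din)
  expect_equal(two$overall$din, mean(x$din))
  # unbalanced within a month: the two orders differ
  y <- dplyr::bind_rows(x, x[x$date == as.Date("2017-01-15"), ])
  y$din[nrow(y)] <- 1e5
  two2 <- aggregate_metrics(y, cols = "din")
  pooled2 <- aggregate_metrics(y, cols = "din", mode = "pooled")
  jan_two <- two2$monthly$din[two2$monthly$month == 1]
  jan_pool <- pooled2$monthly$din[pooled2$monthly$month == 1]
  expect_false(isTRUE(all.equal(jan_two, jan_pool)))
})

test_that("overall mean lies within the annual means", {
  set.seed(33)
  x <- monthly_site("A", din = rlnorm(96, 6, 1))
  agg <- aggregate_metrics(x, cols = "din")
  expect_gte(agg$overall$din, min(agg$annual$din))
  expect_lte(agg$overall$din, max(agg$annual$din))
})

test_that("months map to meteorological seasons", {
  expect_equal(as.character(month_season(c(3, 5, 6, 8, 9, 11, 12, 1, 2))),
               c("spring", "spring", "summer", "summer", "autumn",
                 "autumn", "winter", "winter", "winter"))
  expect_error(month_season(13))
})

test_that("minimum monthly Si scan finds month, season and depletion", {
  mo <- tibble::tibble(site_id = "A", month = 1:12,
                       si_pct = c(rep(50, 4), 18, rep(50, 7)))
  out <- seasonal_min_si(mo)
  expect_equal(out$min_si_pct, 18)
  expect_equal(out$min_si_month, 5L)
  expect_equal(as.character(out$min_si_season), "spring")
  expect_true(out$si_depleted_month)
  # December minimum is winter
  mo$si_pct <- c(rep(50, 11), 25)
  out2 <- seasonal_min_si(mo)
  expect_equal(out2$min_si_month, 12L)
  expect_equal(as.character(out2$min_si_season), "winter")
  expect_false(out2$si_depleted_month)
  # constant values tie to the earliest month
  mo$si_pct <- 45
  out3 <- seasonal_min_si(mo)
  expect_equal(out3$min_si_month, 1L)
  expect_equal(out3$min_si_pct, 45)
  expect_error(seasonal_min_si(mo[0, ]), "no monthly")
})
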