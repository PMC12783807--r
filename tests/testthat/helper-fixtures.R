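# Build a harmonized sample tibble from vectors (din/totp/si in ug/l).
make_samples <- function(site_id, date, din, totp, si) {
  tibble::tibble(site_id = site_id, date = as.Date(date),
                 din = din, totp = totp, si = si)
}

# One site with monthly samples covering the given years.
monthly_site <- function(site_id = "A", years = 2017:2024,
                         din = 500, totp = 30, si = 2700,
                         months = 1:12) {
  grid <- expand.grid(year = years, month = months)
  make_samples(
    site_id,
    sprintf("%d-%02d-15", grid$year, grid$month),
    rep_len(din, nrow(grid)), rep_len(totp, nrow(grid)),
    rep_len(si, nrow(grid))
  )
}

# Raw-dialect (pre-harmonization) rows for ingest tests.
raw_rows <- function(...) tibble::tibble(...)
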