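test_that("rarity filter uses a strict study-wide threshold", {
  rec <- toy_records(c("common", "boundary", "rare"), c(100, 75, 74))
  out <- filter_rare(rec, threshold = 75)
  expect_setequal(unique(out$species), c("common", "boundary"))
  expect_equal(nrow(filter_rare(rec[0, ])), 0)
})

test_that("monthly rates divide counts by surveyed days", {
  cal <- tibble::tibble(month = month_seq("1998-01", 2),
                        market_days = c(30L, 20L))
  rec <- toy_records("sp", 30, month = "1998-01")
  s <- monthly_rates(rec, cal)
  expect_equal(s$value, c(1, 0))

  cal0 <- tibble::tibble(month = as_month("1998-01"), market_days = 0L)
  expect_error(monthly_rates(rec, cal0), "1998-01")
})

test_that("monthly rates equal a record-by-record brute-force tally", {
  set.seed(42)
  months <- month_seq("1999-03", 8)
  cal <- tibble::tibble(month = months,
                        market_days = sample(20:26, 8, replace = TRUE))
  n <- 300
  rec <- tibble::tibble(
    date = sample(months, n, replace = TRUE) +
      sample(0:27, n, replace = TRUE),
    species = sample(c("a", "b"), n, replace = TRUE),
    group = "rodent",
    method = sample(c("trap", "shotgun"), n, replace = TRUE),
    origin = "island", condition = "fresh", price_fcfa = 500
  )
  rec$date <- pmin(rec$date, max(months) + 27) # stay inside the window
  s <- monthly_rates(rec, cal, method = "trap")
  brute <- vapply(seq_along(months), function(i) {
    hits <- 0
    for (r in seq_len(n)) {
      same_month <- format(rec$date[r], "%Y-%m") == format(months[i], "%Y-%m")
      if (same_month && rec$method[r] == "trap") hits <- hits + 1
    }
    hits / cal$market_days[i]
  }, numeric(1))
  expect_equal(s$value, brute)
})

test_that("gap imputation averages the two neighbours only", {
  s <- monthly_series(month_seq("2001-01", 3), c(2, NA, 4))
  expect_equal(impute_gap(s, "2001-02")$value[2], 3)
  s_eq <- monthly_series(month_seq("2001-01", 3), c(5, NA, 5))
  expect_equal(impute_gap(s_eq, "2001-02")$value[2], 5)
  s_chain <- monthly_series(month_seq("2001-01", 4), c(2, NA, NA, 4))
  expect_error(impute_gap(s_chain, "2001-02"), "chained")
  expect_error(impute_gap(s, "2001-01"), "first or last")
})

test_that("the study-shaped scenario yields a gap-free series after imputation", {
  cfg <- default_scenario(seed = 2)
  cen <- generate_census(cfg)
  s <- monthly_rates(cen$records, cen$calendar, group = "primate")
  expect_identical(which(is.na(s$value)),
                   which(s$month == as_month("2001-02")))
  s <- impute_gap(s, "2001-02")
  expect_false(anyNA(s$value))
  expect_equal(nrow(s), 156L)
  expect_equal(range(s$month), as_month(c("1997-10", "2010-09")))
})

test_that("period labels open on the configured breakpoint months", {
  s <- monthly_series(month_seq("1997-10", 156), rnorm(156))
  s <- assign_periods(s, period_partition())
  lab <- function(m) as.character(s$period[s$month == as_month(m)])
  expect_equal(lab("1997-10"), "Early")
  expect_equal(lab("2003-03"), "Early")
  expect_equal(lab("2003-04"), "Pre-ban")
  expect_equal(lab("2007-10"), "Pre-ban")
  expect_equal(lab("2007-11"), "Post-ban")
  expect_equal(lab("2010-09"), "Post-ban")
  short <- monthly_series(month_seq("1997-10", 24), rnorm(24))
  expect_error(assign_periods(short, period_partition()), "inside")
})

test_that("market summary reproduces totals, biomass and shares", {
  ref <- species_reference()
  expect_equal(nrow(ref), 28L)
  ms <- market_summary(ref)
  expect_equal(ms$overall$n, 196892)
  # group totals equal the sum of member species
  joined <- merge(ms$species, ms$groups, by = "group",
                  suffixes = c("", "_grp"))
  sums <- tapply(joined$n, joined$group, sum)
  expect_equal(as.numeric(sums[ms$groups$group]), ms$groups$n)
  sums_b <- tapply(joined$biomass_kg, joined$group, sum)
  expect_equal(as.numeric(sums_b[ms$groups$group]), ms$groups$biomass_kg)
  expect_equal(sum(ms$groups$n), ms$overall$n)
  expect_lt(abs(sum(ms$groups$biomass_kg) - ms$overall$biomass_kg), 1e-6)
  # biomass computed from printed masses stays within rounding slack of the
  # published study-wide total
  expect_lt(abs(ms$overall$biomass_kg - 873993.28), 30)
  # percentage shares of counts sum to 100
  expect_lt(abs(sum(ms$groups$share_n_pct) - 100), 0.05)

  one <- market_summary(ref[ref$species == "Philantomba monticola", ])
  expect_equal(one$species$share_n_pct, 100)

  rec <- toy_records("Unlisted species", 10)
  expect_error(market_summary(ref, rec), "Unlisted")
})

test_that("summary counts can be tallied from records", {
  rec <- toy_records(c("Philantomba monticola", "Mandrillus leucophaeus poensis"),
                     c(20, 10))
  ms <- market_summary(species_reference(), rec)
  expect_equal(ms$overall$n, 30)
  expect_equal(ms$species$n[ms$species$species == "Philantomba monticola"], 20)
  expect_equal(
    ms$species$biomass_kg[ms$species$species ==
                            "Mandrillus leucophaeus poensis"],
    10 * 14.25
  )
})

test_that("census CSV round-trips through disk", {
  cfg <- default_scenario(seed = 4, n_months = 30)
  cfg$missing_months <- NULL
  cen <- generate_census(cfg)
  dir <- withr::local_tempdir()
  write_census_csv(cen, dir)
  rec <- read_census_csv(file.path(dir, "census.csv"))
  cal <- read_calendar_csv(file.path(dir, "calendar.csv"))
  expect_equal(nrow(rec), nrow(cen$records))
  expect_equal(rec$date, cen$records$date)
  expect_equal(cal$market_days, cen$calendar$market_days)
  expect_equal(cal$month, cen$calendar$month)
})
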