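test_that("constructor enforces the field invariants", {
  vals <- array(1, c(3, 2, 2))
  tm <- as.Date("2000-01-01") + 0:2
  f <- gridded_field(vals, tm, 1:2, 1:2)
  expect_s3_class(f, "gridded_field")
  expect_false(any(f$missing))

  expect_error(gridded_field(array(1, c(3, 2, 2)), rev(tm), 1:2, 1:2),
               "increasing")
  bad <- vals; bad[1, 1, 1] <- -0.1
  expect_error(gridded_field(bad, tm, 1:2, 1:2), "positive")
  expect_error(gridded_field(array(1, c(2, 2, 2)), tm, 1:2, 1:2), "dimensions")

  # land cells carry no data and are never marked missing
  land <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  f2 <- gridded_field(vals, tm, 1:2, 1:2, land = land)
  expect_true(all(is.na(f2$values[, 1, 1])))
  expect_false(any(f2$missing[, 1, 1]))
})

test_that("compose_8day averages valid days per window and restarts each January 1", {
  n_days <- 365 * 2 + 1                 # spans a leap boundary (2000 is leap)
  tm <- as.Date("2000-01-01") + seq_len(n_days) - 1
  vals <- array(NA_real_, c(n_days, 1, 2))
  vals[, 1, 1] <- 1                      # constant pixel
  vals[1:8, 1, 2] <- 1:8                 # first window: mean 4.5
  vals[9:16, 1, 2] <- c(2, rep(NA, 7))   # single valid value
  # window 3 (days 17:24) left all-missing
  vals[25:n_days, 1, 2] <- 1
  f <- gridded_field(vals, tm, 1, 1:2)
  comp <- compose_8day(f)

  expect_equal(length(comp$time), 2 * 46)      # 46 windows per calendar year
  expect_equal(comp$values[1, 1, 2], 4.5)
  expect_equal(comp$values[2, 1, 2], 2.0)
  expect_true(is.na(comp$values[3, 1, 2]))
  expect_true(comp$missing[3, 1, 2])
  expect_true(all(comp$values[, 1, 1] == 1))
  # windows restart on Jan 1 of year 2
  expect_equal(comp$time[47], as.Date("2001-01-01"))
  # compositing never increases the per-pixel missing fraction
  expect_lte(gap_fraction(comp)$summary, gap_fraction(f)$summary)
  expect_error(compose_8day(comp), "daily")
})

test_that("conservative regridding is an area-weighted mean with correct masks", {
  tm <- as.Date("2000-01-01") + 8 * 0:1
  # 4x4 fine grid at 0.5 deg -> 2x2 coarse at 1 deg
  vals <- array(2.5, c(2, 4, 4))
  f <- gridded_field(vals, tm, lat = seq(0.25, 1.75, by = 0.5),
                     lon = seq(0.25, 1.75, by = 0.5))
  g <- regrid_conservative(f, 1)
  expect_equal(dim(g$values), c(2, 2, 2))
  expect_true(all(abs(g$values - 2.5) < 1e-12))   # constant preserved

  # two equal-area valid cells 1 and 3 (same latitude), rest missing -> 2
  vals2 <- array(NA_real_, c(2, 4, 4))
  vals2[, 1, 1] <- 1; vals2[, 1, 2] <- 3
  vals2[, 3:4, 3:4] <- 1
  f2 <- gridded_field(vals2, tm, lat = seq(0.25, 1.75, by = 0.5),
                      lon = seq(0.25, 1.75, by = 0.5))
  g2 <- regrid_conservative(f2, 1)
  expect_equal(g2$values[1, 1, 1], 2)
  expect_true(is.na(g2$values[1, 2, 1]))          # no valid fine cell
  expect_true(g2$missing[1, 2, 1])

  # coarse land only when all fine cells are land
  land <- matrix(FALSE, 4, 4); land[1:2, 1:2] <- TRUE; land[1, 3] <- TRUE
  f3 <- gridded_field(array(1, c(2, 4, 4)), tm,
                      lat = seq(0.25, 1.75, by = 0.5),
                      lon = seq(0.25, 1.75, by = 0.5), land = land)
  g3 <- regrid_conservative(f3, 1)
  expect_true(g3$land[1, 1])
  expect_false(g3$land[1, 2])
  expect_equal(g3$values[1, 1, 2], 1)

  expect_error(regrid_conservative(f, 0.7), "multiple")
})

test_that("regridding conserves the area-weighted mean of fully valid regions", {
  set.seed(42)
  tm <- as.Date("2000-01-01") + 8 * 0:2
  lat <- seq(10.25, 13.75, by = 0.5); lon <- seq(60.25, 63.75, by = 0.5)
  vals <- array(exp(rnorm(3 * 8 * 8)), c(3, 8, 8))
  f <- gridded_field(vals, tm, lat, lon)
  g <- regrid_conservative(f, 1)
  w_fine <- cos(lat * pi / 180)
  for (t in 1:3) {
    m_fine <- sum(vals[t, , ] * w_fine) / (sum(w_fine) * 8)
    w_coarse <- cos(g$lat * pi / 180)
    m_coarse <- sum(g$values[t, , ] * w_coarse) / (sum(w_coarse) * 4)
    expect_equal(m_coarse, m_fine, tolerance = 1e-12)
  }
})

test_that("gap_fraction reports per-pixel fractions over ocean only", {
  f <- random_field(n_t = 8, miss_frac = 0, land_border = TRUE, seed = 3)
  f$values[1:2, 3, 3] <- NA; f$missing[1:2, 3, 3] <- TRUE
  r <- gap_fraction(f)
  expect_equal(r$fraction[3, 3], 0.25)             # 2 of 8 composites
  expect_true(is.na(r$fraction[1, 1]))             # land excluded
  expect_equal(sum(r$fraction > 0, na.rm = TRUE), 1)

  r0 <- gap_fraction(random_field(miss_frac = 0, seed = 4))
  expect_true(all(r0$fraction == 0))
  expect_equal(r0$summary, 0)

  f$values[, 4, 4] <- NA; f$missing[, 4, 4] <- TRUE
  expect_equal(gap_fraction(f)$fraction[4, 4], 1.0)
  expect_error(gap_fraction(f, integer(0)), "nonempty")
})
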