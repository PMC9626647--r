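test_that("annual median follows the even-length convention", {
  expect_equal(annual_median(c(1, 2, 3)), 2)
  expect_equal(annual_median(rep(4.2, 46)), 4.2)
  expect_equal(annual_median(c(1, 1, 1, 9)), 1)
  expect_error(annual_median(numeric(0)), "valid composite")
})

test_that("initiation is the first strict exceedance of 1.05 x median", {
  s <- c(rep(1, 10), 1.2, rep(1, 35))
  expect_equal(bloom_initiation(s), 11L)
  expect_true(is.na(bloom_initiation(rep(2, 46))))   # never exceeds own median
  # strict inequality: exactly the threshold does not trigger
  s2 <- c(rep(1, 10), 1.05, 1.2, rep(1, 10))
  expect_equal(bloom_initiation(s2), 12L)
  # window restriction skips earlier exceedances
  expect_equal(bloom_initiation(s, search_window = 20:46), NA_integer_)
  expect_error(bloom_initiation(s, search_window = 40:50), "outside")
})

test_that("peak is the earliest argmax inside the summer window", {
  s <- c(rep(1, 20), 5, rep(1, 10), 5, rep(1, 14))
  expect_equal(bloom_peak(s, 15:40), 21L)            # tie -> earliest
  expect_equal(bloom_peak(s, 25:40), 32L)
  expect_error(bloom_peak(s, integer(0)), "nonempty")
  expect_error(bloom_peak(s, 40:50), "outside")
})

test_that("initiation and peak match brute-force scan oracles on random series", {
  for (case in 1:200) {
    set.seed(7000 + case)
    n <- sample(20:46, 1)
    s <- exp(rnorm(n, 0, 0.6))
    win <- sort(sample(seq_len(n), sample(5:n, 1)))
    fac <- runif(1, 1.0, 1.2)
    expect_identical(bloom_initiation(s, fac, win),
                     oracle_initiation(s, fac, win))
    expect_identical(bloom_peak(s, win), oracle_peak(s, win))
  }
})

test_that("bloom_indices ties initiation scan and peak window to calendar months", {
  dates <- as.Date("2001-01-01") + 8 * 0:45
  curve <- 0.3 + 2 * exp(-(as.integer(format(dates, "%j")) - 200)^2 / 800)
  bi <- bloom_indices(curve, dates)
  expect_equal(format(bi$peak_date, "%m"), "07")
  expect_gte(as.integer(format(bi$initiation_date, "%m")), 6)
  expect_equal(bi$threshold_value, 1.05 * median(curve))
  # whole-year scan finds the earlier (pre-June) crossing
  bi_full <- bloom_indices(curve, dates, init_months = 1:12)
  expect_lt(bi_full$initiation_index, bi$initiation_index)
})

test_that("identical members give a zero-width phenology range", {
  truth <- simulate_chl_field(seed = 61)
  fits <- fit_field(truth$field)
  ens <- generate_ensembles(truth$field, fits$fits, n_members = 20, seed = 3)
  ph <- ensemble_phenology(ens, 1999, cell = c(6, 6))
  expect_equal(ph$initiation$min, ph$initiation$max)
  expect_equal(ph$initiation$mean, ph$initiation$min)
  expect_equal(ph$peak$min, ph$peak$max)
  expect_equal(ph$frac_undetected, 0)
})

test_that("ensemble initiation range brackets the complete-observation result", {
  # the ensemble spread quantifies imputation uncertainty only, so the
  # quantity it can bracket is the initiation a complete (gap-free)
  # observed series would have given, not the noise-free curve
  sim <- run_small_pipeline(seed = 67, n_members = 100, summer_gap = 0.4)
  tp <- sim$truth$truth_phenology
  tm <- sim$truth$field$time
  covered <- 0; n_cells <- 0
  for (r in which(tp$year == 1999)) {
    ph <- ensemble_phenology(sim$ens, 1999,
                             cell = c(tp$lat_idx[r], tp$lon_idx[r]))
    i <- which(as.integer(format(tm, "%Y")) == 1999)
    complete <- sim$truth$field$values[i, tp$lat_idx[r], tp$lon_idx[r]]
    ref <- bloom_initiation(complete, 1.05, month_window(tm[i], 6:9))
    n_cells <- n_cells + 1
    if (!is.na(ref) && !is.na(ph$initiation$min) &&
        ph$initiation$min <= ref && ref <= ph$initiation$max)
      covered <- covered + 1
  }
  expect_gt(covered / n_cells, 0.6)
})

test_that("climatological ensemble initiation matches the truth within one composite", {
  # moderate noise isolates the property under test (that climatological
  # ensemble averaging is unbiased for the initiation index) from the
  # threshold method's intrinsic sensitivity to observation noise
  sim <- run_small_pipeline(seed = 71, n_members = 100, summer_gap = 0.25,
                            params = synth_params(noise_sigma = 0.1))
  # climatological member series at a central cell: average the three years
  ms <- bloomfill:::member_series(sim$ens, 1998, cell = c(6, 6))
  clim <- ms$series
  for (y in 1999:2000) {
    msy <- bloomfill:::member_series(sim$ens, y, cell = c(6, 6))
    clim <- clim + msy$series
  }
  clim <- clim / 3
  dates <- ms$dates
  init <- apply(clim, 2, function(s)
    bloom_initiation(s, 1.05, month_window(dates, 6:9)))
  truth_clim <- rowMeans(vapply(1998:2000, function(y) {
    i <- which(as.integer(format(sim$truth$field$time, "%Y")) == y)
    sim$truth$curve[i, 6, 6]
  }, numeric(46)))
  truth_init <- bloom_initiation(truth_clim, 1.05, month_window(dates, 6:9))
  expect_lte(abs(mean(init, na.rm = TRUE) - truth_init), 1)
})

test_that("regional averaging over ocean pixels is supported", {
  sim <- run_small_pipeline(seed = 73, n_members = 20)
  ph <- ensemble_phenology(sim$ens, 1999,
                           region = list(lat_idx = 4:8, lon_idx = 4:8))
  expect_s3_class(ph, "phenology_summary")
  expect_true(ph$initiation$min <= ph$initiation$mean)
  expect_true(ph$initiation$mean <= ph$initiation$max)
})
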