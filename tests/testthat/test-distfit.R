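test_that("normal MLE uses the sample mean and population SD", {
  x <- c(1, 2, 3, 1, 2, 3, 1, 2, 3)         # n = 9 >= minimum sample
  f <- fit_family(x, "normal")
  expect_equal(f$location, mean(x))
  expect_equal(f$scale, sqrt(mean((x - mean(x))^2)))
  expect_error(fit_family(c(1, 2, 3), "normal"), "at least")
  expect_error(fit_family(c(rep(1, 8), -1), "normal"), "positive")
})

test_that("lognormal and gamma MLEs recover generating parameters", {
  set.seed(101)
  x <- exp(rnorm(5000, 0, 0.5))
  fl <- fit_family(x, "lognormal")
  expect_lt(abs(fl$shape - 0.5) / 0.5, 0.05)      # shape within 5%
  expect_lt(abs(log(fl$scale)), 0.05)             # log-scale near 0

  set.seed(102)
  y <- rgamma(5000, shape = 2, scale = 1)
  fg <- fit_family(y, "gamma")
  expect_lt(abs(fg$shape - 2) / 2, 0.10)          # shape within 10%
  expect_lt(abs(fg$scale - 1), 0.15)
  expect_gte(fg$location, 0)
})

test_that("location-0 fits agree with the independent fitdistrplus/MASS route", {
  skip_if_not_installed("fitdistrplus")
  set.seed(103)
  y <- rgamma(2000, shape = 3, scale = 0.5)
  ours <- bloomfill:::fit_gamma_at(y, 0)
  ref <- suppressWarnings(fitdistrplus::fitdist(y, "gamma", method = "mle"))
  expect_equal(ours$shape, unname(ref$estimate["shape"]), tolerance = 1e-3)
  expect_equal(1 / ours$scale, unname(ref$estimate["rate"]), tolerance = 1e-3)

  x <- exp(rnorm(2000, 0.2, 0.4))
  ref2 <- suppressWarnings(fitdistrplus::fitdist(x, "lnorm", method = "mle"))
  ours2 <- bloomfill:::fit_lnorm_at(x, 0)
  expect_equal(ours2$shape, unname(ref2$estimate["sdlog"]), tolerance = 1e-3)
  expect_equal(log(ours2$scale), unname(ref2$estimate["meanlog"]),
               tolerance = 1e-3)
})

test_that("K-S test detects gross mismatch and accepts own-family fits", {
  bad <- fit_family(seq(0.01, 0.03, length.out = 10), "normal")
  bad$location <- 100; bad$scale <- 1
  expect_lt(ks_test(seq(0.01, 0.03, length.out = 10), bad)$p_value, 0.05)

  # a sample laid on an arbitrarily fine quantile grid of the fitted CDF
  f <- fit_family(exp(rnorm(100, 0, 0.3)), "lognormal")
  grid <- f$location + qlnorm(seq(0.0005, 0.9995, length.out = 1000),
                              log(f$scale), f$shape)
  ks <- ks_test(grid, f)
  expect_lt(ks$statistic, 0.01)
  expect_gt(ks$p_value, 0.99)

  # own-MLE lognormal fits are rarely rejected
  rejections <- 0
  for (s in 1:50) {
    set.seed(500 + s)
    x <- exp(rnorm(1000, 0, 1))
    if (ks_test(x, fit_family(x, "lognormal"))$p_value <= 0.05)
      rejections <- rejections + 1
  }
  expect_lte(rejections / 50, 0.10)

  expect_error(ks_test(1:10, fit_kde_cv(exp(rnorm(20)))), "parametric")
})

test_that("cross-validated KDE behaves on bimodal, normal and degenerate samples", {
  # two well-separated clusters -> two local maxima in the density
  set.seed(7)
  x <- c(rnorm(300, 0, 0.15), rnorm(300, 5, 0.15)) + 10
  k <- fit_kde_cv(x)
  dens <- kde_density(k)(seq(9, 16, length.out = 500))
  peaks <- which(diff(sign(diff(dens))) == -2)
  expect_gte(length(peaks), 2)

  # CV bandwidth within a factor 2 of Silverman's rule on a normal sample
  set.seed(8)
  y <- rnorm(2000) + 10
  k2 <- fit_kde_cv(y)
  bw_silverman <- stats::bw.nrd0(y)
  expect_gt(k2$kde$bandwidth, bw_silverman / 2)
  expect_lt(k2$kde$bandwidth, bw_silverman * 2)

  # constant sample: fallback bandwidth, density centred at the constant
  k3 <- fit_kde_cv(rep(2, 10))
  expect_equal(k3$kde$bandwidth, max(1e-6, 1e-3 * 2))
  d3 <- kde_density(k3)
  expect_gt(d3(2), d3(2.1))

  # the KDE density integrates to 1
  ig <- integrate(kde_density(k2), 0, 25, subdivisions = 1000)
  expect_lt(abs(ig$value - 1), 1e-3)
})

test_that("select_pdf picks the generating family and falls back to KDE", {
  set.seed(201)
  expect_equal(select_pdf(rlnorm(2000, 0, 1))$family, "lognormal")
  set.seed(202)
  expect_equal(select_pdf(rnorm(2000, 10, 1))$family, "normal")
  set.seed(203)
  expect_equal(select_pdf(rgamma(2000, 2, scale = 1))$family, "gamma")

  # bimodal lognormal mixture: all parametric candidates rejected -> KDE
  set.seed(204)
  mix <- ifelse(runif(2000) < 0.5, rlnorm(2000, -2, 0.2), rlnorm(2000, 1, 0.2))
  sel <- select_pdf(mix)
  expect_true(all(sel$ks_pvalues < 0.05))
  expect_equal(sel$family, "kde")

  # deterministic given the sample and fold seed
  set.seed(205); z <- rlnorm(500, 0, 0.8)
  s1 <- select_pdf(z, fold_seed = 3)
  s2 <- select_pdf(z, fold_seed = 3)
  expect_identical(s1[setdiff(names(s1), "kde")], s2[setdiff(names(s2), "kde")])
})

test_that("fit_field fits every ocean cell and reports under-sampled ones", {
  f <- random_field(n_t = 40, n_lat = 5, n_lon = 5, miss_frac = 0.2, seed = 51)
  # make one cell chronically unobserved (3 valid values < minimum of 8)
  f$values[seq_len(37), 2, 2] <- NA
  f$missing[seq_len(37), 2, 2] <- TRUE
  res <- fit_field(f)
  expect_equal(nrow(res$table), 25)
  expect_equal(res$table$family[res$table$lat == f$lat[2] &
                                  res$table$lon == f$lon[2]], "unfit")
  expect_null(res$fits[["2_2"]])
  done <- res$table$family != "unfit"
  expect_true(all(res$table$sample_size[done] >= 8))
  expect_true(all(res$table$family[done] %in%
                    c("normal", "lognormal", "gamma", "kde")))
})
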