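test_that("grey_histogram conserves counts and places mass correctly", {
  arr <- array(7L, dim = c(10, 10, 10))
  h <- grey_histogram(voxel_stack(arr, c(1, 1, 1)))
  expect_equal(sum(h$frequencies), 1000)
  expect_equal(h$frequencies[8], 1000)
  expect_equal(sum(h$frequencies[-8]), 0)
  two <- grey_histogram(voxel_stack(array(c(0L, 255L), dim = c(1, 1, 2)),
                                    c(1, 1, 1)))
  expect_equal(two$frequencies[c(1, 256)], c(1, 1))
  # sampled stack: histogram mean tracks the population mean
  set.seed(1)
  arr <- array(as.integer(pmin(pmax(round(rnorm(1e6, 80, 10)), 0), 255)),
               dim = c(100, 100, 100))
  h <- grey_histogram(voxel_stack(arr, c(1, 1, 1)))
  m <- sum(h$positions * h$frequencies) / sum(h$frequencies)
  expect_lt(abs(m - 80), 0.5)
})

test_that("find_inflexion valley locates the minimum between two populations", {
  # forced by symmetry on a 3-point curve
  expect_equal(find_inflexion(frequency_curve(c(10, 20, 30), c(100, 0, 100)),
                              "valley", 1), 20)
  # two distant spikes: valley at the midpoint up to binning
  f <- numeric(256); f[6] <- 100; f[201] <- 100
  v <- find_inflexion(frequency_curve(0:255, f), "valley", 1)
  expect_lt(abs(v - 102.5), 3)
  # sampled equal-weight N(50,5) + N(150,10) mixture
  set.seed(2)
  cv <- draws_curve(c(rnorm(5e5, 50, 5), rnorm(5e5, 150, 10)))
  v <- find_inflexion(cv, "valley")
  expect_gte(v, 75); expect_lte(v, 125)
})

test_that("find_inflexion signals no-valley on monotone curves; knee works", {
  geom <- frequency_curve(0:30, 1000 * 0.7^(0:30))
  expect_error(find_inflexion(geom, "valley"), class = "glomseg_no_valley")
  k <- find_inflexion(geom, "knee")
  expect_gt(k, 0); expect_lt(k, 30)
  expect_error(find_inflexion(frequency_curve(1:4, rep(1, 4)), "valley", 5),
               class = "glomseg_bad_input")
})

test_that("fit_gaussian recovers noiseless parameters to 1e-6 relative", {
  x <- 0:255
  cv <- frequency_curve(x, 1000 * exp(-0.5 * ((x - 80) / 10)^2))
  f <- fit_gaussian(cv)
  expect_lt(abs(f$amplitude - 1000) / 1000, 1e-6)
  expect_lt(abs(f$mean - 80) / 80, 1e-6)
  expect_lt(abs(f$sd - 10) / 10, 1e-6)
  expect_gte(f$r_squared, 1 - 1e-6)
})

test_that("fit_gaussian recovers sampled parameters", {
  set.seed(11)
  f <- fit_gaussian(draws_curve(rnorm(1e6, 80, 10)))
  expect_lt(abs(f$mean - 80), 0.1)
  expect_lt(abs(f$sd - 10), 0.1)
  # parameter-recovery property over 20 seeded histograms
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    mu <- runif(1, 60, 100); sg <- runif(1, 5, 15)
    abs(fit_gaussian(draws_curve(rnorm(1e5, mu, sg)))$mean - mu)
  }, 0)
  expect_lt(median(errs), 0.2)
})

test_that("fit_gaussian rejects empty ranges and restricts to fit_range", {
  cv <- frequency_curve(0:255, rep(0, 256))
  expect_error(fit_gaussian(cv), class = "glomseg_fit_error")
  # lectin tail outside the range must not bias the restricted fit
  x <- 0:255
  f <- 1000 * exp(-0.5 * ((x - 80) / 10)^2) + ifelse(x > 150, 50, 0)
  fit <- fit_gaussian(frequency_curve(x, f), fit_range = c(40, 120))
  expect_lt(abs(fit$mean - 80), 0.01)
})

test_that("lectin_threshold applies mean + k*sd and its properties hold", {
  mkfit <- function(m, s) {
    x <- seq(m - 5 * s, m + 5 * s, length.out = 101)
    fit_gaussian(frequency_curve(x, 100 * exp(-0.5 * ((x - m) / s)^2)))
  }
  expect_equal(lectin_threshold(mkfit(80, 10)), 112.9, tolerance = 1e-6)
  expect_equal(lectin_threshold(mkfit(10, 1)), 13.29, tolerance = 1e-6)
  # strictly increasing in mean and sd
  expect_gt(lectin_threshold(mkfit(90, 10)), lectin_threshold(mkfit(80, 10)))
  expect_gt(lectin_threshold(mkfit(80, 12)), lectin_threshold(mkfit(80, 10)))
  expect_error(lectin_threshold(mkfit(200, 20)), class = "glomseg_saturated")
  # the threshold excludes the expected normal fraction
  expect_gte(stats::pnorm(K_SD_DEFAULT), 0.995)
  set.seed(3)
  x <- rnorm(1e6, 80, 10)
  frac_above <- mean(x > 80 + K_SD_DEFAULT * 10)
  p <- 1 - stats::pnorm(K_SD_DEFAULT)
  expect_lt(abs(frac_above - p), 3 * sqrt(p * (1 - p) / 1e6))
})

test_that("background_threshold finds the medium/tissue valley", {
  set.seed(4)
  cv <- draws_curve(c(rnorm(3e5, 5, 2), rnorm(7e5, 80, 10)))
  thr <- background_threshold(cv)
  expect_gte(thr, 15); expect_lte(thr, 55)
  # no background population: single bell has no interior valley
  set.seed(5)
  expect_error(background_threshold(draws_curve(rnorm(1e5, 80, 10))),
               class = "glomseg_no_valley")
})

test_that("tissue_fit_range clips the bright tail at 1% of the peak", {
  x <- 0:255
  f <- 1000 * exp(-0.5 * ((x - 80) / 10)^2)
  r <- tissue_fit_range(frequency_curve(x, f), 30)
  expect_equal(r[1], 30)
  expect_gt(r[2], 100)  # beyond the bell
  expect_lt(r[2], 130)  # but before the far tail
})

test_that("frequency_curve and threshold_set enforce their invariants", {
  expect_error(frequency_curve(c(1, 1, 2), c(0, 0, 0)),
               class = "glomseg_bad_input")
  expect_error(frequency_curve(1:3, c(1, -1, 1)), class = "glomseg_bad_input")
  ts <- threshold_set(20, 112.9, 750, 0.34)
  expect_s3_class(ts, "threshold_set")
  expect_error(threshold_set(120, 112.9, 750, 0.34),
               class = "glomseg_bad_input")
  expect_error(threshold_set(20, 112.9, 750, 1.2),
               class = "glomseg_bad_input")
  # CSV round trip
  path <- withr::local_tempfile(fileext = ".csv")
  cv <- frequency_curve(c(0.5, 1.5, 2.5), c(3, 0, 7))
  write_curve_csv(cv, path)
  back <- read_curve_csv(path)
  expect_equal(back$positions, cv$positions)
  expect_equal(back$frequencies, cv$frequencies)
})
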