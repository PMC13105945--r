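test_that("default band scheme reproduces the ten printed band edges", {
  sch <- make_band_scheme()
  expect_identical(sch$bands$label, paste0("F", 1:10))
  expect_equal(sch$bands$low,
               c(10, 30, 65, 85, 105, 125, 145, 165, 185, 205))
  expect_equal(sch$bands$high,
               c(29.5, 49.5, 84.5, 104.5, 124.5, 144.5, 164.5, 184.5,
                 204.5, 224.5))
  # half-open bin convention: 39 discrete 0.5-Hz bins per band
  expect_true(all(vapply(1:10, function(m) length(band_bins(sch, m)), 0L) == 39L))
})

test_that("band scheme respects exclusions, grid and frequency ceiling", {
  sch <- make_band_scheme()
  allbins <- unlist(lapply(1:10, band_bins, scheme = sch))
  expect_identical(anyDuplicated(allbins), 0L)          # no bin assigned twice
  expect_false(any(allbins >= 50 & allbins < 65))       # no excluded bin
  one <- make_band_scheme(low = 5, width = 10, count = 1, exclusions = list())
  expect_equal(one$bands[, c("low", "high")], data.frame(low = 5, high = 15))
  expect_error(make_band_scheme(max_freq = 200), "ceiling")
  expect_error(make_band_scheme(width = 19.7), "multiple of bin_width")
})

test_that("spectral_power yields the documented grid and obeys Parseval", {
  x <- sin(2 * pi * 100 * (0:1999) / 1000)
  sp <- spectral_power(x, 1000)
  expect_length(sp$power, 480)
  expect_equal(sp$freqs[which.max(sp$power)], 100)
  expect_equal(sum(sp$power), mean(x^2), tolerance = 0.1)
  expect_true(all(sp$power >= 0))
  z <- spectral_power(numeric(2000), 1000)
  expect_identical(z$power, numeric(480))
  expect_error(spectral_power(rnorm(100), 1000, bin_width = 0.5),
               "too short")
  expect_error(spectral_power(rnorm(2000), 400, fmax = 250), "2 \\* fmax")
})

test_that("band power sums windows at the configured resolution", {
  set.seed(3)
  rec <- recording(rnorm(60000), 1000, "emg", "M1")
  sch <- make_band_scheme()
  bp <- band_power_series(rec, sch, window = 2, step = 1)
  expect_length(bp, 10)
  # floor((60 - 2)/1) + 1 fully contained windows, centred timestamps
  expect_length(bp$F1$values, 59)
  expect_equal(bp$F1$times, 1:59)
  expect_equal(unique(vapply(bp, function(s) s$step, 0)), 1)

  # conservation: band sums equal the spectrum summed over assigned bins
  sp <- spectral_power(rec$samples[1:2000] * 1, 1000)
  for (m in c(1, 4, 10)) {
    sel <- sp$freqs %in% band_bins(sch, m)
    expect_equal(bp[[m]]$values[1], sum(sp$power[sel]), tolerance = 1e-12)
  }
})

test_that("a pure tone lands its power in the owning band", {
  rec <- recording(sin(2 * pi * 100 * (0:59999) / 1000), 1000, "emg")
  bp <- band_power_series(rec, make_band_scheme())
  tot <- rowSums(vapply(bp, function(s) s$values, numeric(59)))
  expect_gt(sum(bp$F4$values) / sum(tot), 0.95)  # 100 Hz lies in F4 [85,104.5]
  z <- band_power_series(recording(numeric(10000), 1000, "emg"),
                         make_band_scheme())
  expect_true(all(vapply(z, function(s) all(s$values == 0), TRUE)))
  expect_error(band_power_series(recording(rnorm(1000), 1000, "emg"),
                                 make_band_scheme(), window = 2),
               "shorter than one window")
})

test_that("global z-scoring gives exact zero mean and unit SD", {
  s <- make_bp(c(1, 2, 3))
  z <- zscore_global(s)
  expect_equal(mean(z$values), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z$values), 1, tolerance = 1e-12)
  expect_true(z$normalized)
  expect_equal(zscore_global(z)$values, z$values, tolerance = 1e-9)
  expect_error(zscore_global(make_bp(rep(5, 10))), "zero variance")
})

test_that("linear detrending removes ramps and leaves structure intact", {
  n <- 1000
  ramp <- make_bp(seq(0, 5, length.out = n))
  expect_lt(max(abs(detrend_series(ramp)$values)), 1e-10)
  set.seed(4)
  noise <- rnorm(n)
  out <- detrend_series(make_bp(noise))
  expect_gt(stats::cor(out$values, noise), 0.99)
  sinus <- sin(2 * pi * (1:n) / 20)
  mixed <- detrend_series(make_bp(sinus + seq(0, 3, length.out = n)))
  expect_gt(stats::cor(mixed$values, sinus), 0.99)
  expect_error(detrend_series(make_bp(c(1, 2))), "at least 3")
})
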