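test_that("Pan-Tompkins recovers beats of a constant-rate synthetic EKG", {
  spec <- synth_spec(n_participants = 1, duration = 180,
                     hr_profile = function(t) rep(60, length(t)), seed = 21L)
  ek <- synth_ekg(spec)
  expect_equal(length(ek$peaks$peak_times), 180, tolerance = 1)
  det <- detect_r_peaks(ek$recording)
  expect_equal(length(det$peak_times), length(ek$peaks$peak_times),
               tolerance = 1)
  err <- vapply(det$peak_times,
                function(t) min(abs(ek$peaks$peak_times - t)), 0)
  expect_true(all(err <= 0.010))
})

test_that("detection degrades gracefully and tracks a rate ramp", {
  flat <- recording(numeric(2000), 1000, "ekg")
  expect_warning(pt <- detect_r_peaks(flat), "flat|no peaks")
  expect_length(pt$peak_times, 0)

  spec <- synth_spec(n_participants = 1, duration = 120,
                     hr_profile = function(t) 60 + 0.5 * t, seed = 22L)
  ek <- synth_ekg(spec)
  det <- detect_r_peaks(ek$recording)
  rr <- diff(det$peak_times)
  sm <- stats::filter(rr, rep(1 / 5, 5))
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) < 0))     # smoothed RR monotonically decreasing
})

test_that("hr_series matches closed-form rates", {
  pk <- function(tt) structure(list(peak_times = tt), class = "acfc_peak_train")
  expect_true(all(hr_series(pk(seq(0, 60, by = 1)))$values == 60))
  expect_true(all(hr_series(pk(seq(0, 30, by = 0.5)))$values == 120))
  # drifting RR: spline resampling stays within 1 BPM of 60/RR(t)
  rr <- seq(1.0, 0.6, length.out = 150)
  tt <- cumsum(c(10, rr))
  hs <- hr_series(pk(tt))
  truth <- stats::approx(tt[-1], 60 / rr, xout = hs$times)$y
  expect_lt(max(abs(hs$values - truth)), 1)
  expect_error(hr_series(pk(c(1, 2))), "at least 3")
})

test_that("artifact correction replaces only flagged points with window means", {
  base <- acfc:::new_rate_series("hr", 0:60, rep(60, 61), 1)
  base$values[31] <- 180
  out <- correct_artifacts(base, window = 10, k = 2)
  # direct-formula oracle on the constructed series
  idx <- which(abs(base$times - 30) <= 5)
  expect_equal(out$values[31], mean(base$values[idx]))
  expect_equal(out$values[-31], base$values[-31])

  const <- acfc:::new_rate_series("hr", 0:60, rep(72, 61), 1)
  expect_identical(correct_artifacts(const)$values, const$values)

  # brute-force threshold oracle on irregular input
  set.seed(5)
  noisy <- acfc:::new_rate_series("hr", 0:199, 70 + rnorm(200), 1)
  out <- correct_artifacts(noisy, window = 10, k = 2)
  oracle <- noisy$values
  for (i in seq_along(oracle)) {
    idx <- which(abs(noisy$times - noisy$times[i]) <= 5)
    m <- mean(noisy$values[idx]); s <- stats::sd(noisy$values[idx])
    if (abs(noisy$values[i] - m) > 2 * s) oracle[i] <- m
  }
  expect_equal(out$values, oracle)

  # smooth bounded fluctuation never trips the 2-SD rule
  sine <- acfc:::new_rate_series("hr", 0:199, 70 + 5 * sin(2 * pi * (0:199) / 40), 1)
  expect_equal(correct_artifacts(sine)$values, sine$values)
})

test_that("breath-peak detection recovers sinusoidal breathing rates", {
  tt <- seq(0, 180, by = 1 / 100)
  r25 <- recording(sin(2 * pi * 0.25 * tt), 100, "resp")
  br <- br_from_peaks(r25)
  expect_lt(max(abs(br$values - 15)), 0.5)
  r20 <- recording(sin(2 * pi * 0.2 * tt), 100, "resp")
  expect_lt(max(abs(br_from_peaks(r20)$values - 12)), 0.5)
  expect_error(br_from_peaks(recording(numeric(5000), 100, "resp")),
               "fewer than 3")
})

test_that("spectral-ridge breathing rate tracks constant and chirped rates", {
  tt <- seq(0, 120, by = 1 / 100)
  br <- br_tfr(recording(sin(2 * pi * 0.25 * tt), 100, "resp"))
  expect_equal(br$step, 0.5)
  expect_equal(diff(br$times[1:2]), 0.5)
  interior <- br$values[br$times > 15 & br$times < 105]
  expect_lt(max(abs(interior - 15)), 0.5)

  # linear chirp 0.2 -> 0.4 Hz over 300 s
  t2 <- seq(0, 300, by = 1 / 100)
  finst <- 0.2 + 0.2 * t2 / 300
  phase <- 2 * pi * cumsum(finst) / 100
  ch <- br_tfr(recording(sin(phase), 100, "resp"))
  expect_lt(abs(ch$values[1] - 12), 1.5)
  expect_lt(abs(ch$values[length(ch$values)] - 24), 1.5)
  sm <- stats::filter(ch$values, rep(1 / 9, 9))
  expect_true(all(diff(sm[!is.na(sm)]) > -0.05))   # monotone up to smoothing
})
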