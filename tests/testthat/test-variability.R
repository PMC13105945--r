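as_cts <- function(values) {
  structure(list(pair_id = c("A", "B"), link_id = c("F1", "F1"),
                 times = seq_along(values), values = values,
                 window_length = 6, step = 3),
            class = "acfc_coupling_ts")
}

test_that("static statistics match closed-form and large-sample moments", {
  two <- static_stats(as_cts(rep(c(0, 1), 10)))
  expect_equal(two$sd, stats::sd(rep(c(0, 1), 10)))
  expect_equal(two$skewness, 0)
  expect_equal(two$kurtosis_pearson, 1)     # m4/m2^2 for a symmetric two-point mass
  expect_equal(two$kurtosis_excess, -2)

  set.seed(30)
  g <- static_stats(as_cts(rnorm(5000)))
  expect_lt(abs(g$skewness), 3 * sqrt(6 / 5000))
  expect_lt(abs(g$kurtosis_pearson - 3), 3 * sqrt(24 / 5000))

  const <- static_stats(as_cts(rep(0.3, 20)))
  expect_equal(const$sd, 0)
  expect_true(is.na(const$skewness))        # undefined, flagged not zeroed

  expect_error(static_stats(as_cts(rnorm(5))), "at least 8")
})

test_that("moment conventions agree with an independent implementation", {
  set.seed(31)
  v <- rnorm(300)^2
  st <- static_stats(as_cts(v))
  expect_equal(st$skewness, e1071::skewness(v, type = 1), tolerance = 1e-12)
  expect_equal(st$kurtosis_excess, e1071::kurtosis(v, type = 1),
               tolerance = 1e-12)
})

test_that("DFA fluctuation function matches a brute-force recomputation", {
  set.seed(32)
  x <- rnorm(500)
  d <- dfa(x, scales = c(4, 8, 16, 32, 64, 125))
  Y <- cumsum(x - mean(x))
  brute <- vapply(d$scales, function(n) {
    m <- length(Y) %/% n
    r2 <- c()
    for (Yp in list(Y, rev(Y))) {
      for (w in seq_len(m)) {
        seg <- Yp[((w - 1) * n + 1):(w * n)]
        r2 <- c(r2, mean(stats::lm.fit(cbind(1, 1:n), seg)$residuals^2))
      }
    }
    sqrt(mean(r2))
  }, 0)
  expect_equal(d$fluctuation, brute, tolerance = 1e-10)
})

test_that("DFA is shift/scale equivariant and annihilates fitted trends", {
  set.seed(33)
  x <- rnorm(1000)
  d1 <- dfa(x)
  d2 <- dfa(5 * x - 3)
  expect_equal(d2$alpha, d1$alpha, tolerance = 1e-12)
  expect_equal(d2$fluctuation, 5 * d1$fluctuation, tolerance = 1e-10)
  # constant signal: linear profile, annihilated by DFA-1
  expect_lt(max(dfa(rep(2, 500))$fluctuation), 1e-10)
  # ramp signal: quadratic profile, annihilated by second-order detrending
  expect_lt(max(dfa(seq(0, 1, length.out = 1000),
                    detrend_order = 2)$fluctuation), 1e-8)
  expect_warning(dfa(rnorm(140), scales = c(4, 8, 16, 30, 50)), "N/4")
  suppressWarnings(
    expect_error(dfa(rnorm(20), scales = c(40, 50, 60, 70)), "usable scales"))
})

test_that("sign series of an independent-increment process scales like noise", {
  set.seed(34)
  ms <- magnitude_sign(as_cts(cumsum(rnorm(4000))))
  d <- dfa(ms$sign)
  expect_equal(d$alpha, 0.5, tolerance = 0.08)
})

test_that("magnitude-sign decomposition follows its definition", {
  ms <- magnitude_sign(as_cts(c(0.1, 0.3, 0.2)))
  expect_equal(ms$increments, c(0.2, -0.1))
  expect_equal(ms$magnitude, c(0.2, 0.1))
  expect_equal(ms$sign, c(1, -1))
  expect_true(all(magnitude_sign(as_cts(sort(rnorm(50))))$sign == 1))
  const <- magnitude_sign(as_cts(rep(0.5, 10)))
  expect_true(all(const$increments == 0) && all(const$sign == 0))
  gappy <- magnitude_sign(as_cts(c(0.1, 0.2, NA, 0.4, 0.5)))
  expect_length(gappy$increments, 3)
  expect_identical(gappy$spans_gap, c(FALSE, TRUE, FALSE))
  expect_error(magnitude_sign(as_cts(c(NA, 0.2))), "at least 2")
})
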