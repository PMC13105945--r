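test_that("coupling matrices have the right shape and self-coupling diagonal", {
  set.seed(10)
  a <- make_bp_set(matrix(rnorm(2000), 200, 10), "LegL")
  cm <- coupling_matrix(a, a)
  expect_identical(dim(cm$values), c(10L, 10L))        # 100 cells per pair
  expect_equal(unname(diag(cm$values)), rep(1, 10))
  hr <- acfc:::new_rate_series("hr", a[[1]]$times, rnorm(200), 1)
  ch <- coupling_matrix(hr, a, pair_id = c("Heart", "LegL"))
  expect_identical(dim(ch$values), c(1L, 10L))         # 10 cells per rate pair
  expect_identical(rownames(ch$values), "HR")
})

test_that("independent long series produce near-zero coupling", {
  set.seed(11)
  a <- make_bp_set(matrix(rnorm(1e5), 1e4, 10), "A")
  b <- make_bp_set(matrix(rnorm(1e5), 1e4, 10), "B")
  cm <- coupling_matrix(a, b)
  expect_lt(max(abs(cm$values)), 0.05)                 # null bound ~ 3/sqrt(N)
})

test_that("coupling is symmetric under argument exchange and scale-invariant", {
  set.seed(12)
  raw <- matrix(rexp(600), 200, 3)
  a <- lapply(make_bp_set(raw, "A"), zscore_global)
  b <- lapply(make_bp_set(matrix(rnorm(600), 200, 3), "B"), zscore_global)
  expect_equal(coupling_matrix(a, b)$values,
               t(coupling_matrix(b, a)$values), tolerance = 1e-12,
               ignore_attr = TRUE)
  a_scaled <- lapply(make_bp_set(raw * 37.5, "A"), zscore_global)
  expect_equal(coupling_matrix(a_scaled, b)$values,
               coupling_matrix(a, b)$values, tolerance = 1e-12)
})

test_that("every entry matches a direct two-pass Pearson on the overlap", {
  set.seed(13)
  a <- make_bp(rnorm(100), t0 = 1)
  b <- make_bp(rnorm(150), t0 = 26)       # partial overlap: t 26..100
  r <- coupling_matrix(a, b)$values[1, 1]
  expect_equal(r, stats::cor(a$values[26:100], b$values[1:75]),
               tolerance = 1e-12)
  expect_error(coupling_matrix(make_bp(rnorm(5)), make_bp(rnorm(5))),
               "10 points")
  expect_error(coupling_matrix(make_bp(rep(1, 50)), make_bp(rnorm(50))),
               "zero-variance.*F1")
})

test_that("best_lag recovers constructed shifts with deterministic ties", {
  set.seed(14)
  x <- rnorm(400)
  a <- make_bp(x)
  b_shift <- make_bp(c(rep(0, 2), x[1:398]))  # b(t) = a(t - 2): b lags a
  got <- best_lag(a, b_shift, -3:3)
  expect_equal(got$lag, 2)
  expect_equal(best_lag(a, a, -3:3)$lag, 0)
  ind <- best_lag(a, make_bp(rnorm(400)), -3:3)
  expect_lt(ind$r, 3 / sqrt(400))
  expect_error(best_lag(a, a, c(0, 200)), "25%")
})

test_that("group averaging is an element-wise mean with count bookkeeping", {
  mk <- function(v) acfc:::new_coupling_matrix(
    matrix(v, 2, 2, dimnames = list(c("F1", "F2"), c("F1", "F2"))),
    c("A", "B"), 0, NULL, 1L)
  expect_equal(group_average(list(mk(0.2), mk(0.4)))$values[1, 1], 0.3)
  single <- group_average(list(mk(0.5)))
  expect_equal(single$values, mk(0.5)$values)
  set.seed(15)
  ms <- lapply(1:5, function(i) mk(runif(4, -1, 1)))
  ga <- group_average(ms)
  brute <- Reduce(`+`, lapply(ms, function(m) m$values)) / 5
  expect_equal(ga$values, brute, tolerance = 1e-15)
  expect_identical(ga$n_participants, 5L)
  bad <- acfc:::new_coupling_matrix(matrix(0, 1, 2), c("A", "B"), 0, NULL, 1L)
  expect_error(group_average(list(mk(0), bad)), "share")
})

test_that("network construction classifies links against breakpoints", {
  m <- matrix(c(0.7, 0.1, 0.3, 0.55), 2, 2,
              dimnames = list(c("F1", "F2"), c("F1", "F2")))
  cm <- acfc:::new_coupling_matrix(m, c("LegL", "LegR"), 0, NULL, 1L)
  net <- build_network(list(cm), "methods")
  lk <- net$links
  expect_equal(lk$class[lk$band_a == "F1" & lk$band_b == "F1"], "very strong")
  expect_equal(lk$class[lk$band_a == "F2" & lk$band_b == "F1"], "below-threshold")
  expect_equal(lk$class[lk$band_a == "F2" & lk$band_b == "F2"], "strong")
  # the published preset families
  expect_equal(link_class_presets()$fig6_intermuscular,
               c(0.05, 0.15, 0.25, 0.35))
  under_fig6 <- build_network(list(cm), "fig6_intermuscular")$links
  expect_equal(under_fig6$class[under_fig6$band_a == "F1" &
                                  under_fig6$band_b == "F1"], "very strong")
  expect_error(build_network(list(cm), c(0.5, 0.4, 0.6, 0.7)),
               "strictly increasing")
})

test_that("six ten-band sub-networks yield 600 links", {
  set.seed(16)
  mats <- lapply(1:6, function(i) {
    m <- matrix(runif(100, -1, 1), 10, 10,
                dimnames = list(paste0("F", 1:10), paste0("F", 1:10)))
    acfc:::new_coupling_matrix(m, c(paste0("M", i), paste0("N", i)), 0, NULL, 1L)
  })
  net <- build_network(mats)
  expect_identical(nrow(net$links), 600L)
  expect_true(all(abs(net$links$strength) <= 1))
  ps <- network_pair_summary(net)
  expect_identical(sum(ps$n_links), 600L)
})
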