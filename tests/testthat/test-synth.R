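test_that("generators are pure functions of spec and seed", {
  spec <- synth_spec(n_participants = 1, duration = 20, rate = 500, seed = 60L)
  expect_identical(synth_emg(spec, "LegL")$samples,
                   synth_emg(spec, "LegL")$samples)
  expect_false(identical(synth_emg(spec, "LegL", seed = 61L)$samples,
                         synth_emg(spec, "LegL")$samples))
  e1 <- synth_ekg(spec); e2 <- synth_ekg(spec)
  expect_identical(e1$peaks$peak_times, e2$peaks$peak_times)
  expect_identical(synth_resp(spec)$samples, synth_resp(spec)$samples)
})

test_that("a single-band design concentrates power in that band", {
  spec <- synth_spec(n_participants = 1, duration = 60,
                     band_power = c(0, 0, 0, 1, 0, 0, 0, 0, 0, 0), seed = 62L)
  bp <- band_power_series(synth_emg(spec, "LegL"))
  tot <- Reduce(`+`, lapply(bp, function(s) sum(s$values)))
  expect_gt(sum(bp$F4$values) / tot, 0.90)
})

test_that("an uncoupled design measures near-zero envelope correlation", {
  spec <- synth_spec(n_participants = 1, duration = 600,
                     channels = c("LegL", "LegR"),
                     rho_same = 0, rho_diff = 0, seed = 63L)
  coh <- synth_cohort(spec)
  expect_lt(mean(abs(coh$truth$rho_envelope_measured)), 0.05)
})

test_that("EKG beat trains integrate the programmed rate profile", {
  spec <- synth_spec(n_participants = 1, duration = 60,
                     hr_profile = function(t) rep(60, length(t)), seed = 64L)
  ek <- synth_ekg(spec)
  expect_equal(length(ek$peaks$peak_times), 60, tolerance = 1)
  ramp <- synth_spec(n_participants = 1, duration = 60,
                     hr_profile = function(t) 60 + t, seed = 64L)
  rr <- diff(synth_ekg(ramp)$peaks$peak_times)
  expect_true(all(diff(rr) < 1e-9))        # RR strictly decreasing (grid-snapped)
})

test_that("respiration carries its fundamental at the programmed rate", {
  spec <- synth_spec(n_participants = 1, duration = 120,
                     br_profile = function(t) rep(15, length(t)), seed = 65L)
  r <- synth_resp(spec)
  d <- acfc:::decimate_resp(r, 25)
  n <- length(d$x)
  P <- Mod(stats::fft(d$x - mean(d$x)))[2:(n %/% 2)]^2
  ff <- (1:(n %/% 2 - 1)) * d$rate / n
  expect_equal(ff[which.max(P)], 0.25, tolerance = 0.02)
})

test_that("cohorts bundle recordings, truth tables and reproduce exactly", {
  spec <- synth_spec(n_participants = 2, duration = 20, rate = 500, seed = 66L)
  coh <- synth_cohort(spec)
  expect_length(coh$participants, 2)
  p1 <- coh$participants[[1]]
  expect_length(p1$emg, 4)
  expect_s3_class(p1$ekg, "acfc_recording")
  expect_s3_class(p1$resp, "acfc_recording")
  expect_identical(nrow(coh$truth), 2L * 6L * 10L)
  expect_true(all(c("rho_design", "rho_latent", "rho_envelope_measured")
                  %in% names(coh$truth)))
  coh2 <- synth_cohort(spec)
  expect_identical(p1$emg$BackR$samples,
                   coh2$participants[[1]]$emg$BackR$samples)
})

test_that("designed coupling hierarchy is recovered by the estimator", {
  spec <- synth_spec(n_participants = 2, duration = 300, seed = 67L)
  coh <- synth_cohort(spec)
  same <- c(); diff_ <- c()
  for (p in coh$participants) {
    bp <- lapply(p$emg, function(r) {
      lapply(band_power_series(r), zscore_global)
    })
    same <- c(same,
              mean(diag(coupling_matrix(bp$LegL, bp$LegR)$values)),
              mean(diag(coupling_matrix(bp$BackL, bp$BackR)$values)))
    diff_ <- c(diff_,
               mean(diag(coupling_matrix(bp$LegL, bp$BackL)$values)),
               mean(diag(coupling_matrix(bp$LegR, bp$BackR)$values)))
  }
  # same-type pairs (rho 0.6) couple more strongly than different-type (0.2)
  expect_gt(mean(same), mean(diff_))
  expect_gt(min(same), max(diff_))
})

test_that("infeasible designs are rejected", {
  expect_error(synth_spec(rho_same = 1.5), "\\[-1, 1\\]")
  rho <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_error(synth_spec(channels = c("A", "B", "C"), rho = rho),
               "positive definite")
  expect_error(synth_spec(rate = 300), "twice the highest band edge")
  expect_error(synth_ekg(synth_spec(hr_profile = function(t) rep(300, length(t)),
                                    duration = 10)),
               "25, 250")
})
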