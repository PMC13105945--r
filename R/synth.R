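#' Specify a synthetic cohort
#'
#' Parameters of the seeded generator that stands in for human recordings:
#' per participant it produces four EMG channels whose per-band amplitude
#' envelopes carry a designed pairwise correlation, an EKG-like pulse train
#' following a programmable instantaneous heart-rate profile, and a slow
#' quasi-sinusoidal respiration waveform following a programmable
#' breathing-rate profile.
#'
#' The EMG model is `x(t) = sum over bands of sqrt(w_m E_m(t)) c_m(t)`:
#' each carrier `c_m` is unit-variance band-limited noise confined to band
#' `F_m` (flat amplitude spectrum, random phases), and each envelope `E_m`
#' is a lognormal map of a slow latent Gaussian process (bandwidth
#' `envelope_bandwidth`). Same-band latents are correlated across channels
#' through the matrix `rho`; the latent correlation is analytically
#' compensated for the lognormal map so that the *envelope* correlation
#' equals the design value exactly.
#'
#' @param n_participants Cohort size (default 5).
#' @param duration Recording length in seconds (default 600).
#' @param rate Sampling rate in samples/s (default 1000; must exceed twice
#'   the highest band edge).
#' @param channels EMG channel names (default LegL, LegR, BackL, BackR;
#'   names sharing their first three letters count as "same-type" for the
#'   default coupling design).
#' @param scheme Band scheme defining band edges ([make_band_scheme()]).
#' @param rho Either a full channel-correlation matrix (applied to every
#'   band's envelopes) or NULL to build one from `rho_same` / `rho_diff`.
#' @param rho_same,rho_diff Envelope correlation for same-type and
#'   different-type channel pairs (defaults 0.6 and 0.2).
#' @param band_power Relative mean power per band (recycled to the number
#'   of bands; default equal).
#' @param envelope_bandwidth Latent envelope bandwidth in Hz (default 0.2,
#'   matching slow exercise-cycle timescales).
#' @param envelope_sigma Lognormal log-SD of the envelopes (default 0.5).
#' @param emg_noise_sd,ekg_noise_sd,resp_noise_sd Additive noise floors.
#' @param hr_profile,br_profile Functions of time (s) returning
#'   beats/min within 25-250 and breaths/min within 4-80.
#' @param seed Base integer seed; all generators are pure functions of
#'   (spec, seed).
#' @return An object of class `acfc_synth_spec`.
#' @export
synth_spec <- function(n_participants = 5, duration = 600, rate = 1000,
                       channels = c("LegL", "LegR", "BackL", "BackR"),
                       scheme = make_band_scheme(),
                       rho = NULL, rho_same = 0.6, rho_diff = 0.2,
                       band_power = 1,
                       envelope_bandwidth = 0.2, envelope_sigma = 0.5,
                       emg_noise_sd = 0, ekg_noise_sd = 0.02,
                       resp_noise_sd = 0.05,
                       hr_profile = function(t) 70 + 8 * sin(2 * pi * t / 120),
                       br_profile = function(t) 15 + 2 * sin(2 * pi * t / 150),
                       seed = 1L) {
  nch <- length(channels)
  if (is.null(rho)) {
    type <- substr(channels, 1, 3)
    rho <- matrix(rho_diff, nch, nch, dimnames = list(channels, channels))
    rho[outer(type, type, "==")] <- rho_same
    diag(rho) <- 1
  }
  if (any(abs(rho) > 1)) stop("synth_spec: rho entries must lie in [-1, 1]")
  if (rate < 2 * max(scheme$bands$high)) {
    stop("synth_spec: rate must be at least twice the highest band edge")
  }
  nb <- nrow(scheme$bands)
  band_power <- rep_len(band_power, nb)
  spec <- structure(
    list(n_participants = n_participants, duration = duration, rate = rate,
         channels = channels, scheme = scheme, rho = rho,
         band_power = band_power,
         envelope_bandwidth = envelope_bandwidth,
         envelope_sigma = envelope_sigma,
         emg_noise_sd = emg_noise_sd, ekg_noise_sd = ekg_noise_sd,
         resp_noise_sd = resp_noise_sd,
         hr_profile = hr_profile, br_profile = br_profile,
         seed = as.integer(seed)),
    class = "acfc_synth_spec")
  # latent correlation compensated for the lognormal envelope map; the
  # Cholesky factorization doubles as the positive-definiteness check
  spec$rho_latent <- compensate_lognormal(rho, envelope_sigma)
  spec$chol_latent <- tryCatch(chol(spec$rho_latent), error = function(e) {
    stop("synth_spec: rho matrix is not positive definite under the latent construction")
  })
  spec
}

#' @export
print.acfc_synth_spec <- function(x, ...) {
  cat(sprintf("<Synthetic cohort spec: n=%d, %g s @ %g Hz, channels %s, seed %d>\n",
              x$n_participants, x$duration, x$rate,
              paste(x$channels, collapse = "/"), x$seed))
  invisible(x)
}

# corr(exp(s z1), exp(s z2)) = (exp(rho_z s^2) - 1)/(exp(s^2) - 1);
# invert so the envelope correlation hits the design value exactly
compensate_lognormal <- function(rho, s) {
  rz <- log(1 + rho * (exp(s^2) - 1)) / s^2
  diag(rz) <- 1
  rz
}

# slow unit-variance latent processes, one column per channel, correlated
# through the spec's (compensated) correlation matrix; returned at the
# latent rate together with that rate
latent_envelope_base <- function(spec, seed) {
  fs_lat <- 4
  nl <- max(16L, round(spec$duration * fs_lat))
  nch <- length(spec$channels)
  nb <- nrow(spec$scheme$bands)
  z <- with_seed(seed, {
    arr <- array(stats::rnorm(nl * nch * nb), dim = c(nl, nch, nb))
    arr
  })
  # impose cross-channel correlation band by band (same-band design)
  L <- t(spec$chol_latent)
  for (m in seq_len(nb)) z[, , m] <- z[, , m] %*% t(L)
  # Gaussian low-pass in the frequency domain, then re-standardize
  ff <- (seq_len(nl) - 1) * fs_lat / nl
  ff <- pmin(ff, fs_lat - ff)
  H <- exp(-0.5 * (ff / spec$envelope_bandwidth)^2)
  for (m in seq_len(nb)) {
    zm <- z[, , m, drop = FALSE]
    dim(zm) <- c(nl, nch)
    Z <- stats::mvfft(zm)
    zf <- Re(stats::mvfft(Z * H, inverse = TRUE)) / nl
    zf <- sweep(zf, 2, apply(zf, 2, stats::sd), "/")
    zf <- sweep(zf, 2, colMeans(zf))
    z[, , m] <- zf
  }
  list(z = z, rate = fs_lat)
}

# lognormal envelopes (unit mean) for all channels/bands at the latent rate
envelopes_from_latents <- function(spec, lat) {
  s <- spec$envelope_sigma
  exp(s * lat$z - s^2 / 2)
}

# unit-variance constant-power carrier confined to [low, high): a single
# frequency-modulated component whose instantaneous frequency wanders
# slowly inside the band (3 Hz guard margin). Constant instantaneous
# power means the windowed band power tracks the applied envelope almost
# exactly, so the designed envelope correlation survives into the
# measured band-power series instead of being attenuated by the power
# fluctuations a filtered-noise realization would add.
band_carrier <- function(n, rate, low, high, seed, margin = 3) {
  with_seed(seed, {
    fs_mod <- 4
    nl <- max(16L, ceiling(n / rate * fs_mod))
    u <- stats::rnorm(nl)
    ffm <- (seq_len(nl) - 1) * fs_mod / nl
    ffm <- pmin(ffm, fs_mod - ffm)
    H <- exp(-0.5 * (ffm / 0.3)^2)
    u <- Re(stats::fft(stats::fft(u) * H, inverse = TRUE)) / nl
    u <- (u - mean(u)) / stats::sd(u)
    u <- pmin(pmax(u / 2.5, -1), 1)       # bounded wander in [-1, 1]
    t_lat <- (seq_len(nl) - 1) / fs_mod
    t <- (seq_len(n) - 1) / rate
    fc <- (low + high) / 2
    dev <- max((high - low) / 2 - margin, 0.5)
    finst <- fc + dev * stats::approx(t_lat, u, xout = t, rule = 2)$y
    ph0 <- stats::runif(1, 0, 2 * pi)
    sqrt(2) * cos(ph0 + 2 * pi * cumsum(finst) / rate)
  })
}

# all EMG channels of one participant share latent envelopes; carriers and
# noise are channel-specific
synth_emg_all <- function(spec, seed) {
  n <- round(spec$duration * spec$rate)
  lat <- latent_envelope_base(spec, seed)
  env <- envelopes_from_latents(spec, lat)
  t_lat <- (seq_len(dim(env)[1]) - 1) / lat$rate
  t_full <- (seq_len(n) - 1) / spec$rate
  nb <- nrow(spec$scheme$bands)
  out <- vector("list", length(spec$channels))
  names(out) <- spec$channels
  for (ci in seq_along(spec$channels)) {
    x <- numeric(n)
    for (m in seq_len(nb)) {
      if (spec$band_power[m] <= 0) next
      b <- spec$scheme$bands[m, ]
      carrier <- band_carrier(n, spec$rate, b$low, b$high,
                              seed = seed + 131L * ci + 7L * m)
      a <- sqrt(spec$band_power[m] *
                  stats::approx(t_lat, env[, ci, m], xout = t_full,
                                rule = 2)$y)
      x <- x + a * carrier
    }
    if (spec$emg_noise_sd > 0) {
      x <- x + with_seed(seed + 900000L + ci,
                         stats::rnorm(n, sd = spec$emg_noise_sd))
    }
    out[[ci]] <- recording(x, spec$rate, "emg", spec$channels[ci])
  }
  attr(out, "envelopes") <- env
  attr(out, "envelope_rate") <- lat$rate
  out
}

#' Generate one synthetic EMG channel
#'
#' Deterministic in (spec, seed): the shared latent envelopes of the whole
#' channel set are generated from the seed and the requested channel is
#' returned, so channels generated one by one from the same seed carry the
#' designed cross-channel envelope correlations.
#'
#' @param spec A [synth_spec()].
#' @param channel Channel name (must appear in `spec$channels`).
#' @param seed Integer seed (default `spec$seed`).
#' @return An EMG [recording()].
#' @export
synth_emg <- function(spec, channel, seed = spec$seed) {
  if (!channel %in% spec$channels) {
    stop("synth_emg: unknown channel '", channel, "'")
  }
  synth_emg_all(spec, seed)[[channel]]
}

#' Generate a synthetic EKG recording with ground-truth beats
#'
#' Beat times integrate the instantaneous heart-rate profile (a beat fires
#' whenever the accumulated phase crosses an integer); a stylized biphasic
#' QRS-like pulse is placed at each beat and Gaussian noise added at the
#' configured floor.
#'
#' @param spec A [synth_spec()].
#' @param seed Integer seed (default `spec$seed`).
#' @return List with `recording` (kind `"ekg"`) and `peaks`, the
#'   ground-truth `acfc_peak_train`.
#' @export
synth_ekg <- function(spec, seed = spec$seed) {
  n <- round(spec$duration * spec$rate)
  t <- (seq_len(n) - 1) / spec$rate
  hr <- spec$hr_profile(t)
  if (any(hr < 25 | hr > 250)) {
    stop("synth_ekg: hr_profile must stay within [25, 250] BPM")
  }
  phase <- cumsum(hr / 60) / spec$rate
  nbeats <- floor(phase[n])
  beat_times <- stats::approx(phase, t, xout = seq_len(nbeats))$y
  beat_times <- beat_times[!is.na(beat_times)]
  # only beats whose template fits entirely inside the recording
  beat_times <- beat_times[beat_times >= 0.06 &
                             beat_times <= spec$duration - 0.09 - 1 / spec$rate]
  # biphasic QRS template: sharp R upstroke with a smaller S dip
  tt <- seq(-0.06, 0.09, by = 1 / spec$rate)
  template <- exp(-0.5 * (tt / 0.008)^2) - 0.25 * exp(-0.5 * ((tt - 0.03) / 0.012)^2)
  x <- numeric(n)
  off <- which.max(template) - 1L
  for (bt in beat_times) {
    i0 <- round(bt * spec$rate) + 1L - off
    idx <- seq(i0, i0 + length(template) - 1L)
    ok <- idx >= 1L & idx <= n
    x[idx[ok]] <- x[idx[ok]] + template[ok]
  }
  if (spec$ekg_noise_sd > 0) {
    x <- x + with_seed(seed + 555000L, stats::rnorm(n, sd = spec$ekg_noise_sd))
  }
  # true beat times snapped to the sample grid, like the placed templates
  bt_snap <- (round(beat_times * spec$rate)) / spec$rate
  list(recording = recording(x, spec$rate, "ekg", "EKG"),
       peaks = structure(list(peak_times = bt_snap),
                         class = "acfc_peak_train"))
}

#' Generate a synthetic respiration recording
#'
#' Phase-integrated quasi-sinusoid following the breathing-rate profile,
#' with slow amplitude jitter and an additive noise floor; the
#' ground-truth instantaneous rate is `spec$br_profile`.
#'
#' @param spec A [synth_spec()].
#' @param seed Integer seed (default `spec$seed`).
#' @return A [recording()] of kind `"resp"`.
#' @export
synth_resp <- function(spec, seed = spec$seed) {
  n <- round(spec$duration * spec$rate)
  t <- (seq_len(n) - 1) / spec$rate
  br <- spec$br_profile(t)
  if (any(br < 4 | br > 80)) {
    stop("synth_resp: br_profile must stay within [4, 80] breaths/min")
  }
  phase <- 2 * pi * cumsum(br / 60) / spec$rate
  jitter <- with_seed(seed + 777000L, {
    nl <- max(16L, round(spec$duration * 2))
    z <- stats::rnorm(nl)
    stats::approx(seq(0, spec$duration, length.out = nl),
                  0.1 * stats::filter(z, rep(1 / 8, 8), sides = 2,
                                      circular = TRUE),
                  xout = t, rule = 2)$y
  })
  x <- (1 + jitter) * sin(phase)
  if (spec$resp_noise_sd > 0) {
    x <- x + with_seed(seed + 778000L, stats::rnorm(n, sd = spec$resp_noise_sd))
  }
  recording(x, spec$rate, "resp", "Resp")
}

#' Generate a full synthetic cohort with ground truth
#'
#' For every participant: the EMG channel set (shared correlated
#' envelopes), one EKG channel with true beat times, and one respiration
#' channel. The truth tables record, per participant, channel pair and
#' band, the designed envelope correlation, the compensated latent
#' correlation and the correlation actually measured between the generated
#' envelope series.
#'
#' @param spec A [synth_spec()].
#' @param out_dir Optional directory: each participant is written as
#'   CSV + sidecar via [write_recordings()], plus `truth.csv`.
#' @return List with `participants` (each with `emg`, `ekg`, `resp`,
#'   `true_peaks`), `truth` (data frame), and `spec`.
#' @export
synth_cohort <- function(spec, out_dir = NULL) {
  parts <- vector("list", spec$n_participants)
  truth <- list()
  for (p in seq_len(spec$n_participants)) {
    pseed <- spec$seed + 7919L * p
    emg <- synth_emg_all(spec, pseed)
    env <- attr(emg, "envelopes")
    ekg <- synth_ekg(spec, pseed)
    resp <- synth_resp(spec, pseed)
    nb <- nrow(spec$scheme$bands)
    cp <- utils::combn(length(spec$channels), 2L)
    for (q in seq_len(ncol(cp))) {
      i <- cp[1, q]; j <- cp[2, q]
      for (m in seq_len(nb)) {
        truth[[length(truth) + 1L]] <- data.frame(
          participant = p,
          channel_a = spec$channels[i], channel_b = spec$channels[j],
          band = spec$scheme$bands$label[m],
          rho_design = spec$rho[i, j],
          rho_latent = spec$rho_latent[i, j],
          rho_envelope_measured = stats::cor(env[, i, m], env[, j, m]),
          stringsAsFactors = FALSE)
      }
    }
    parts[[p]] <- list(emg = emg[], ekg = ekg$recording, resp = resp,
                       true_peaks = ekg$peaks)
    names(parts[[p]]$emg) <- spec$channels
  }
  truth <- do.call(rbind, truth)
  out <- list(participants = parts, truth = truth, spec = spec)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (p in seq_along(parts)) {
      recs <- c(parts[[p]]$emg, list(parts[[p]]$ekg, parts[[p]]$resp))
      write_recordings(recs, file.path(out_dir, sprintf("participant%02d.csv", p)),
                       overwrite = TRUE)
    }
    utils::write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  }
  out
}
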