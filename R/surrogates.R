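# run code under a temporary RNG seed, restoring global RNG state after
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Fourier phase-randomization surrogate of a recording
#'
#' Generates a surrogate signal whose amplitude spectrum equals the
#' original's bin for bin (conjugate-symmetric random phases; the DC
#' component and, for even lengths, the Nyquist bin are untouched), while
#' the temporal organization carried by the Fourier phases is destroyed.
#' Such surrogates retain the distribution of power across frequency bands
#' but break envelope co-modulation between channels, so genuine
#' amplitude-amplitude coupling collapses toward zero. The
#' `"amplitude-adjusted"` mode additionally restores the original
#' amplitude distribution by iterative rank remapping (IAAFT), at the cost
#' of only approximate spectrum preservation.
#'
#' @param rec A [recording()] of length at least 64.
#' @param seed Integer seed; the same seed reproduces the surrogate
#'   bit-identically and different channels should receive different
#'   seeds.
#' @param mode `"phase"` (default, spectrum-exact) or
#'   `"amplitude-adjusted"` (IAAFT).
#' @param iterations IAAFT iterations (amplitude-adjusted mode only).
#' @return A surrogate `Recording` with the same metadata.
#' @export
phase_randomize <- function(rec, seed, mode = c("phase", "amplitude-adjusted"),
                            iterations = 50) {
  mode <- match.arg(mode)
  x <- rec$samples
  n <- length(x)
  if (n < 64) stop("phase_randomize: need at least 64 samples")
  X <- stats::fft(x)
  amp <- Mod(X)
  surr <- with_seed(seed, {
    ph <- random_phase_vector(n)
    s <- Re(stats::fft(amp * exp(1i * ph), inverse = TRUE)) / n
    if (mode == "amplitude-adjusted") {
      sorted <- sort(x)
      for (it in seq_len(iterations)) {
        S <- stats::fft(s)
        s <- Re(stats::fft(amp * exp(1i * Arg(S)), inverse = TRUE)) / n
        s <- sorted[rank(s, ties.method = "first")]
      }
    }
    s
  })
  recording(surr, rec$rate, rec$kind, rec$channel_id, rec$start_time)
}

# conjugate-symmetric random phase vector; DC (and Nyquist, n even) keep
# the original phase structure by being left at zero rotation
random_phase_vector <- function(n) {
  ph <- numeric(n)
  half <- if (n %% 2 == 0) n / 2 - 1 else (n - 1) / 2
  if (half > 0) {
    rnd <- stats::runif(half, 0, 2 * pi)
    ph[2:(half + 1)] <- rnd
    ph[n:(n - half + 1)] <- -rnd
  }
  ph
}

#' Enumerate all unordered participant pairs
#'
#' @param n Number of participants (at least 2).
#' @return Two-column integer matrix with `choose(n, 2)` rows (595 rows
#'   for n = 35).
#' @export
participant_pairs <- function(n) {
  if (n < 2) stop("participant_pairs: need at least 2 participants")
  t(utils::combn(n, 2L))
}

#' Surrogate statistics and significance threshold
#'
#' @param values Pooled surrogate link strengths.
#' @return List with `mu_surr`, `sigma_surr` and
#'   `threshold = mu_surr + 2 * sigma_surr`.
#' @export
surrogate_threshold <- function(values) {
  mu <- mean(values)
  sg <- stats::sd(values)
  list(mu_surr = mu, sigma_surr = sg, threshold = mu + 2 * sg)
}

#' Cross-participant surrogate link distribution
#'
#' Builds the null distribution of link strengths used to declare links
#' physiologically significant. Every EMG channel of every participant is
#' phase-randomized (independent seeds per channel), band-power series are
#' recomputed through the identical pipeline, and for every unordered
#' participant pair, every muscle pair and every band-band link the
#' coupling is computed between signals of the two *different*
#' participants. Pooling all values gives `mu_surr`, `sigma_surr` and the
#' 95% significance threshold `Th = mu_surr + 2 sigma_surr`. Pairing is
#' exhaustive: 35 participants yield 595 combinations and, with 6 muscle
#' pairs of 100 links, 357,000 pooled values.
#'
#' @param cohort List of participants; each participant is a named list of
#'   EMG [recording()]s (same channel names across participants).
#' @param config An [acfc_config()] (band scheme and global window/step
#'   are taken from it).
#' @param seed Integer base seed.
#' @param mode Surrogate mode, see [phase_randomize()].
#' @return An `acfc_surrogate_dist`: `values`, `mu_surr`, `sigma_surr`,
#'   `threshold`, plus bookkeeping counts.
#' @export
surrogate_link_distribution <- function(cohort, config = acfc_config(),
                                        seed = config$seed, mode = "phase") {
  np <- length(cohort)
  if (np < 2) stop("surrogate_link_distribution: need at least 2 participants")
  scheme <- make_band_scheme(config$band_low, config$band_width,
                             config$band_count, config$bin_width,
                             config$band_exclusions)
  chans <- names(cohort[[1]])
  # per-participant surrogate band-power series, computed once
  surr_bp <- vector("list", np)
  for (p in seq_len(np)) {
    surr_bp[[p]] <- lapply(seq_along(chans), function(ci) {
      sr <- phase_randomize(cohort[[p]][[chans[ci]]],
                            seed = seed + 1000L * p + ci, mode = mode)
      lapply(band_power_series(sr, scheme, config$global_window,
                               config$global_step), zscore_global)
    })
    names(surr_bp[[p]]) <- chans
  }
  pp <- participant_pairs(np)
  mp <- t(utils::combn(chans, 2L))
  vals <- vector("list", nrow(pp) * nrow(mp))
  k <- 0L
  for (r in seq_len(nrow(pp))) {
    for (q in seq_len(nrow(mp))) {
      cm <- coupling_matrix(surr_bp[[pp[r, 1]]][[mp[q, 1]]],
                            surr_bp[[pp[r, 2]]][[mp[q, 2]]],
                            lag = config$lag)
      k <- k + 1L
      vals[[k]] <- as.vector(cm$values)
    }
  }
  values <- unlist(vals)
  st <- surrogate_threshold(values)
  structure(list(values = values, mu_surr = st$mu_surr,
                 sigma_surr = st$sigma_surr, threshold = st$threshold,
                 n_participant_pairs = nrow(pp),
                 n_system_pairs = nrow(mp),
                 n_links = length(vals[[1]])),
            class = "acfc_surrogate_dist")
}

#' @export
print.acfc_surrogate_dist <- function(x, ...) {
  cat(sprintf("<Surrogate distribution: %d values (%d participant pairs x %d system pairs x %d links)>\n",
              length(x$values), x$n_participant_pairs, x$n_system_pairs,
              x$n_links))
  cat(sprintf("  mu = %.4f, sigma = %.4f, Th = mu + 2 sigma = %.4f\n",
              x$mu_surr, x$sigma_surr, x$threshold))
  invisible(x)
}

#' Flag non-significant links in a network
#'
#' Links whose strength does not exceed the surrogate threshold are
#' flagged `significant = FALSE` but retained in the map.
#'
#' @param network An `acfc_network`.
#' @param th Threshold in [0, 1] (e.g. the `threshold` of an
#'   `acfc_surrogate_dist`).
#' @return The network with a logical `significant` column on its links.
#' @export
apply_threshold <- function(network, th) {
  if (!(th >= 0 && th <= 1)) stop("apply_threshold: th must lie in [0, 1]")
  network$links$significant <- network$links$strength > th
  network
}
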