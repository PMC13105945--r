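# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# wrap a plain numeric vector as a band-power series for coupling tests
make_bp <- function(values, band = "F1", muscle = "M", step = 1,
                    t0 = 1, normalized = FALSE) {
  structure(list(muscle_id = muscle, band_label = band,
                 times = t0 + (seq_along(values) - 1) * step,
                 values = as.numeric(values), step = step,
                 window_length = 2, normalized = normalized),
            class = "acfc_band_power")
}

make_bp_set <- function(mat, muscle = "M", step = 1) {
  lapply(seq_len(ncol(mat)), function(j) {
    make_bp(mat[, j], band = paste0("F", j), muscle = muscle, step = step)
  })
}

# two EMG channels, 600 s, designed same-band envelope correlation 0.6:
# the spec'd conditions for coupling-recovery and surrogate-collapse checks
coupled_pair_600s <- function() {
  fixture("coupled_pair_600s", function() {
    spec <- synth_spec(n_participants = 1, duration = 600,
                       channels = c("LegL", "LegR"), rho_same = 0.6,
                       rho_diff = 0.2, seed = 11L)
    emg <- list(LegL = synth_emg(spec, "LegL"), LegR = synth_emg(spec, "LegR"))
    bp <- lapply(emg, function(r) {
      lapply(band_power_series(r), zscore_global)
    })
    list(spec = spec, emg = emg, bp = bp)
  })
}

# clean synthetic EKG, 180 s, slowly modulated heart rate, with truth
ekg_180s <- function() {
  fixture("ekg_180s", function() {
    spec <- synth_spec(n_participants = 1, duration = 180, seed = 3L)
    c(synth_ekg(spec), list(spec = spec))
  })
}

# default five-participant cohort at a short duration (counts and network
# bookkeeping do not depend on recording length)
cohort_default <- function() {
  fixture("cohort_default", function() {
    synth_cohort(synth_spec(n_participants = 5, duration = 60, seed = 9L))
  })
}
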