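# acfc

Amplitude–amplitude cross-frequency coupling (ACFC) for physiological
networks: an R toolkit that turns simultaneous EMG, EKG and
respiratory-belt recordings into inter-muscular, cardio-muscular and
respiratory-muscular coupling matrices, multiplex network maps, coupling
time series and variability statistics, with surrogate-based significance
thresholds and a seeded synthetic-cohort generator for end-to-end
validation.

It is written for movement physiologists and network-physiology
researchers who record several muscles at ≥500 Hz together with one EKG
and one respiration channel and want to quantify how the *amplitudes* of
spectral components co-modulate across frequency bands and organ systems
— the coordination signature that raw-waveform correlation misses.

## The method in brief

1. **Band power.** Each EMG channel is band-pass (5–250 Hz) and notch
   filtered, segmented into sliding windows (2 s / 1-s step), tapered and
   Fourier transformed; power on a 0.5-Hz grid is summed over ten
   19.5-Hz-wide bands F1–F10 spanning 10–230 Hz (the 50–65 Hz notch
   region is skipped):
   `P(F_m, t_i) = Σ_{f_j ∈ F_m} S(f_j, t_i)`, then each band series is
   z-scored.
2. **Rates.** Pan–Tompkins R-peak detection gives instantaneous heart
   rate 60/RR (cubic-spline resampled to 1 s, artifact-corrected with a
   ±2 SD / 10-s window rule); a 20-s/0.5-s windowed spectral ridge gives
   breathing rate.
3. **Global coupling.** Equal-time Pearson coefficients `C_{m,k}` at zero
   lag (configurable) between all band pairs of each muscle pair
   (10×10 = 100 links) and between HR/BR and each muscle's bands
   (1×10), averaged across participants and drawn as a multiplex network
   with link-strength classes.
4. **Dynamic coupling.** Within 6-s windows (3-s step) both series are
   re-normalized locally and
   `C^{t_i}_{τ=0} = (1/(W−1)) Σ_j P̂1_j P̂2_j` yields a coupling time
   series per link (600 series for four muscles), summarized by Δc = 0.05
   histograms rescaled to their peak, SD/skewness/kurtosis, detrended
   fluctuation analysis (`F(n) ~ n^α`; α = 0.5 white noise, 1.5 random
   walk) and the magnitude–sign decomposition of increments ΔC.
5. **Significance.** Fourier phase-randomization surrogates (spectrum
   preserved exactly, temporal organization destroyed) computed across
   every pair of *different* participants pool into a null distribution
   whose threshold is `Th = μ_surr + 2σ_surr`.

## Worked example

```r
library(acfc)

# a small synthetic cohort with known ground truth:
# same-type muscle pairs couple at rho = 0.6, different-type at 0.2
spec <- synth_spec(n_participants = 2, duration = 300,
                   rho_same = 0.6, rho_diff = 0.2, seed = 42)
cohort <- synth_cohort(spec)
p <- cohort$participants[[1]]

res <- acfc_participant(p$emg, ekg = p$ekg, resp = p$resp,
                        preprocess = FALSE)
res$matrices[["LegL-LegR"]]
```

```
<Coupling matrix LegL-LegR (10x10), lag 0 s, n=1>
        F1     F2     F3     F4     F5     F6     F7     F8     F9    F10
F1   0.615 -0.050  0.033  0.077  0.154 -0.012 -0.040  0.122 -0.006  0.049
F2  -0.094  0.507 -0.015 -0.185 -0.056 -0.002  0.119 -0.081  0.067 -0.056
...
F10  0.108 -0.166 -0.067  0.081 -0.078  0.109  0.000  0.148  0.090  0.478
```

The diagonal (same-band links) recovers the designed coupling of 0.6 up
to estimator noise, while off-band links scatter around zero — the
designed cross-band correlation. Mean link strength per sub-network shows
the designed hierarchy (same-type pairs above different-type pairs):

```r
network_pair_summary(res$network)
```

```
         pair mean_strength n_links
1 BackL-BackR    0.04766663     100
2  LegL-BackL    0.02008390     100
3  LegL-BackR    0.02934093     100
4   LegL-LegR    0.05726330     100
5  LegR-BackL    0.01823236     100
6  LegR-BackR    0.02598296     100
```

(Means over all 100 links are diluted by the 90 near-zero off-band
links; the same-band diagonal means are 0.55 for LegL–LegR vs 0.16 for
LegL–BackL.) Temporal
variability of one link and the cohort-level significance threshold:

```r
cts <- res$dynamic[["LegL-LegR"]][["F1:F1"]]
static_stats(cts)[, c("n", "sd", "skewness", "kurtosis_pearson")]
#>    n        sd  skewness kurtosis_pearson
#> 1 98 0.4171688 -1.249961         3.600179

surrogate_link_distribution(lapply(cohort$participants, `[[`, "emg"),
                            seed = 42)
#> <Surrogate distribution: 600 values (1 participant pairs x 6 system pairs x 100 links)>
#>   mu = 0.0018, sigma = 0.0601, Th = mu + 2 sigma = 0.1221
```

Links whose group-averaged strength exceeds `Th` are flagged significant
via `apply_threshold()`. A command-line front end covering the same
stages (`synth`, `preprocess`, `bandpower`, `rates`, `global`, `dynamic`,
`variability`, `surrogate`, `run`) is installed at
`system.file("cli", "acfc", package = "acfc")`.

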