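---
title: "Amplitude-amplitude cross-frequency coupling: models and methods"
author: "acfc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amplitude-amplitude cross-frequency coupling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

During whole-body movement the muscles, the heart and the respiratory
system do not act in isolation: the power that a muscle expresses in
specific EMG frequency bands waxes and wanes together with the power of
other muscles' bands, with the instantaneous heart rate and with the
breathing rate. `acfc` quantifies this *amplitude-amplitude
cross-frequency coupling*: instead of comparing raw waveforms, it compares
the slow amplitude modulations of band-limited spectral power across
channels and systems, producing coupling matrices, multiplex network maps,
coupling time series and variability statistics.

## The measurement model

**Band power.** Each EMG channel is band-pass filtered (5-250 Hz by
default) and notch filtered at the mains frequency, then segmented into
sliding windows (2 s with a 1-s step for inter-muscular and
cardio-muscular analyses). Each window is tapered (Hamming) and Fourier
transformed as a single segment; power is accumulated on a 0.5-Hz grid
over 10-250 Hz (480 bins for a 2-s window). Ten bands of equal 19.5-Hz
width partition 10-230 Hz, skipping 50-65 Hz because the notch filter
empties it: F1 = [10, 29.5], F2 = [30, 49.5], F3 = [65, 84.5], ...,
F10 = [205, 224.5]. The band power is

$$P(F_m, t_i) = \sum_{f_j \in F_m} S(f_j, t_i),$$

one value per band per window centre $t_i$. Before the global analysis
every band series is z-scored over the whole segment (zero mean, unit SD),
so coupling reflects relative co-modulation rather than absolute
amplitude.

*Bin convention.* The printed inclusive band edges ([10, 29.5] on a
0.5-Hz grid) would contain 40 grid points, while each band is defined to
hold 39 bins. We resolve this by assigning bins under a half-open
convention, $f \in [\mathrm{low}, \mathrm{low} + 19.5)$, which yields
exactly 39 bins per band and never assigns a bin twice; the 0.5-Hz sliver
at each band's upper printed edge belongs to no band. The conservation
test (band sums equal the spectrum summed over assigned bins) is stated
accordingly.

**Rate series.** R peaks are detected with the Pan-Tompkins cascade
(band-pass 5-15 Hz, derivative, squaring, 150-ms moving-window
integration, adaptive two-level thresholding with a 250-ms refractory
period), refined to the extremum of the band-passed signal. Instantaneous
heart rate is 60/RR beats per minute, assigned at the later R peak of
each interval — a causal convention; the source method does not state an
anchor — and cubic-spline resampled to a 1-s grid whose timestamps
coincide with band-power window centres. Artifacts are corrected with a
local rule: any point deviating from the mean of its 10-s window by more
than two of that window's SDs is replaced by the window mean. The window
is *centred on the evaluated point and includes it*; statistics are taken
from the original series in one pass, so the result does not depend on
processing order. Breathing rate comes either from prominence-based
breath-peak detection (clean recordings) or, preferably during movement,
from a windowed-spectrum ridge: 20-s windows stepped by 0.5 s, dominant
frequency in a 0.05-1.0 Hz search band located by parabolic interpolation
on a four-fold zero-padded grid, converted to breaths/min, then smoothed
with a 2-s moving average. This ridge extractor is a deliberately
self-contained replacement for external wavelet time-frequency toolboxes;
it honours the same 20-s/0.5-s windowing contract and is accurate to a
fraction of a breath per minute on quasi-sinusoidal input, as the tests
verify.

**Global coupling (phase 1).** For each pair of systems the equal-time
Pearson coefficient is computed between every pair of series on their
trimmed common time support, giving a 10 x 10 matrix per muscle pair (100
links) and a 1 x 10 matrix per rate-muscle pair. The default lag is zero;
`best_lag()` scans candidate lags (in steps of the series resolution)
with ties broken toward the smallest absolute lag, negative first.
Group-level matrices are element-wise means of raw coefficients (a
Fisher-z option exists but is off by default, matching the method's
plain-average definition). Matrices map onto a multiplex network whose
nodes are (system, band) pairs; links are classified against configurable
breakpoints. Because the published stratifications differ by context,
four presets ship: `methods` (0.20/0.35/0.50/0.65), `fig6_intermuscular`
(0.05/0.15/0.25/0.35), `fig6_cardio` (0/0.10/0.20/0.30) and `fig6_resp`
(0.15/0.30/0.45/0.60). The classes are presentational; none is canonical.

**Dynamic coupling (phase 2).** To resolve how coupling fluctuates, the
band-power (and rate) series are re-normalized *locally* within each 6-s
window (3-s step) and the zero-lag coefficient

$$C^{t_i}_{\tau=0}(F_m, F_k) = \frac{1}{W-1}\sum_{j=1}^{W}
\hat P_1(F_m, t_i, j)\, \hat P_2(F_k, t_i, j)$$

is computed per window — exactly the per-window Pearson correlation.
Local normalization preserves the short-timescale fluctuation pattern
that whole-segment normalization would distort. The window/step
description ("6-s windows, 3-s step") and the segment-count shorthand
"NL = N/L" in the source cannot both hold; we follow the window/step
description, so a support of duration $T$ yields
$\lfloor (T - 6)/3 \rfloor + 1$ windows, with values placed at window
centres. Windows with zero variance yield missing values — flagged, never
imputed as zero — and propagate as missing through histograms and
statistics.

**Variability measures (step 8).** Per link: the histogram of coupling
values over fixed bins of width $\Delta c = 0.05$ spanning $[-1, 1]$,
rescaled to its peak; SD (n-1 denominator), skewness ($m_3/m_2^{3/2}$)
and kurtosis, reported in both the Pearson (normal = 3) and excess
conventions so no consumer has to guess; detrended fluctuation analysis
of the coupling series; and the magnitude-sign decomposition
$\Delta C(t_i) = C(t_{i+1}) - C(t_i)$ into $|\Delta C|$ (nonlinear
features) and $\mathrm{sgn}\,\Delta C$ (linear features), with
$\mathrm{sgn}(0) = 0$ retained.

**DFA.** The profile $Y(k) = \sum_{i \le k} (C(t_i) - \bar C)$ is divided
at each scale $n$ into non-overlapping windows; after removing a local
polynomial trend of order 1 (DFA-1 by default) the fluctuation function is

$$F(n) = \sqrt{\tfrac{1}{N}\sum_{k=1}^{N}\left(Y(k) - Y_n(k)\right)^2},$$

and $F(n) \sim n^\alpha$ defines the scaling exponent: $\alpha = 0.5$ for
uncorrelated noise, $1.5$ for a random walk, intermediate values for
persistent correlations. The source cites the original formulation
without parameters, so we adopt community defaults: about 15 log-spaced
scales from 4 to $N/4$, non-overlapping windows, forward and reversed
profile passes averaged, exponent from a least-squares fit of
$\log F$ on $\log n$ over all usable scales. Note that DFA-1 annihilates
a *linear profile* (constant signal), not a linear signal trend — a ramp
signal integrates to a quadratic profile and requires DFA-2; both
properties are tested. Degenerate inputs (constant series, fewer than two
positive fluctuation values) return `NA` exponents rather than failing.

**Surrogate testing.** Fourier phase randomization replaces each
channel's phases with conjugate-symmetric uniform random phases (DC and
Nyquist untouched), preserving the amplitude spectrum bin for bin while
destroying the temporal organization that carries envelope co-modulation.
Strictly, a surrogate cannot preserve both the power spectrum and the
amplitude distribution; the default is the spectrum-exact classical
variant, with an IAAFT amplitude-adjusted option for users who need the
marginal distribution retained. The link-significance threshold pools
coupling values computed between phase-randomized signals of *different*
participants — all unordered pairs, enumerated exhaustively (595 pairs for
35 participants; 6 muscle pairs x 100 links x 595 = 357,000 values) — and
sets $Th = \mu_{surr} + 2\sigma_{surr}$. Surrogate values run through the
identical band-power/normalization/coupling code path as real data.
Links at or below `Th` are flagged non-significant but retained.

## The synthetic cohort

The generator provides ground truth that human recordings cannot. Each
EMG channel is

$$x(t) = \sum_m \sqrt{w_m\, E_m(t)}\; c_m(t),$$

where each envelope $E_m$ is a lognormal map of a slow latent Gaussian
process (bandwidth 0.2 Hz, matching slow exercise-cycle timescales;
log-SD 0.5) and same-band latents are correlated across channels. Two
choices matter:

* *Exact envelope correlation.* The lognormal map shrinks correlations,
  so the latent correlation is set to
  $\rho_z = \log(1 + \rho\,(e^{s^2}-1))/s^2$, making the *envelope*
  correlation equal the design $\rho$ exactly. Truth tables record the
  design value, the compensated latent value and the correlation measured
  on the realized envelopes.
* *Constant-power carriers.* Each $c_m$ is a unit-variance
  frequency-modulated component wandering slowly inside its band (3-Hz
  guard margin) rather than a filtered-noise realization. Filtered noise
  carries chi-square power fluctuations that attenuate the measurable
  band-power correlation well below the designed envelope correlation;
  a constant-power carrier makes the windowed band power track the
  envelope almost exactly, so the estimator's recovery can be tested
  against the design value within +/-0.07.

The default cohort is 5 participants, 600 s at 1000 samples/s, four EMG
channels (LegL, LegR, BackL, BackR) with same-type envelope correlation
0.6 and different-type 0.2, an EKG pulse train integrating a programmable
rate profile (beats are only placed where the full QRS template fits, so
truth and waveform agree), and a phase-integrated quasi-sinusoidal
respiration channel. Everything is a pure function of (spec, seed).

What the generator does *not* emulate: motor-unit physiology and
non-Gaussian EMG amplitude statistics, cross-band envelope correlation
(off-band design correlations are zero; spectral leakage adds only a
small positive bias between adjacent bands), movement artifacts,
electrode noise, ectopic beats and P/T-wave morphology. Passing the
recovery tests therefore demonstrates that the estimator chain is
correct and unbiased under its own model assumptions, not that every
physiological confounder is handled.

## Numerical and design choices

* Filters: 4th-order Butterworth applied forward-backward (zero phase,
  preserving the timing that equal-time coupling depends on), band-pass
  realized as a high-pass/low-pass cascade for numerical robustness at
  low cut-offs, notch as a 1-Hz-wide band-stop, odd-reflection padding
  against edge transients.
* Spectral taper: Hamming on the single segment per window, configurable;
  power scaled so in-band sums obey Parseval against the taper-corrected
  mean square.
* Windows not fully contained in a recording are dropped — no padding —
  to avoid edge-biased estimates; all timestamps refer to window centres.
* Coupling values are clipped to $[-1, 1]$ only against floating-point
  rounding; exact ties in lag scans resolve deterministically.
* The respiratory channel is block-mean decimated to ~25 Hz before ridge
  extraction, with the decimated rate chosen so the 0.5-s step maps to a
  whole number of samples (timestamps stay on the step grid).
* HR/BR series are clamped to configurable physiological bounds
  (25-250 BPM, 4-80 breaths/min) after spline interpolation.
* Group averaging ignores missing cells and records the participant
  count.

## Problem sizes used by the test-suite

Structural bookkeeping (matrix shapes, 600 link series, exhaustive pair
counts) does not depend on recording length, so the cohort-level tests
run the default five-participant cohort at 60 s. Estimator-recovery tests
use the conditions under which the tolerances are stated: 600 s for
coupling recovery and surrogate collapse, 180 s for heart-rate recovery,
300 s for the breathing-rate chirp, and series of length 10,000 averaged
over 20 seeds for the DFA limits. `scripts/acceptance.R` recomputes the
DFA exponents at exactly those sizes.

## Limitations

Pearson coupling captures linear equal-time co-modulation only; the
method's own magnitude-sign analysis is the first step beyond that. The
ten-band scheme presumes surface EMG with energy to ~230 Hz and a mains
notch; other band layouts are supported but the printed edges apply to
the default. The surrogate threshold assumes exchangeability across
participants. DFA exponents from short coupling series (tens of windows)
are noisy; `variability_summary()` refuses series shorter than 16 windows
by default. EDF ingestion is out of scope — the CSV-plus-sidecar contract
is this package's own storage choice, since the method prescribes none.
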