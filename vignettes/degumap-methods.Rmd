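---
title: "Methods: spatial maps, LFP bands, phase locking, and ripples in degumap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial maps, LFP bands, phase locking, and ripples in degumap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degumap)
```

degumap analyzes tetrode recordings from rodent hippocampal CA1 during
open-field foraging and novel-object-location sessions. This vignette is the
package's account of the science it implements: the models and procedures,
the parameters that matter and why they have the defaults they do, what the
synthetic-session generator does and does not emulate, and the numerical
choices made where the design was genuinely open.

## Data model

A session is a `session_record`: spike trains per sorted unit (timestamps in
seconds on the session clock, which starts at 0), a 50 Hz video trajectory in
a 90 cm square arena (absent for rest sessions, which happen in a 30 cm box
out of camera range), one or more LFP channels at 2 kHz, and metadata
(session type, object positions). All coordinates are cm with the origin at
the arena's south-west corner; spatial bins are half-open `[low, high)`.

Preprocessing follows fixed conventions:

* **LFP** is low-pass filtered at 1 kHz with a zero-phase (forward-backward)
  4th-order Butterworth filter and decimated to 2 kHz (`preprocess_lfp()`).
  Zero-phase filtering is used for every filter in the package so that phase
  analyses are not biased by filter lag.
* **Running speed** is displacement over a 200 ms window divided by the
  elapsed time, evaluated per tracking sample with a centered window (±100
  ms), trailing at the record edges (`compute_speed()`). The centered
  convention gives a symmetric instantaneous estimate; at 50 Hz the two
  conventions differ by at most two samples.
* **Tracking gaps** longer than 0.5 s are flagged and excluded from
  occupancy and speed, never interpolated. Out-of-arena positions are
  clamped to the walls and counted in a QC report.

## Spatial maps, information, and stability

`build_rate_map()` bins the trajectory on a 2.5 cm grid, accumulates
occupancy time and spike counts per bin (each spike is assigned the position
of the most recent tracking sample), forms the ratio map, and smooths it
with a 2D Gaussian kernel of 1.6 bin standard deviations. The kernel is
renormalized over visited bins only, so no rate leaks into unvisited space
and unvisited bins remain undefined rather than zero. Occupancy
probabilities `p_i` and the mean rate `lambda = sum(p_i * lambda_i)` are
recomputed from the smoothed map, and both conservation identities are
asserted on every map.

Spatial information is the Skaggs measure

$$I_{\text{spike}} = \sum_i p_i \frac{\lambda_i}{\lambda}
  \log_2\!\frac{\lambda_i}{\lambda} \quad \text{(bits/spike)},
  \qquad I_{\text{rate}} = \lambda \, I_{\text{spike}} \quad \text{(bits/s)}.$$

Both modes are exposed; the default is the information *rate*, because
classification thresholds for place cells are conventionally quoted in
bits/s. On the hand-evaluable two-bin map with equal occupancy and rates
(2, 0) Hz both forms equal exactly 1.

Split-half **stability** is the Pearson correlation between smoothed maps
built from the two halves of the session (split at the time midpoint), over
bins visited in both halves; with fewer than 10 jointly visited bins the
score is undefined and flagged rather than reported as 0.

### Shuffle nulls and classification

Chance levels come from circular time shifts: the whole spike train is
shifted along the trajectory by a uniform random interval in
`[30 s, T - 30 s]`, wrapping the end of the session to the beginning, which
preserves spike count and the full autocorrelation structure while breaking
the spike-position relationship. The default is 1000 shuffles per cell for
spatial statistics and 100 for phase locking, both configurable. All cells'
shuffled values are pooled, and the 95th/99th percentiles of the pool
(linear interpolation between order statistics) become the thresholds; a
cell passes on a strict inequality. Ties at the threshold therefore do not
pass — an arbitrary but fixed rule.

Whether a *population* contains more passing cells than chance is an exact
binomial tail: with `N` cells and chance probability `q` per cell, the
p-value for observing `S` or more passers is `sum_{l=S..N} C(N,l) q^l
(1-q)^(N-l)`, computed as a log-space sum of `dbinom(log = TRUE)` terms so
that p-values of order 1e-100 remain accurate
(`population_pvalue()`).

```{r}
population_pvalue(95, 26, 0.05)
```

### Open choices made here

* The printed information formula is dimensionless per spike while
  published thresholds are in bits/s; the package defaults to the rate form
  and exposes both.
* Any bin with positive occupancy counts as visited; no minimum-dwell
  criterion is applied (none is stated in the source methods).
* 5 cm binning exists only as a visualization option; statistics always use
  2.5 cm bins.

## Object exploration and object-related firing

Object positions (P1, P2, P3) define 10 cm circles. `exploration_time()`
accumulates tracked dwell time inside each circle over consecutive 30 s
windows; circle membership includes the boundary (a measure-zero choice at
50 Hz). Comparisons conventionally restrict to the first 5 minutes of each
session, where novelty-driven exploration is concentrated — in the package
this is a filter on the window table, applied by the caller.

`normalized_session_rates()` divides each unit's per-session rate by the
*unweighted mean* of its rates over the day's four sessions, so each neuron
contributes equally to population statistics regardless of its absolute
rate; by construction the day-mean of normalized rates is 1 per unit, and
this is asserted. The unweighted reading of "averaged over the sessions"
generalizes correctly to sessions of unequal duration.

`local_object_rates()` computes rates inside each circle and in the
complement of their union from raw events and raw occupancy — no binning, no
smoothing — and reports unvisited regions as undefined (`NA`), never 0.

Group comparisons (`session_comparisons()`) wrap the standard
nonparametric tests from `stats`. The Tukey–Kramer-style post-hoc after a
Kruskal–Wallis test is implemented as Tukey HSD on rank-transformed data,
the closest construction available from base R; the Wilcoxon z statistic is
recovered from the two-sided p-value via the normal quantile, signed by the
direction of the group medians.

## LFP spectral analysis and speed-defined bands

Three complementary views of the LFP:

* `psd_windows()`: one-sided periodograms of consecutive 2 s windows
  (0.5 Hz resolution), normalized so `sum(psd) * df` equals the window's
  mean squared amplitude (Parseval is tested at 1%). Window subsets are
  selected by joining on per-window mean speed (cutoffs 5 or 1 cm/s) or
  low-theta state; the median across windows is preferred to the mean to
  down-weight high-amplitude channels.
* `morlet_transform()`: analytic complex Morlet CWT with a fixed
  nondimensional width of 6 cycles (a conventional choice; exposed as a
  parameter), normalized so a sinusoid of amplitude A yields instantaneous
  amplitude A at its frequency. Implemented in the frequency domain with
  one FFT of the signal reused across frequencies; output can be
  subsampled to the tracking clock so dense grids over 20-minute sessions
  stay in memory.
* `band_envelope()`: instantaneous amplitude and phase of a whole band.
  The zero-phase 4th-order Butterworth band-pass is applied *spectrally* —
  the FFT is multiplied by the closed-form forward-backward magnitude
  response `|H(f)|^2` of the filter and the analytic signal is formed in
  the same pass. This is numerically exact and remains stable for
  arbitrarily narrow normalized bands (a time-domain IIR recursion for the
  1–5 Hz band at 2 kHz is unstable in double precision). Phase 0
  corresponds to the positive peak of the band-filtered signal; published
  phase angles are not portable across phase-origin conventions.

**Speed–amplitude profiles** (`speed_amplitude_profile()`) express the mean
instantaneous amplitude per 2.5 cm/s speed bin (0–30 cm/s) as percent
change relative to the lowest bin — the "0 cm/s" reference. Frequency bands
are then *defined* by the sign structure of this profile
(`derive_band_boundaries()`): frequencies whose mean change over the
10–30 cm/s range exceeds 3% in magnitude are classified by sign, runs of
consistent sign become regimes, and the boundary between adjacent
opposite-sign regimes is placed at the interpolated zero crossing of the
coupling curve. Zero crossings are used because the wavelet's bandwidth
(`sigma_f = f / n_cycles`) makes the sign transition gradual: run endpoints
alone systematically under-cover each regime, while the crossing is an
unbiased edge estimate whenever spectral density is continuous across the
edge. The canonical analysis bands — delta 1–5, theta 6–11, beta 20–30,
gamma 35–100 Hz, ripple 120–240 Hz — are available as constants
(`canonical_bands()`); the conservative 20 Hz lower edge of beta avoids
the first theta harmonic.

## Spike-phase locking

Units are split at a mean-rate cutoff of 7 Hz into putative pyramidal
(≤ 7 Hz, ties inclusive) and putative fast-spiking cells. For each unit and
band, the band phase is linearly interpolated at spike times — on the
unwrapped phase, then re-wrapped, to avoid ±π artifacts — and summarized by
the mean vector length `R = |mean(exp(i phi))|`. Significance again uses
circular time shifts (100 per cell), pooled across units per band; with
fewer than 20 spikes R is strongly positively biased, so such results are
flagged and their significance suppressed.

The shuffle null is only informative when band phase is non-stationary:
against a strictly periodic oscillation a time-shifted train remains
phase-locked. Real LFP (and the generator's noise-driven bands) drift in
frequency, which is what makes the null work; the package's tests use
broadband components for exactly this reason.

`phase_rate_curve()` bins spikes by phase, divides by the *time the
oscillation spent in each phase bin* (dwell correction — without it any
asymmetric oscillator would fake phase modulation), normalizes by the
unit's mean rate, and averages across units; the circular mean of the
population curve summarizes the preferred phase.
`spike_lag_histogram()` provides the classical autocorrelogram view.

## Sharp-wave ripples

Because the sharp wave itself has spectral content overlapping theta,
low-theta *episodes* are defined from the ratio of Morlet amplitudes at
8 Hz and 6 Hz, each smoothed by a centered 15 s moving average (reflection
padding at the edges): an episode is a maximal run where the 8 Hz amplitude
does not exceed 1.4× the 6 Hz amplitude. The criterion is a ratio, hence
invariant to overall gain; its temporal resolution is the 15 s smoothing
width.

Events are peaks of the Hilbert envelope of the 120–240 Hz band exceeding
the envelope mean by 5 SD, gated to low-theta episodes, with a 0.5 s
minimum spacing enforced greedily by descending amplitude (deterministic
and order-independent). The SD baseline is the whole record by default
(configurable to episodes-only). Event rates are counted in 1-minute
windows and pooled by session type. `swr_spectral_signature()` checks for
the ripple-band bump in a PSD batch against a log-log linear background
fit over 60–300 Hz (excluding the band): a peak is an interior local
maximum of the residual exceeding 0.1 log10 units (~26%).

## The synthetic-session generator

Every stage is validated by parameter recovery on synthetic sessions whose
generative assumptions match what the analyses assume:

* **Trajectory** (`simulate_trajectory()`): 2D Ornstein–Uhlenbeck velocity
  (persistence 2 s) reflected at the walls, interleaved with
  exponential move/pause bouts (means 8 s / 2 s). The pauses matter: a pure
  OU forager essentially never moves below 2.5 cm/s, leaving the 0 cm/s
  reference bin of speed profiles empty, whereas real foraging rodents
  pause constantly. The OU scale is duty-cycle-corrected so the long-run
  mean speed equals the requested 15 cm/s default.
* **Place cells** (`simulate_place_cell()`): inhomogeneous Poisson spikes
  with a Gaussian rate bump (default peak 10 Hz, width 10 cm, baseline
  0.1 Hz), drawn per 20 ms tracking interval.
* **LFP** (`simulate_lfp()`): a sum of per-band components whose amplitude
  is modulated linearly by interpolated running speed, plus 1/f pink
  background noise. Default components tile the spectrum contiguously
  (delta 1–5, theta 6–11, beta 12–30, gamma 31–100 Hz) with in-band 1/f
  spectral shape and RMS amplitudes drawn from a common 1/f envelope, so
  the composite spectrum is continuous across edges, as in real
  recordings; the generative beta regime deliberately spans 12–30 Hz even
  though the conservative analysis band starts at 20 Hz. Default slopes
  (−0.0093, +0.0053, −0.0040, +0.0067 per cm/s) reproduce the
  characteristic coupling magnitudes of CA1 (−28%, +16%, −12%, +20%
  between immobility and 30 cm/s). Spectral continuity is also what makes
  edge recovery well-posed: at a density-matched edge the zero crossing of
  the coupling curve falls on the edge regardless of wavelet smearing.
* **Phase-locked spiking** (`simulate_phase_locked_spikes()`): intensity
  proportional to a von Mises density of the band's Hilbert phase,
  normalized to the requested mean rate; as spike count grows the mean
  vector length converges to the Bessel ratio `I1(kappa)/I0(kappa)`, which
  the tests verify for kappa in {0.5, 1, 2, 4} to within 0.01.
* **Ripples**: Hanning-windowed bursts (default 180 Hz, 80 ms, centered on
  the stated event time) riding on a slow negative sharp-wave deflection,
  so the low-theta gating is exercised realistically.

What the generator does **not** emulate: theta's spectral peak above the
1/f background (components are pink within their bands), theta-phase
precession, cross-frequency coupling, multi-channel covariance across
tetrodes, spike-sorting errors, and tracking noise. Passing recovery tests
therefore demonstrates correctness of the estimators under the stated
generative model, not robustness to every artifact of real recordings.

## Numerical choices and problem sizes

* Degenerate inputs: zero-occupancy maps error; zero-mean-rate information
  is defined as 0 with a warning; constant LFP yields zero ripple events
  (the envelope SD has no meaningful scale); empty phase input gives
  `NA` with a flag.
* Timestamps survive the CSV round trip bit-identically (shortest
  round-trip representation on write, correctly rounded `strtod` on read);
  LFP samples are stored as little-endian float32.
* Null calibration in the test suite uses 200 cells × 100 shuffles for
  spatial information (the 5% ± 2% band at 200 cells is wide by design)
  and 400 units for the phase-locking false-positive rate, where the
  ±2-point band then spans ~2.9 binomial standard errors. Sessions are
  20 minutes for spatial/band recovery and 10 minutes for phase
  calibration; these sizes give stable statistics while keeping the full
  suite fast.
* The deposited recordings of the original study are an optional benchmark:
  they are not redistributable with the package, so the corresponding
  acceptance test documents the requirement and fails informatively when
  the data are absent.

## A worked example

```{r, fig.width = 5, fig.height = 4}
tr <- simulate_trajectory(600, seed = 1)
sp <- simulate_place_cell(tr, center = c(30, 60), width = 10,
                          peak_rate = 10, baseline_rate = 0.1, seed = 2)
m <- build_rate_map(sp, tr)
glance(m)
stability_score(sp, tr)
autoplot(m)
```
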