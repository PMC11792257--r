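---
title: "Model-based spectral analysis of closed-loop cardiorespiratory and cardiovascular coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based spectral analysis of closed-loop cardiorespiratory and cardiovascular coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ck2coh)
```

## The problem

Heart period (HP, the interval between consecutive ECG R-wave peaks),
systolic arterial pressure (SAP) and respiration (RESP) interact in closed
loops. Respiration modulates HP within the same beat (respiratory sinus
arrhythmia, RSA), while the heart can in turn influence respiratory timing
one beat later; SAP drives HP within the beat through the cardiac arm of the
baroreflex, while HP feeds back on the next systolic value through
ventricular filling and diastolic runoff (the mechanical feedforward).
Symmetric association measures such as the squared coherence K² cannot
attribute an observed HP–RESP or HP–SAP association to one arm of the loop.
This package implements the directional alternative: the causal squared
coherence CK², computed from a bivariate autoregressive (BAR) model of the
beat-to-beat series pair, together with the full pipeline around it —
beat-series extraction from raw 400 Hz recordings, univariate autoregressive
spectral markers, and an IAAFT-surrogate test of the uncoupling null.

## The model

Each series pair is normalised (linear detrend, then scaling to zero mean
and unit variance) and described by a two-channel autoregression with
direction-specific latencies,

$$ y(n) = \sum_{k=1}^{p} a_{yy}(k)\, y(n-k) + \sum_{k=k_{xy}}^{p} a_{yx}(k)\, x(n-k) + w_y(n), $$

and symmetrically for $x(n)$ with minimum cross lag $k_{yx}$. The latency
pair encodes the physiology: RESP and SAP act on HP at lag 0 (within the
current beat), HP acts back at lag 1. At most one direction may be
instantaneous; because the lag-0 dependence is modelled explicitly by a
regression coefficient, the innovation covariance is taken diagonal. Each
equation is estimated by least squares via a Cholesky factorisation of its
normal equations (with a pivoted fallback if the Gram matrix condition
exceeds $10^{12}$), and one common order $p \in [5, 14]$ is selected by the
multivariate Akaike figure of merit $N \log(\lambda_x \lambda_y) + 2\,
n_\mathrm{coef}$, evaluated on the common sample aligned at the maximum
candidate order so all candidates see the same data.

From the fitted coefficients the cross-spectral matrix is
$S(f) = H(f) \Lambda H(f)^{H}$ with $H(f) = [I - A(f)]^{-1}$, and

$$ K^2(f) = \frac{|S_{12}(f)|^2}{S_{11}(f) S_{22}(f)} \in [0, 1]. $$

The causal squared coherence in the direction $x \to y$ is the same ratio
evaluated on a modified model in which every cross-regression coefficient of
the reverse pathway ($y \to x$, i.e. the lags of $y$ in the equation of
$x$) is forced to zero, all other coefficients and the innovation variances
being retained. When the reverse pathway is already absent, CK² coincides
with K² exactly; when both pathways are silenced the coherence vanishes.
Markers are band averages of these functions in the LF (0.04–0.15 Hz) and
HF (0.15–0.4 Hz) bands.

### Frequency axis

All spectral computation lives in the beat domain (cycles/beat, grid of
1025 uniform points on $[0, 0.5]$). Conversion to Hz divides by the mean
heart period of the analysed segment in seconds; band membership uses the
closed-open rule $[f_{lo}, f_{hi})$, so 0.15 Hz belongs to HF only. Band
averages are arithmetic means over the grid points falling in the band — a
deliberate choice over power weighting, since the coherence is already a
normalised quantity.

## Univariate markers

Time-domain markers are the mean and the population (divide-by-$n$)
variance, the convention consistent with the biased autocorrelation
estimate used in fitting. Each series is linearly detrended and fitted by a
univariate AR model via the Levinson–Durbin recursion on the biased
autocorrelation (which guarantees a stable model); the order minimises
$n \log \sigma^2_w + 2p$ over 8–14. The power spectral density is factorised
into one component per real pole or complex-conjugate pole pair, with the
component power obtained from the residue of $S(z)/z$ at the pole: the
signed residue powers sum to the modelled variance exactly. Components with
numerically negative residue power (near-cancelling poles) are clipped at
zero for marker purposes and flagged; a warning is raised only when the
clipped mass exceeds 1% of the variance. Real poles map to 0 Hz (positive)
or the beat-domain Nyquist (negative) and therefore never contribute to LF
or HF powers. The respiratory rate is the central frequency of the
largest-power HF component of the RESP series (ties broken towards the
lower frequency), in breaths/min.

## Surrogate test of uncoupling

The significance of a band marker is assessed against surrogate pairs that
keep each channel's value distribution exactly and its amplitude spectrum
approximately, but destroy the cross-correlation. The IAAFT procedure
starts from a phase-randomised copy (conjugate-symmetric phases uniform on
$[0, 2\pi)$) and alternates spectrum adjustment (reimpose the original
amplitude spectrum) with amplitude adjustment (rank-remap onto the original
values) for 100 iterations, ending on the amplitude step so distribution
exactness always wins. Using two different phase seeds for the two channels
makes the pair uncoupled. For each original pair, 100 surrogate pairs are
generated; the marker is recomputed on every pair with the full
identification pipeline (detrending, normalisation and — by default —
order selection re-run per pair; freezing the original order is available
as an option), and the null hypothesis of uncoupling is rejected when the
original marker lies strictly above the nearest-rank 95th percentile of
the null distribution. Note that with $N$ null values the strict
nearest-rank rule has an exchangeability rejection probability of
$\lfloor N(1 - q) \rfloor + 1$ over $N + 1$ rather than exactly $1 - q$
(about 0.059 for $N = 100$ at the 95th percentile) — the empirical size
checks in the test suite account for this.

Unstable surrogate fits are dropped from the null; if they exceed 20% of
the pairs the test aborts with an "unreliable null" error rather than
returning a distorted threshold. All surrogate seeds derive
deterministically from a single master seed, so a test result — including
every null value — reproduces exactly.

## The synthetic bench

No recordings ship with the package; every validation runs on
seed-deterministic generators whose directional coupling is known by
construction.

* `simulate_coupled_pair()` drives a first-order autoregression $y$ from a
  narrow-band AR(2) source $x$ (pole modulus 0.9 at the respiratory or LF
  rhythm) with a lag-0 gain, plus an optional lag-1 reverse gain. The
  exported five-point gain ladder (0.1, 0.25, 0.5, 1, 2) is the fixture
  shared by the recovery and statistical-power validations.
* `simulate_subject()` produces the trivariate closed loop: RESP is an
  autonomous narrow-band oscillator (weakly fed back from HP at lag 1),
  SAP carries a Mayer-wave-like LF resonance (pole modulus 0.85 at 0.1 Hz)
  and receives HP at lag 1, and HP is driven by RESP and SAP at lag 0.
  Channels are rescaled to the configured means and variances
  (defaults: HP 884 ms, variance 749 ms²; SAP 138 mmHg, variance
  28.5 mmHg²; breathing near 0.268 Hz ≈ 16 breaths/min at rest — values
  typical of a supine adult cohort), with a small white measurement noise
  on RESP only.
* `simulate_raw_signals()` synthesises 400 Hz waveforms from a beat series
  (template QRS train, per-beat half-sine pressure pulses whose maxima
  equal the SAP values, a spline through the RESP values, and a 0.5 s
  baseline lead-in so the first QRS is complete), giving the extraction
  stage a round-trip ground truth.

Preset families encode the two study regimes. `HEALTHY_REST` →
`HEALTHY_STAND` lowers the RSA gain (1.2 → 0.35), raises the baroreflex
gain (0.3 → 1.0), shortens the mean HP (884 → 798 ms) and slightly raises
the breathing rate — the expected orthostatic response. The `COVID_*`
presets keep all coupling gains fixed across conditions while still showing
the haemodynamic response (tachycardia, SAP rise): a blunted autonomic
response on top of a normal operating-point shift. The mechanical
feedforward gain is negative (a longer interval lowers the next systolic
value via diastolic runoff); with a positive sign the engaged-baroreflex
loop would be unstable, and the coherence markers are insensitive to the
sign. Generator stability is verified at construction from the companion
matrix of the reduced form, and unstable configurations are refused.

Two deliberate simplifications matter when reading test results. First,
because STAND changes the mean HP, the band geometry in the beat domain
changes even when the coupling gains do not; the `COVID_*` paired
differences are therefore centred near zero but not exactly zero, and the
no-change property is asserted through the median absolute paired
difference (< 0.1) rather than a sign test. Second, synthetic SAP variance
splits only between the LF oscillator and the HP feedback (measurement
noise is confined to RESP), so the LF share of SAP power is higher than in
typical real recordings; the HP-side magnitudes (total variance, HF power
of order 10² ms², respiratory rate near 16 breaths/min) are the regime the
generator is calibrated to.

What passing these tests shows — and what it does not: the pipeline
recovers directional coupling, holds its nominal type-I error and conserves
spectral power *on data generated by low-order linear Gaussian loops*. Real
cardiovascular series add nonstationarity, nonlinearity, ectopy and
measurement artefacts that the generators only touch through the
out-of-range repair path; conclusions about real data always need the
surrogate test, not the generator benchmarks.

## Numerical and design choices

* Biased (divide-by-$n$) autocovariance everywhere: trades a small bias for
  guaranteed positive-definiteness and model stability.
* Order selection on a common sample (aligned at the maximum candidate
  order), then re-estimation of the selected order on all usable rows.
* One BAR order per pair and condition, shared by both CK² directions —
  both derive from the single fitted model, and orders are selected
  independently per condition.
* 256-beat segments, chosen uniformly at random from the repaired series
  with a fixed seed (power-of-two friendly for the FFT-based surrogates;
  longer series are accepted but slower).
* HP validity range 300–2000 ms by default; out-of-range beats are repaired
  by linear interpolation over the beat index between the nearest in-range
  neighbours (edge beats take the nearest in-range value), with SAP and
  RESP interpolated at the same beats. More than 5% interpolated beats sets
  a warning flag rather than failing: it marks a quality concern, not an
  impossibility.
* R-peak detection: adaptive threshold at 0.4 of the running 2 s maximum of
  the positive ECG derivative (floored at 10% of its global maximum),
  refined to the raw-ECG argmax within 100 ms, 250 ms refractory. The
  refinement makes detection robust to QRS amplitude changes.
* Coherence values are analytically confined to $[0,1]$; the implementation
  refuses to mask violations beyond $10^{-9}$ (they would indicate a real
  defect) and clips only rounding-level excursions.

## Validation problem sizes

The test suite exercises: power conservation on 100 random stable AR(8–14)
models against dense PSD integration (relative tolerance $10^{-6}$);
Levinson–Durbin against a direct Toeplitz solve on 50 series ($10^{-8}$);
bound/symmetry fuzzing on 200 random stable BAR fits; directional recovery
and reverse-direction leakage over 200 seeds at the ladder top; empirical
test size over 500 uncoupling tests of 100 surrogate pairs each; power over
200 tests at the ladder top; beat-level round trips over 50 seeds; and a
40-subject paired REST/STAND contrast for both preset families. The
acceptance script (`scripts/acceptance.R`) recomputes the headline
quantities from scratch at comparable sizes.

## Known limitations

* Pairs only: the trivariate loop is simulated but analysed pairwise, so
  common-drive effects (e.g. respiration reaching both HP and SAP) are not
  partialled out.
* Linear Gaussian modelling: nonlinear or amplitude-asymmetric coupling is
  visible to CK² only through its linear signature.
* The IAAFT null preserves each channel's sampled periodogram; for strongly
  coupled narrow-band pairs the surrogate null sits slightly above the
  independent-realisation floor (both surrogates inherit the same shared
  rhythm), which makes the test marginally conservative in exactly the
  cases where coupling is obvious.
* No arrhythmia handling beyond out-of-range repair, and no respiratory
  signal derived from the ECG.
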