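---
title: "Separating periodic and aperiodic EEG dynamics: models, choices, and validation"
author: "specsift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating periodic and aperiodic EEG dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Task EEG power spectra are a superposition of two very different signals:
narrow-band oscillations (alpha, beta, sometimes theta) and a broadband
aperiodic background whose power falls off as $1/f^{\chi}$. In
time-frequency analyses the aperiodic background is usually treated as a
static floor and removed by baseline correction. In continuous paradigms
such as the n-back this assumption fails: the aperiodic exponent $\chi$
itself changes within a trial. When it does, baseline-corrected
time-frequency maps show an apparent post-stimulus *increase in
low-frequency power* that is easily read as a theta oscillation, even
though nothing oscillates. specsift implements the full analysis chain
needed to make, test, and guard against that misreading.

## The spectral model

A power spectrum over frequencies $F$ (here 3--50 Hz) is modeled in
semi-log space (only power is log-transformed) as the sum of an aperiodic
component and Gaussian peaks:

$$\log_{10} P(F) \;=\; \underbrace{b - \chi \log_{10} F}_{\text{aperiodic}}
\;+\; \sum_k a_k \exp\!\left(\frac{-(F - c_k)^2}{2 w_k^2}\right),$$

with offset $b$ (log10-power units), exponent $\chi \ge 0$ (the log-log
slope is $-\chi$; a *steeper* slope means a *larger* exponent), and peaks
described by center $c_k$ (Hz), power above the aperiodic fit $a_k$, and
Gaussian SD $w_k$ (reported bandwidth $= 2 w_k$). The knee parameter of
more general formulations is fixed at zero: over 3--50 Hz scalp EEG
spectra are adequately linear in log-log space. The logarithm base is 10
throughout, consistent with decibel displays.

Fitting (`fitSpectrum()`) follows the standard spectral-parameterization
algorithm:

1. **Robust aperiodic fit** (`robustAperiodicFit()`): an initial line fit
   in $\log_{10} F$, residuals clipped at zero, and a refit restricted to
   frequencies at or below the 2.5th percentile of the clipped residuals
   — in effect all points on or below the initial line, which masks out
   peak regions.
2. **Iterative peak extraction** (`extractPeaks()`): repeatedly take the
   maximum of the flattened spectrum; stop when it drops below
   `max(2 SD of the flattened spectrum, 0)`; estimate the Gaussian SD
   from the half-height width (clipped to half the 0.5--12 Hz bandwidth
   limits); *drop* candidates whose center is within 1 estimated SD of a
   range edge (their Gaussian is still subtracted before continuing);
   drop the smaller of two overlapping candidates; finally refit all
   retained Gaussians jointly by bounded least squares (L-BFGS-B with
   analytic gradients).
3. **Aperiodic refit** on the peak-subtracted spectrum, and iteration of
   steps 2--3 until the aperiodic parameters are stationary (at most 10
   cycles, with an early stop when the change stalls at the noise
   level). A single pass leaves a small bias in both the aperiodic and
   the peak parameters whenever peaks are present, because the peaks were
   fitted against a slightly contaminated aperiodic estimate; iterating
   to the fixed point removes it — on noiseless in-model spectra the true
   parameters *are* the fixed point, and recovery reaches optimizer
   tolerance (median error $\sim 10^{-6}$ over random draws).

Two caveats that the validation studies make explicit. First, a broad,
low peak riding on a steep background is weakly identified: the model
fits essentially perfectly while peak and aperiodic parameters trade off
against each other, so good fit metrics (R², mean absolute error) do not
guarantee accurate parameters. Second, peaks at the edge of the fitted
range (e.g. a true 3 Hz peak on a 3--50 Hz range) are *dropped by design*
(`bwStdEdge`), so their power is absorbed by the aperiodic component and
inflates the exponent — `edgeFailureStudy()` reproduces this failure mode
(detection < 10% at 3 Hz with a positive exponent bias, > 95% at 10 Hz).
Low-frequency conclusions should therefore never rest on the spectral
decomposition alone, which is why the rhythmicity module exists.

## Time-frequency front end

`tfrEpochs()` decomposes single trials with either plain Morlet wavelets
or multiplicative superlets, averages power across the correct-response
trials of each subject-condition cell, and decimates the averaged power
to 100 Hz by subsampling (the wavelet bandwidth has already smoothed
power in time, so no extra anti-alias filter is applied). The defaults
mirror standard practice: 3--50 Hz in 1 Hz steps, base wavelet of 3
cycles, superlet order growing linearly from 1 at the lowest frequency to
20 at the highest, magnitudes combined by a geometric mean (fractional
orders enter the last wavelet with weight $o - \lfloor o \rfloor$), and
power as the squared combined magnitude — so order 1 reduces *exactly* to
Morlet power. Wavelets are unit-energy and truncated at ±3.5 temporal
SDs; samples within one wavelet half-length of an epoch edge are flagged
invalid and excluded from all downstream fitting (spectral
parameterization is restricted to −0.5 to 2 s for the same reason).

`applyBaseline()` implements the four correction variants compared in the
package's studies — decibel $10\log_{10}(P/B)$, relative change
$(P-B)/B$, normalized change $(P-B)/(P+B)$, absolute change $P-B$ — with
the baseline $B$ the arithmetic time-mean per channel and frequency over
a pre-stimulus window (−0.5 to −0.2 s by default; −0.3–0 and −0.5–0 s are
the conventional alternatives). Baselines are per subject-condition cell.

## Rhythmicity (pACF)

The phase autocorrelation function quantifies how stable a signal's phase
is, independent of amplitude. From the analytic signal at frequency $f$
(3-cycle Morlet convolution — superlets are deliberately not used here,
as mixing wavelet widths distorts phase), unit phasors of the phase
increment at lag $l$,
$z_i = \exp\{j(\varphi_i - \varphi_{i-l})\}$, are averaged in a centered
moving window of 2.5 cycles; the magnitude of that average, averaged
across lags of 1--3 cycles in 0.1-cycle steps (converted to samples by
rounding, duplicates removed), is the pACF at that timepoint. Values lie
in $[0, 1]$; the measure is *exactly* invariant to positive rescaling of
the signal. Lags start at one cycle because near-zero lags are dominated
by filter autocorrelation; the magnitude is taken after window-averaging
per lag (before averaging across lags) so that the index is real and
bounded.

## Mixed-model statistics

All inference is mass-univariate: one model per channel(-frequency)-
timepoint. Two model families are used:

* **Correlation maps** (`massUnivariateR2()`): response ~ single
  predictor with random intercepts for subject *and* condition (condition
  treated as a sample from a population of conditions). The effect size
  is the marginal $R^2$,
  $\sigma_f^2 / (\sigma_f^2 + \sigma_\gamma^2 + \sigma_\alpha^2 +
  \sigma_\varepsilon^2)$, where $\sigma_f^2$ is the variance of the
  fixed-effect predictions; its sign is taken from the predictor's
  coefficient.
* **Condition comparisons** (`massUnivariateConditions()`):
  `y ~ 1 + modality * load * stimulus + rt + (1 | subject)` with
  sum-to-zero contrasts (so main effects remain interpretable under the
  full interaction model) and the cell-level ex-Gaussian $\mu$ as the
  mean-centered reaction-time covariate.

Models are fitted by maximum likelihood with the variance ratios
profiled: a closed-form group-sum path for a single random intercept and
a Cholesky path for crossed intercepts. Satterthwaite denominator degrees
of freedom come from the delta method on the coefficient variance as a
function of the variance components, with the asymptotic covariance of
the variance components taken from the finite-difference Hessian of the
ML negative log-likelihood; components estimated at the zero boundary are
held fixed. The test suite verifies exact agreement (estimates, variance
components, log-likelihood, Satterthwaite SE/df/p) with lme4/lmerTest on
reference problems; the native fitter exists because mass-univariate maps
need tens of thousands of fits per run.

Multiplicity is handled by Benjamini–Yekutieli FDR (valid under arbitrary
dependence; `stats::p.adjust` supplies the step-up, and the test suite
checks it against a brute-force implementation of the definition) at
$q = 0.05$ per term map, followed by a cluster-extent rule: a significant
point is kept only if it sits in a run of ≥ 3 consecutive significant
timepoints at its channel or ≥ 3 channels are simultaneously significant
at its timepoint (same frequency). Channels are counted without a spatial
adjacency requirement, since no sensor geometry is assumed. p-value maps
are never averaged before inference; averaging is for display only.

Reaction times are summarized per subject-condition cell by the
ex-Gaussian $\mu$ (approximately the distribution mode): after removing
within-cell $|z| > 3$ outliers and anticipations below 200 ms, the
ex-Gaussian (Normal + Exponential) is fitted by maximum likelihood with
moment-based starting values; $\sigma$ and $\tau$ are estimated but not
used downstream.

## The synthetic-data generator

`simulateEpochs()` builds multi-subject, multi-condition single-trial
EEG from known ground truth, which is what makes every stage testable:

* **Aperiodic track**: short-time inverse-FFT synthesis — 1 s windows at
  50% overlap filled with the target amplitude spectrum
  $10^{(b - \chi \log_{10} f)/2}$ and uniform random phases, weighted by
  square-root-Hann windows (whose *squares* overlap-add to one, keeping
  synthesized power stationary across seams) and summed. The window-grid
  origin is jittered per realization so seam structure does not sit at
  fixed epoch positions across trials. Exponent events are
  Gaussian-in-time bumps with per-channel-group weights and per-condition
  multipliers; each event rotates the spectrum about a pivot frequency
  (default 20 Hz, i.e. $\Delta b = \Delta\chi \log_{10} 20$), matching
  the empirical observation that offset and exponent co-vary — a pure
  tilt about 1 Hz would *decrease* 3–7 Hz power and is available by
  setting `pivotHz = 0`.
* **Oscillations**: sinusoids with uniform-random phase per trial
  (induced activity), an amplitude envelope that ramps down by the
  suppression depth over the suppression interval, and per-channel-group
  weights. Default amplitudes (0.3 for alpha at 10 Hz, 0.15 for beta at
  20 Hz, against an aperiodic track of SD ≈ 0.23) give fitted peak
  heights around 0.5–1.3 log10 units, the realistic range.
* **ERP**: a Gaussian bump added *identically* to every trial
  (phase-locked by construction), which is what the ERP-subtraction
  control relies on to distinguish evoked from induced power.
* **Between-subject variation** of $b_0$ and $\chi_0$, white sensor
  noise, and per-cell ex-Gaussian reaction times (defaults
  $\mu = 0.5$, $\sigma = 0.05$, $\tau = 0.15$ s).

One master seed deterministically spawns per-subject / per-trial /
per-channel substreams, so identical specs reproduce bit-identical data.
Default study conditions: 20 subjects, 2×2×2 conditions, 30 trials per
cell, 4 channels with frontal/parietal/occipital group weights, 200 Hz
sampling (an integer multiple of the 100 Hz analysis rate), epochs −1.5
to 2.8 s, $\chi_0 = 1$, $b_0 = 0$, exponent events at 0.3 s (frontal)
and 0.7 s (parietal).

What the generator does *not* emulate: electrode geometry and volume
conduction, artifacts (blinks, muscle), non-sinusoidal waveform shape,
and trial-to-trial amplitude variability of oscillations. Passing tests
therefore show that the algorithms are correct on data obeying the
generative model, not that real recordings obey it.

## Validation studies

The exported study functions recompute the package's headline results
from scratch (they also back `scripts/acceptance.R`):

* `spectralRecoveryStudy()` — parameter recovery over random in-model
  spectra, noiseless and with 0.05 log-power noise.
* `edgeFailureStudy()` — the documented edge-peak failure mode.
* `misattributionStudy()` — the central demonstration: 20 subjects × 2
  conditions × 30 trials × 4 channels whose *only* post-stimulus change
  is a $\Delta\chi = 0.3$ exponent increase during 0.2–0.8 s produce a
  clear (> +0.2 dB, typically ≈ +1 dB) decibel-baseline-corrected
  increase at 3–7 Hz while the reconstructed periodic component stays
  flat (|change| < 0.05 log10 units); with a suppressed alpha
  oscillation added, both representations show the alpha decrease.
  Spectral fitting uses every 5th timepoint of the 100 Hz maps (band
  means over 0.6 s windows are unaffected by a 50 ms grid).
* `rhythmicityContrastStudy()` — across channels varying alpha amplitude
  (with exponent varying independently and the offset pivoted at 10 Hz
  so aperiodic power there is constant), periodic 10 Hz power correlates
  with pACF at $r > 0.7$ while the exponent does not ($|r| < 0.2$).
* `conditionPowerStudy()` — power/type-I Monte Carlo for the full
  statistics chain on exponent maps (4 channels × 26 timepoints, noise
  SD 0.1 and subject SD 0.15, matching what the estimation stage
  delivers at ~30 trials): a planted stimulus-type difference of 0.2 is
  detected (cluster-filtered) in ≥ 80% of replicates, null replicates
  show any detection in ≤ 10%. Simulating at the map level keeps 100
  replicates affordable on one CPU; the misattribution study covers the
  signal-level half of the chain.
* `exgaussRecoveryStudy()` — $\mu$ recovery at n = 1000.

## Numerical choices and degenerate inputs

* Peak SD bounds are half the 0.5–12 Hz *bandwidth* limits; candidate
  centers are bounded within ±2 estimated SDs in the joint refit.
* Fits that fail (non-positive power, optimizer error) yield NA maps with
  a warning once more than 5% of fits fail — never silent zeros, which
  would bias the mixed models.
* `fitLMM()` profiles $\log \lambda$ on $[-16, 12]$; a variance
  component at the lower bound reproduces OLS to ~$10^{-6}$ and its
  Satterthwaite df degrade gracefully to the classical values.
* Ratio baselines refuse non-positive baseline power, naming the
  channel/frequency; the baseline window must lie inside the
  edge-valid region.
* pACF timepoints whose window or maximal lag leaves the signal are NA,
  and lags that collide after rounding are deduplicated (relevant at
  high frequency and low sampling rate).
* Containers are versioned; truncated or foreign files raise a schema
  error rather than crashing, and newer minor versions round-trip with
  extras preserved.

## Limitations

The aperiodic generator controls the *spectrum* of the synthetic track,
not its waveform statistics; the per-window constant-amplitude synthesis
has sub-Rayleigh amplitude fluctuations within a window. Exponent maps
estimated from ~30 trials carry temporal noise of SD ≈ 0.05–0.1, which
bounds how subtle a planted exponent event can be and still be detected.
The LMM fitter supports at most two crossed random intercepts and no
random slopes — exactly the structures the analysis uses. REML is not
offered (maximum likelihood is used throughout), and no permutation-based
cluster statistics are provided.
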