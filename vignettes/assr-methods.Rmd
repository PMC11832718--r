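---
title: "Methods: 40 Hz ASSR analysis with assrpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 40 Hz ASSR analysis with assrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assrpipe)
```

## The scientific problem

A 40 Hz amplitude-modulated tone entrains cortical oscillations at the
modulation frequency — the auditory steady-state response (ASSR). How
strongly, how quickly and how consistently a brain entrains carries
information about the integrity of the underlying networks, and changes
in these features have been linked to cognitive decline. `assrpipe`
implements a complete analysis chain for such experiments: from raw
multichannel EEG through a single per-subject entrainment component,
envelope and phase-coherence profiles, a five-parameter response-curve
fit, and a cohort-level inferential layer relating the fitted features
to cognition and executive-function scores.

The protocol assumed throughout is 40 stimulation trials of 6 s each,
separated by 5 s silent intervals (a 435 s session), recorded on 64
channels in the 10-20 layout and analysed at 250 Hz.

## Preprocessing

Raw recordings are re-referenced to the common average, resampled to
250 Hz (anti-alias filtered before decimation), bandpass filtered to
0.5–90 Hz with an order-18 Chebyshev type-II IIR filter, notch filtered
at 50 Hz (order 8), epoched over a half-open window of [−1 s, 6 s)
around each stimulus onset, and baseline corrected by subtracting the
per-epoch, per-channel mean over (−0.5 s, −0.25 s).

Two numerical choices deserve note:

* **Second-order sections.** An order-18 IIR bandpass is numerically
  unstable as a single transfer-function polynomial in double
  precision (we measured poles at radius 1.0027 after polynomial
  expansion). All filters are therefore designed in zero-pole-gain form
  and realized as cascaded biquads; the design is validated in the test
  suite against an independent transfer-function implementation at low
  order.
* **Stopband attenuation.** The filter orders are part of the method
  definition; the type-II stopband depth is a free design parameter and
  defaults to 40 dB (60 dB for the anti-alias lowpass).

Component-based artifact removal requires an externally trained
classifier and is out of scope; `artifact_clean_hook()` accepts a
user-supplied cleaning function and otherwise passes data through.

## RESS spatial filtering

Rhythmic entrainment source separation reduces the channel dimension to
one component that maximizes 40 Hz power relative to the neighbouring
spectrum. Per trial, each channel is narrowband filtered by spectral
Gaussians — FWHM 0.5 Hz at 40 Hz for the signal covariance `S`, and
FWHM 1 Hz at 39 and 41 Hz for the reference covariance `R` — over the
6 s stimulation window, and per-trial covariances are averaged across
trials (covariance first, averaging second). The spatial filters are
the generalized eigenvectors of `S v = lambda R v`.

Numerical choices:

* `R` is shrunk towards a scaled identity,
  `(1 - gamma) R + gamma mean(diag(R)) I` with `gamma = 0.01`, because
  0.5 Hz-wide filtered data can make `R` nearly rank deficient.
* The generalized problem is solved through the Cholesky factor of the
  regularized `R` (never by explicit inversion), which is the
  numerically stable equivalent of eigendecomposing `R^{-1} S`.
* Each covariance is divided by its filter's equivalent noise
  bandwidth. This scalar normalization leaves the eigenvectors
  untouched but puts `S` and `R` on a per-Hz scale, so spectrally flat
  noise gives a flat eigenvalue spectrum and the eigenvalues read as
  per-Hz power ratios.
* Eigenvector signs are arbitrary in a generalized eigenproblem; the
  convention here makes each vector's largest-magnitude element
  positive. Eigenvectors are *not* orthogonal and the code never
  assumes they are.

One filter is estimated per subject from all trials jointly and applied
to every trial, yielding single-channel epochs. The component's quality
is summarized by an SNR spectrum: power at the 40 Hz FFT bin divided by
the mean flanking power within ±2 Hz, excluding ±0.5 Hz.

## Complex demodulation

The component is narrowband filtered (Chebyshev type-II bandpass with
corner frequencies 39.5 and 40.5 Hz), multiplied by
`exp(-i 2 pi 40 t)`, and lowpass filtered at 2 Hz, producing a complex
series `z(t)` whose modulus and argument estimate the instantaneous
envelope (`2|z| ~ A(t)`) and phase. Two profiles summarize the trials:
the amplitude modulation `AM(t)` (trial mean of `2|z|`, baseline
subtracted) and the inter-trial phase coherence `ITPC(t)` (resultant
length of the across-trial unit phasors, baseline subtracted; bounded
by [0, 1] before subtraction).

Numerical choices, each of which measurably mattered:

* **Bandpass order 12.** The corner frequencies define a 1 Hz design
  band, but how much of it is usable passband depends on the order. At
  order 8 the realized two-pass passband is only about ±0.2 Hz: the
  envelope is smeared over roughly two seconds and stimulus-onset
  energy bleeds backwards into the pre-stimulus baseline (on synthetic
  data the baseline phase coherence rose to ~0.9). Order 12 keeps the
  transition inside the design band. The lowpass is order 6.
* **Carrier-coherent edge padding.** Zero-phase filtering needs edge
  extension, and generic odd reflection phase-conjugates the 40 Hz
  carrier at the boundary. A 1 Hz-wide filter rings for seconds off
  that discontinuity; we measured envelope errors of 5–10 % across the
  whole epoch for a constant tone. Each epoch is instead extended by a
  constant-envelope 40 Hz continuation matched in amplitude and phase
  to the data edge, held for 1 s, then tapered by a raised cosine over
  the remaining 4 s of the pad — long enough that the taper's spectral
  footprint stays inside the passband. This reduced the constant-tone
  envelope error to ±0.5 %.
* **Zero-modulus phasors.** Samples where `|z|` falls below 1e-12 of
  the series maximum are excluded from the phasor average (this only
  ever matters for silent synthetic inputs); a time point with no valid
  trial is carried as missing and excluded from curve fits.
* **Baselines.** The profile baselines reuse the epoching baseline
  window (−0.5, −0.25) s and are subtracted after trial averaging.

Average ASSR band power is the per-epoch power in 40 ± 0.5 Hz over the
stimulation window (periodogram-bin sum scaled so a sine of amplitude
`a` gives `a^2/2`), averaged over epochs; evaluated per channel it
yields the 40 Hz scalp topography. Time-frequency maps for export use a
Hann-windowed STFT (0.5 s window, 90 % overlap); the evoked spectral
perturbation is the trial-mean squared modulus, optionally resampled to
a 224 × 224 grid for image classifiers.

## The MCGF response curve

Both profiles are summarized by the modified cumulative Gaussian
function

$$\mathrm{MCGF}(t) = \frac{A d}{d+1} e^{\mu\alpha + 0.5\sigma^2\alpha^2 - \alpha t}
G(t;\,\mu+\sigma^2\alpha,\,\sigma) + \frac{A}{d+1} G(t;\,\mu,\,\sigma),$$

with magnitude `A`, latency `mu` (s), slope `sigma` (s), decay `alpha`
(1/s) and term ratio `d`. The curve rises around `mu` and, for
`alpha > 0`, relaxes towards the asymptote `A/(d+1)`. Fits use
Levenberg-Marquardt least squares over the window 0–5 s with pre-onset
target forced to zero, deterministic data-driven starting values
(window maximum, first half-maximum crossing, `sigma = 0.2` s,
`d = 1`, `alpha = 0.05`), box bounds that keep the exponential term
finite (`mu` in the window, `sigma <= 5` s, `alpha <= 5` 1/s,
`d` in [1e-3, 1e3]), and log-space evaluation of the decaying term.
Because the residual surface is multi-modal in `(d, alpha)` — a
decaying-pulse regime and a sustained regime can both fit locally — the
optimizer always restarts from five fixed multiplicative perturbations
and keeps the lowest-residual solution, reporting an honest convergence
flag. AM and ITPC are fitted independently.

## Inferential layer

The IQ index is z-scored; SOC mean moves for 4-move problems enters as
its reciprocal; SOC problems solved in minimum moves enters as
`log(max - SOCprob)` reflected against the sample maximum. Since the
sample maximum is by construction attained by at least one subject, the
offset-free reflection always hits `log(0)`; the transform therefore
falls back to a half-count offset of 0.5 with a warning, and an
explicit instrument maximum (12) may be supplied instead. Exact
back-transforms are provided for interpretation.

All three models share one design: a global intercept; main effects of
the AM and ITPC decays and slopes; and, within each group
(cognitively stable `highCog` vs declining `lowCog`), an indicator plus
group-specific slopes for the AM and ITPC magnitudes, latencies, their
magnitude-by-latency products, and the average band power. The two
indicators sum to the intercept; the fitter resolves this one exact
collinearity by dropping a named column, reproducing the conventional
"global intercept plus one group intercept" table. Gaussian
identity-link least squares is used for all three responses; both the
F statistic and the likelihood-ratio chi-squared against the
intercept-only model are reported for every model, since either may be
the one of interest.

Group comparisons use the pooled-variance t test for normally
distributed scores and the Wilcoxon rank-sum test for skewed SOC
outcomes (exact enumeration when the smaller sample has at most eight
observations and no ties; normal approximation with corrections
otherwise), with a user-supplied Bonferroni family size — the family is
a scientific choice, not something the code can infer. Scalp
topographies are compared channel-wise by permutation: the statistic is
the difference of group means, the p value uses the add-one estimator
over label shuffles, and no multiplicity correction is applied because
these maps are exploratory.

## The synthetic cohort

Because the motivating data are confidential, a seeded generator
produces recordings with the statistical structure the analysis
assumes: a 40 Hz component whose envelope follows an MCGF curve within
the stimulation window, a per-trial constant phase offset drawn from a
wrapped normal distribution (its SD controls ITPC), a phenomenological
per-channel gain map, and 1/f Gaussian background noise independent
across channels. Nothing biophysical is simulated — no dipoles, no
forward model — and the auditory stimulus waveform itself (a 1 kHz
click train) is not modelled, only the entrained cortical component.

The generator's default conditions were calibrated once, before the
test suite was frozen, and are not tuning knobs:

* **Envelope timing** (`sigma = 0.35` s; latency 1.8 s for `highCog`,
  2.1 s for `lowCog`). Two constraints drove this. First, the 1 Hz
  demodulation band cannot resolve envelope features faster than a few
  hundred milliseconds, so a generator envelope must be slower than
  that to be recoverable at all. Second, the fit window starts at the
  stimulus onset: if part of the filter-smeared rise falls before 0 s
  it is truncated out of the fit, biasing the fitted latency by an
  amount that depends on the latency itself. At 1.8/2.1 s both groups
  incur the same truncation bias and a planted 0.3 s group offset is
  recovered as 0.30 s at cohort level. Envelope amplitudes are 1.0 and
  0.8 µV with `d = 1`, `alpha = 0.1`.
* **Noise level** (SD four times the envelope peak). This puts the
  single-trial in-band SNR near unity per channel, which is what
  ordinary ASSR recordings look like; it also keeps the inter-trial
  phase coherence in its informative mid-range rather than saturated.
* **Phase jitter** 0.4 rad (`highCog`) vs 0.7 rad (`lowCog`); spatial
  profiles focal-temporal vs diffuse-frontocentral, the diffuse preset
  carrying more total gain. The *directions* of all group contrasts
  (larger entrainment area, delayed assembly, higher band power in
  decliners) reflect the reported physiology; the magnitudes are free
  parameters of the generator.
* **Cognition scores** are generated on the transformed scale as
  `X beta` plus Gaussian noise using the same design the fitter uses,
  then back-transformed. SOC problems solved is rounded and clipped to
  the integer range 0–12; the continuous outcomes are kept at full
  precision so the link relations are exactly invertible, which is what
  makes noise-free coefficient recovery testable to machine precision.

What passing tests on this generator do *not* show: robustness to
artifacts (blinks, muscle, line noise beyond 50 Hz), to non-stationary
background spectra, to between-trial amplitude variability, or to
head-geometry effects — none of which are simulated.

## Problem sizes and determinism

The unit suite runs shortened sessions (4–15 trials) where the property
under test allows it; the acceptance checks run the full 40-trial
protocol for 10 + 10 subjects, 10^4-replicate null calibrations for the
two-sample tests, and 20-seed calibration of the 64-channel permutation
test. Every stochastic step is seeded: generators restore the caller's
RNG state, permutation tests take an explicit seed, and identical
configurations produce byte-identical result bundles (the pipeline
stamps every output with a configuration hash).

## Known limitations

* The demodulation chain's ~0.5–0.7 s smearing is inherent to the 1 Hz
  analysis band; fitted latencies and slopes are *effective* parameters
  of the smeared profile, not of the underlying envelope. Group
  differences are preserved; absolute values are biased by a common
  offset.
* The full interaction design has 21 columns, so the GLM stage needs
  cohorts larger than 21 subjects; the pipeline default is 12 + 12.
* With a very high-SNR synthetic signal the ITPC profile saturates
  near 1 almost immediately after onset and its latency parameter
  carries little information; the default noise level avoids this
  regime.
* `fit_glm` assumes Gaussian errors on the transformed scale; count
  outcomes near their bounds (SOC problems at 0 or 12) violate this
  mildly, exactly as they do in the original analysis.
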