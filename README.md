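# assrpipe

An R package for analysing **40 Hz auditory steady-state responses
(ASSR)** in multichannel EEG, aimed at studies that relate gamma-band
entrainment to cognition and executive function in aging cohorts.

When the brain is driven by a 40 Hz amplitude-modulated tone, cortical
oscillations entrain to the modulation frequency. How large, how fast
and how consistent that entrainment is — and how broadly it spreads
over the scalp — changes with cognitive status. `assrpipe` implements
the full analysis chain needed to quantify this:

1. **Preprocessing** — common-average reference, resampling to 250 Hz,
   zero-phase Chebyshev type-II filtering (order-18 bandpass 0.5–90 Hz,
   order-8 notch at 50 Hz, realized in second-order sections), epoching
   over [−1, 6) s around stimulus onsets, baseline correction over
   (−0.5, −0.25) s.
2. **RESS spatial filtering** — rhythmic entrainment source separation:
   the generalized eigendecomposition `S v = λ R v` of a narrowband
   signal covariance (Gaussian FWHM 0.5 Hz at 40 Hz) against the
   averaged neighbour covariances (FWHM 1 Hz at 39 and 41 Hz), giving
   one maximally-entrained component per subject.
3. **Complex demodulation** — bandpass 39.5–40.5 Hz, frequency shift by
   `e^{-i2π40t}`, lowpass 2 Hz; trial-averaged amplitude-modulation
   profile `AM(t)` and inter-trial phase coherence `ITPC(t)`, plus
   average 40 Hz band power, scalp topographies and ERSP maps.
4. **MCGF fitting** — both profiles are summarized by the
   five-parameter modified cumulative Gaussian

   ```
   MCGF(t) = A·d/(d+1) · e^{μα + 0.5σ²α² − αt} · G(t; μ+σ²α, σ)
           + A/(d+1)   · G(t; μ, σ)
   ```

   with magnitude `A`, latency `μ`, slope `σ`, decay `α` and term
   ratio `d`, fitted by bounded Levenberg-Marquardt over 0–5 s.
5. **Statistics** — Gaussian GLMs with group-interaction designs
   linking the fitted features (and band power) to an IQ index and
   Stockings-of-Cambridge planning outcomes via declared response
   transforms; two-sample t and Wilcoxon rank-sum tests with
   Bonferroni thresholds; channel-wise permutation tests on
   topographies.
6. **Synthetic cohort** — a seeded generator producing recordings (40
   trials × 6 s stimulation, 5 s inter-trial interval, 435 s sessions)
   with MCGF-shaped 40 Hz components, wrapped-normal phase jitter,
   group-dependent spatial gain maps and 1/f noise, plus cognition
   tables generated from the same GLM relations the fitter estimates —
   so the entire pipeline is testable end to end without any
   confidential data.

## Worked example

```r
library(assrpipe)

tl  <- make_session_timeline(40, 6, 5)      # 40 trials, 6 s stim, 5 s ITI
cfg <- group_synth_config("highCog", seed = 42)
ep  <- simulate_assr_epochs(cfg, tl)        # 40 x 14 x 1750 epochs
rr  <- ress(ep)                             # spatial filter + component
prof <- modulation_profile(complex_demodulate(rr$component))
fit  <- fit_mcgf(prof, "am")                # five-parameter curve fit
print(rr)
print(fit)
assr_bandpower(rr$component)
```

```
Session: 40 trials, total 435 s
<assr_epochs> 40 epochs x 14 channels x 1750 samples @ 250 Hz, window [-1, 6) s
<ress_result> 14 channels, top eigenvalue 56.9, SNR 147
<mcgf_fit> A=2.656 d=1000 mu=1.98 s sigma=0.5669 s alpha=0.1295 1/s | rss=3.82 r2=0.996 converged=TRUE
Average 40 Hz band power: 1.831 uV^2
```

Reading the output: the RESS component concentrates 40 Hz power about
57× above the neighbouring spectrum (eigenvalue) with an SNR of 147
against the flanking FFT bins; the amplitude-modulation profile rises
with latency `μ ≈ 2.0 s` and slope `σ ≈ 0.57 s` (both are *effective*
values after the 1 Hz demodulation band smears the envelope — this
subject's generator latency was 1.8 s), and the fit explains 99.6 % of
the profile variance. The band power is the average 40 ± 0.5 Hz power
over the 6 s stimulation window.

A full synthetic cohort — per-subject fits, feature table, cognition
scores, three GLMs, group tests and permutation topographies — is one
call:

```r
bundle <- run_pipeline(list(n_high = 12, n_low = 12, seed = 1,
                            out_dir = "assr_out"))
bundle$glm$IQ          # coefficient table with SE, t, p, R², loglik
bundle$topo_p          # per-channel permutation p values
```

A thin command-line wrapper is installed at
`inst/scripts/assr-entrain` (verbs `simulate`, `run-all`,
`preprocess`).

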