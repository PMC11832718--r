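Package: assrpipe
Title: Analysis Pipeline for 40 Hz Auditory Steady-State Responses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing 40 Hz auditory steady-state responses
    (ASSR) in multichannel EEG: deterministic preprocessing (common-average
    re-referencing, resampling, zero-phase Chebyshev type-II filtering,
    epoching and baseline correction), rhythmic entrainment source
    separation (RESS) spatial filtering via generalized eigendecomposition,
    complex demodulation into amplitude-modulation and inter-trial
    phase-coherence profiles, five-parameter modified cumulative Gaussian
    (MCGF) profile fitting, band-power topographies with permutation tests,
    and generalized linear models linking entrainment features to
    executive-function scores. A seeded synthetic-data module generates
    recordings and cognition tables with the statistical structure the
    analysis assumes, so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
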