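Package: optoephys
Title: Analysis of Optogenetically Evoked LFP, Dopamine Photometry, and
    Closed-Loop Social Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested pipeline for dual-site local field potential (LFP)
    analysis during rhythmic optogenetic stimulation: Chebyshev band-pass
    filtering, short-time Fourier spectrograms with line-noise removal and
    two-stage outlier rejection, stimulation-evoked band-power ratios with a
    group inclusion screen, Morse-wavelet visualization, and phase-locking
    value (PLV) and imaginary PLV coherence normalized to pre-stimulation
    baseline. Companion modules process dopamine-sensor (dF/F) trial data
    (quadratic detrend, baseline normalization, per-second binning) and score
    closed-loop three-chamber social-preference sessions (interaction-zone
    occupancy, preference and normalized preference scores). A synthetic-data
    generator produces LFP, photometry, and trajectory inputs with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
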