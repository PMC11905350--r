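---
title: "Methods: evoked LFP power, phase coherence, dopamine trials, and closed-loop preference scoring"
author: "optoephys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evoked LFP power, phase coherence, dopamine trials, and closed-loop preference scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optoephys)
```

This vignette documents the models, conventions and numerical choices
behind each processing stage, what the synthetic-data generators emulate
(and do not), and the design decisions that were genuinely open. It states
no empirical result beyond what the package's tests and acceptance script
compute.

## 1. LFP preprocessing

**Filtering.** Wide-band conditioning uses a Chebyshev Type II band-pass
(order 4, 40 dB stopband attenuation) applied forward and backward with
`signal::filtfilt`, giving zero phase distortion — essential because all
downstream phase measures assume no filter-induced lag. The defaults are
1–250 Hz; narrowband phase extraction (below) uses order 2 for its
2 Hz-wide bands, where an order-4 design at a 0.2% normalized bandwidth
becomes numerically fragile. Passband gain is within 1 dB of unity at band
center (asserted in tests).

**Spectrograms.** `computeSTFT()` computes a one-sided power spectral
density with a periodic Hann window. Frequency-bin spacing is exactly
`1/windowS`; the time step is `windowS * (1 - overlapFrac)`. Two
conventions coexist deliberately: 5 s windows at 50% overlap for
whole-session spectrograms, and 1 s bins at 50% overlap for
stimulation-trial analysis, where the 1 Hz grid makes the ±1 Hz
quantification band exactly 3 bins wide.

**Line noise.** Rather than notch-filtering the time series,
`removeLineNoise()` excises the 59–61 Hz bins of the spectrogram and fills
them with the nearest out-of-band bin per time bin (nearest interpolation
along frequency). This leaves all other bins bit-identical.

**Two-stage outlier rejection.** Stage 1 screens the mean power across
frequencies per time bin and flags values above mean + 4 SD; flagged bins
are replaced column-wise by per-frequency medians of the clean bins, which
preserves spectral shape (a scalar replacement would not). Stage 2
re-screens the repaired series with a sliding 5 min window, one time bin
per step, flagging bins above the window median + 5 × 1.4826 × MAD. The
MAD is scaled to estimate an SD, and the threshold is one-sided high,
because spectrogram artifacts are strictly positive power excursions. A
zero-MAD (constant) window flags nothing, so silent segments are never
mass-flagged. Stage-2 replacements are forward-filled from the last clean
bin (leading bins fall back to the next clean bin), and the reported mask
is the union of both stages. All thresholds (4 SD, 5 MAD, 5 min) are
arguments with these defaults.

One ambiguity was resolved as a declared convention: whether stage-1
replacement applies to the screening series only or to the spectrogram
itself. We repair the spectrogram (per-frequency medians) so that
downstream band-power quantification also benefits; the mask records what
was touched either way. Manual verification of the cleaned series has no
computational analog; the mask and per-stage counts are the auditable
substitute.

## 2. Evoked power

Per stimulation epoch, `bandPower()` averages spectrogram power over the
closed ±1 Hz band around the drive frequency (band membership by bin
center) in the stimulation window (default 0–120 s from onset) and the
baseline window (the 30 s immediately before onset), and `powerRatio()`
reports their ratio. Results are stored both as the raw ratio and as
`ratio − 1`, so that "no change from baseline" is 0 — the convention used
for plotting evoked responses against a zero baseline.

**Inclusion screen.** Within each channel × frequency group of repeats,
repeats whose ratio deviates from the group mean by strictly more than
2 sample SDs are excluded before averaging. A mathematical point worth
knowing: with n repeats, the deviation score is bounded by
(n−1)/√n sample SDs, so the screen cannot exclude anything from groups of
3 (bound ≈ 1.15) and only begins to bite at n ≥ 7. It therefore acts as a
guard for pooled or cross-session tables rather than within-session
triplets; the group definition (within one channel, one session) and the
screened quantity (the power ratio, as the measurable proxy for a
phase-locked response) are both exposed as choices.

`presentationOrderEffect()` tabulates mean ratios by presentation position
for downstream order-effect testing; no inferential statistic is computed
here by design — standard tests (ANOVA and friends) belong to the caller.

**Morse wavelets.** `morseSpectrogram()` provides a generalized Morse
wavelet (γ = 3, β = 20, log-spaced frequencies) transform magnitude for
visualization. The wavelet pair (γ, β) gives a time-frequency compromise
suited to seconds-long evoked responses; the parameters are exposed. The
magnitude is linear in amplitude and never feeds quantification — the STFT
path does that.

## 3. Phase coherence

Instantaneous phase is the argument of the analytic signal (FFT
construction: negative frequencies zeroed, positive doubled) of the
zero-phase ±1 Hz band-passed signal. Wavelet phase would give nearly
identical narrowband results; the Hilbert route is the declared choice.

For phases φ_a, φ_b, the phase-locking value is
`PLV = |⟨exp(i(φ_a − φ_b))⟩|` and the imaginary PLV is
`iPLV = |Im⟨exp(i(φ_a − φ_b))⟩|`. iPLV discards the real part of the mean
phasor and with it all zero-lag synchrony, the signature of volume
conduction from a shared source; the noiseless identities PLV = 1 and
iPLV = |sin φ₀| for a constant lag φ₀ are asserted in the acceptance
tests, as is exact (1e−9) agreement with a brute-force phasor-averaging
oracle. Both measures are symmetric in the channels: no directionality is
estimated or implied, and none is implemented (an explicit non-goal; so are
Granger causality, phase-slope index, and magnitude-squared coherence).

Edge handling: the band-pass/Hilbert pair produces transients at the
recording edges, so 5% of samples per end are flagged — capped at 2 s,
since transients decay within roughly the reciprocal bandwidth (~0.5 s for
a 2 Hz band) and an uncapped 5% of a 30 min recording would swallow entire
baseline windows. Separately, 5% of each analysis window's samples are
trimmed per end before averaging.

`coherenceRatio()` evaluates PLV and iPLV in the same epoch-relative
stimulation and baseline windows as the power analysis and reports
stimulation/baseline ratios (1 = no change). Repeats can be restricted to
those retained by the evoked-power inclusion screen; the screen is
inherited rather than re-derived from a coherence quantity, which is the
declared reading of screening "as done for power-ratio analyses".

## 4. Dopamine photometry trials

The processing order is fixed: quadratic detrend per ROI → baseline
normalization per ROI → equal-weight ROI averaging → trial parsing. The
quadratic models photobleaching across the session; fitting it to the full
trace (not per trial) keeps the fit from chasing evoked transients.

Normalization maps the mean over the union of 5 s pre-onset windows to 1.
Because a detrended ΔF/F trace is near zero-mean, dividing by its own
baseline would be unstable; the divisor therefore comes from the raw
trace: with m the raw baseline mean and b the detrended baseline mean, the
normalized trace is `(detrended − b + m)/m`. This is invariant to positive
rescaling of the raw signal (e.g., detector gain) and anchors baseline at
exactly 1, matching a dashed-line-at-1 plotting convention. Whether
"normalized to baseline" means division, subtraction, or z-scoring was an
open call; division-to-1 is the declared choice. Reversing the order
(normalize, then detrend) re-centers the trace near zero and destroys the
baseline anchor — a regression test guards the order, and no reordering
switch is exposed.

Trials are parsed from 5 s before to 10 s after each onset (the decay tail
is kept for plotting), but quantification bins use only the 5 s
stimulation window: five 1 s bin means per trial, plus the per-trial
stimulation-window mean. Per-trial values are retained as the observations
for statistics, since dopamine depletion makes trials within a session
dependent on their position. Truncated trials at session edges are dropped
with a warning, never zero-filled.

## 5. Closed-loop behavior scoring

The arena is 71 × 30 cm with three equal-width chambers and one 8 cm
(diameter) cup centered in each outer chamber. The interaction zone is all
points within cup radius + 3 cm margin = 7 cm of a cup center — the "3 cm
beyond the cup" rule read radially. Occupancy integrates sample-and-hold:
each tracking sample represents the span to the next sample. No dwell
debounce is applied; single-sample entries count, matching a trigger that
fires on physical entry.

Closed-loop stimulation epochs are, by definition, the stimulation-side
zone intervals (laser on at entry, off at exit), so total stimulation time
equals T_S exactly — asserted, not assumed. The scores are
`PS = 100·T_S/(T_S + T_NS)` and `NS = 100·PS_T/PS_H`; on this scale 50
means equal time and 100 means testing equals habituation. Some figure
conventions elsewhere describe the same quantities on a /100 scale ("a
value of 1..."); the formulas as implemented govern, and dividing the
outputs is left to presentation code. Habituation trials are scored against
the side later assigned for stimulation in the matching testing trial,
which is what makes NS a within-animal change score. Center-chamber time
never enters PS; `chamberTimes()` reports it separately for locomotion
summaries.

`sessionProtocolCheck()` validates the four-trial structure per animal
(habituation/testing × toy-toy/toy-female, stimulation only in testing,
side assigned only there) and tallies side and session-order
counterbalancing.

## 6. Synthetic data: what it emulates, and what it does not

**LFP.** Background is 1/f^α noise (α = 1 default) built by spectral
shaping of white Gaussian noise — the canonical LFP background model.
Stimulation adds a pure sinusoid at the drive frequency (matching a
sine-wave-driven light source; a rectangular 5 ms pulse-train option
exists), phase-shifted on the second channel by a configurable lag, which
is the controllable ground truth for coherence. A configurable identical
component on both channels emulates volume conduction for iPLV validation.
Artifacts are 0.5 s oscillatory bursts (half-sine envelope on a 12 Hz
carrier): a pure sub-hertz transient would be removed by the pipeline's own
1 Hz high-pass before the spectrogram screen ever saw it, so a burst with
in-band energy is the faithful ground truth for the cleaner. The default
sampling rate is 1000 Hz — a declared default, not an inferred one; all
analysis code takes the rate from the data. The default schedule presents
each of 5/10/20/40 Hz three times in pseudorandomized order with 120 s
epochs and 30 s baseline gaps.

Not emulated: spiking activity, cross-frequency coupling, non-stationary
background power, electrode drift. Passing tests therefore demonstrate
correctness of the estimators under the stated statistical structure, not
robustness to every pathology of real recordings.

**Photometry.** Trace = quadratic trend + per-trial transients + Gaussian
noise; the transient kernel is a difference of exponentials (rise 0.2 s,
decay 1.5 s, unit peak) — sensor kinetics are not published for this
configuration, so these are declared defaults. Per-trial amplitudes may
decay across trials to emulate dopamine depletion. The default layout is
15 trials of 5 s stimulation every 30 s at 20 frames/s, with the first
onset one full period in so every trial has its baseline.

**Behavior.** A reflected Gaussian random walk with zone stickiness
(shorter steps inside a zone ≈ dwell) and a drift toward one cup scaled by
`2·(sideBias − 0.5)`; the construction is exactly symmetric at bias 0.5.
Any trajectory model would do — the contract is only that ground-truth
occupancy is recorded — but this one produces visually plausible dwell
bouts. Tracking rate defaults to 25 Hz, typical of video tracking.

## 7. Problem sizes and reproducibility

Every generator is a pure function of its arguments including the seed
(verified bit-for-bit in tests). The validation suite runs: evoked-power
detection over 100 seeded sessions of 4 frequencies × 3 repeats with 30 s
epochs and 30 s gaps (stimulus RMS twice the background RMS — detection
over 30 s windows is strictly harder than over the full 120 s epochs, so
the scaled check is conservative); artifact recovery over 50 seeded
560 s sessions with 5 injected bursts each; photometry amplitude-ratio
recovery over 50 seeded session pairs (amplitudes A and A/2, noise
0.2 A); and the avoidance scenario over 100 seeded pairs of full 10 min
trials with bias 0.8 toward the stimulation side in habituation and 0.2 in
testing. Workflow outputs carry a parameter manifest, and two runs from
identical configurations produce byte-identical tables.

## 8. Known limitations

* The EDF and HDF5 containers sometimes used for raw recordings and
  spectrograms are not read or written; recordings, protocols, traces and
  trajectories travel as delimited text, spectrograms as a CSV bundle with
  a YAML sidecar.
* The ±2 SD inclusion screen cannot exclude members of groups smaller
  than about 7 (see §2); this is a property of the criterion, not of the
  implementation.
* Group-level inferential statistics, image-plane photometry processing
  (motion correction, ROI extraction), video tracking, and hardware
  control are out of scope; the package consumes their outputs.
* iPLV discards genuinely instantaneous neural coupling along with volume
  conduction; it bounds, rather than measures, lagged interaction.
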