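# Shared fixture builders; everything is generated in code at test time.

# Single-channel recording holding a pure tone (plus optional DC offset).
toneRecording <- function(freqHz, durationS = 10, fsHz = 1000, amp = 1,
                          dc = 0, phase = 0) {
  t <- (seq_len(durationS * fsHz) - 1) / fsHz
  LFPRecording(matrix(amp * cos(2 * pi * freqHz * t + phase) + dc, nrow = 1),
               fsHz = fsHz, channelLabels = "tone")
}

# Two-channel recording: identical tone with a fixed phase offset on ch2.
laggedPairRecording <- function(freqHz, lagRad, durationS = 20,
                                fsHz = 1000, amp = 1, noiseSd = 0,
                                seed = 1) {
  set.seed(seed)
  t <- (seq_len(durationS * fsHz) - 1) / fsHz
  ch1 <- amp * cos(2 * pi * freqHz * t) + rnorm(length(t), sd = noiseSd)
  ch2 <- amp * cos(2 * pi * freqHz * t - lagRad) +
    rnorm(length(t), sd = noiseSd)
  LFPRecording(rbind(ch1, ch2), fsHz = fsHz,
               channelLabels = c("BLA", "mPFC"))
}

# Spectrogram with every cell equal to `value`.
flatSpectrogram <- function(value = 1, nT = 100, nF = 50, binStepS = 2.5,
                            freqStepHz = 1) {
  Spectrogram(matrix(value, nT, nF),
              timesS = (seq_len(nT) - 1) * binStepS + binStepS / 2,
              freqsHz = (seq_len(nF) - 1) * freqStepHz,
              windowS = 2 * binStepS, overlapFrac = 0.5)
}

# PhaseSeries pair with a prescribed phase-difference vector.
phasePairFromDiff <- function(dphi, fsHz = 100) {
  n <- length(dphi)
  t <- (seq_len(n) - 1) / fsHz
  mk <- function(ph, lab) new("PhaseSeries", timesS = t,
                              phaseRad = Arg(exp(1i * ph)), centerHz = 20,
                              halfWidthHz = 1, channelLabel = lab,
                              edgeMask = rep(FALSE, n))
  list(a = mk(dphi, "a"), b = mk(rep(0, n), "b"))
}

# Brute-force PLV/iPLV oracle: explicit loop over samples.
bruteForcePhasors <- function(dphi) {
  sumRe <- 0
  sumIm <- 0
  for (d in dphi) {
    sumRe <- sumRe + cos(d)
    sumIm <- sumIm + sin(d)
  }
  n <- length(dphi)
  list(plv = sqrt((sumRe / n)^2 + (sumIm / n)^2),
       iplv = abs(sumIm / n))
}

# Minimal valid four-trial protocol table for two animals (Table-style).
validProtocolTable <- function() {
  data.frame(
    animal = rep(c("Animal 1", "Animal 2"), each = 4),
    session = c("Toy-Toy", "Toy-Toy", "Toy-Female", "Toy-Female",
                "Toy-Female", "Toy-Female", "Toy-Toy", "Toy-Toy"),
    trial = rep(c("Habituation", "Testing"), 4),
    stim = rep(c("Off", "On"), 4),
    stim_side = c("-", "L", "-", "R", "-", "L", "-", "R")
  )
}

# Stationary trajectory at a fixed point.
stationarySession <- function(x, y, durationS = 60, rateHz = 10, ...) {
  n <- durationS * rateHz
  BehaviorSession(data.frame(time_s = (seq_len(n) - 1) / rateHz,
                             nose_x_cm = rep(x, n),
                             nose_y_cm = rep(y, n)), ...)
}
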