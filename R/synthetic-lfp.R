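# Ground-truth generator for dual-site LFP under rhythmic photostimulation.

# Evaluate expr under a fixed RNG seed without disturbing the caller's RNG.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

.stopConfig <- function(field, why) {
  stop("invalid configuration: '", field, "' ", why, call. = FALSE)
}

# 1/f^alpha noise by spectral shaping of white Gaussian noise, scaled to a
# target RMS. Consumes the current RNG stream.
.pinkNoise <- function(n, fsHz, alpha, rmsAmp) {
  if (rmsAmp <= 0) return(numeric(n))
  m <- stats::nextn(n, c(2, 3, 5))
  w <- stats::rnorm(m)
  W <- stats::fft(w)
  f <- c(0, pmin(seq_len(m - 1), m - seq_len(m - 1))) * fsHz / m
  shape <- c(0, f[-1]^(-alpha / 2))
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / m
  x <- x[seq_len(n)]
  x * rmsAmp / stats::sd(x)
}

# Default pseudorandomized schedule: each frequency repeated nRepeats times,
# order drawn from the current RNG stream, epochs separated by baseline gaps.
.defaultSchedule <- function(stimFreqsHz, nRepeats, epochDurS, gapS) {
  freqs <- rep(stimFreqsHz, each = nRepeats)
  order <- freqs[sample.int(length(freqs))]
  onsets <- gapS + (seq_along(order) - 1) * (epochDurS + gapS)
  data.frame(onset_s = onsets, offset_s = onsets + epochDurS, freq_hz = order)
}

#' Simulate a two-channel LFP recording with stimulation-locked oscillations
#'
#' Generates a "BLA"/"mPFC" channel pair as independent 1/f^alpha background
#' noise plus, during each stimulation epoch, a sinusoid at the epoch's drive
#' frequency added to channel 1 and, phase-shifted by `phaseLagRad`, to
#' channel 2. Optional components: an identical (zero-lag) broadband signal
#' on both channels, 60 Hz line noise, and short high-amplitude artifacts.
#' The default schedule presents each drive frequency `nRepeats` times in
#' pseudorandomized order, each epoch preceded by a baseline gap.
#'
#' Output is a pure function of the arguments including `seed`.
#'
#' @param seed integer RNG seed.
#' @param fsHz sampling rate (samples/s); must exceed twice the larger of
#'   the highest drive frequency and 61 Hz.
#' @param noiseExponent alpha of the 1/f^alpha background (default 1).
#' @param noiseAmp background RMS amplitude (uV) per channel.
#' @param stimFreqsHz drive frequencies (Hz) for the default schedule.
#' @param stimAmp sinusoid amplitude (uV) during epochs.
#' @param stimSchedule optional data.frame (`onset_s`, `offset_s`, `freq_hz`)
#'   overriding the default pseudorandomized layout.
#' @param nRepeats presentations per frequency in the default schedule.
#' @param epochDurS,gapS epoch length and inter-epoch baseline gap (s) for
#'   the default schedule (120 s and 30 s).
#' @param durationS total duration (s); defaults to the schedule span plus a
#'   trailing gap.
#' @param phaseLagRad phase lag (rad) applied to channel 2's stim-locked
#'   component.
#' @param sharedZeroLagAmp RMS amplitude (uV) of an identical 1/f component
#'   added to both channels (volume-conduction surrogate).
#' @param artifactTimesS onset times (s) of injected artifacts.
#' @param artifactAmp artifact peak amplitude (uV); artifacts are 0.5 s
#'   oscillatory bursts (half-sine envelope) added to both channels.
#' @param artifactDurS artifact duration (s).
#' @param artifactFreqHz carrier frequency (Hz) of the artifact burst.
#' @param lineNoiseAmp 60 Hz sinusoid amplitude (uV).
#' @param waveform `"sine"` (default) or `"pulse"` (rectangular 5 ms pulses
#'   at the drive rate).
#' @param pulseWidthMs pulse width (ms) recorded in the protocol and used by
#'   the `"pulse"` waveform.
#' @return list with elements `recording` ([LFPRecording-class]) and
#'   `protocol` ([StimProtocol-class]).
#' @examples
#' sim <- simulateLFPPair(seed = 1, stimFreqsHz = 20, nRepeats = 1,
#'                        epochDurS = 10, gapS = 5)
#' sim$recording
#' epochs(sim$protocol)
#' @export
simulateLFPPair <- function(seed,
                            fsHz = 1000,
                            noiseExponent = 1,
                            noiseAmp = 20,
                            stimFreqsHz = c(5, 10, 20, 40),
                            stimAmp = 50,
                            stimSchedule = NULL,
                            nRepeats = 3,
                            epochDurS = 120,
                            gapS = 30,
                            durationS = NULL,
                            phaseLagRad = 0,
                            sharedZeroLagAmp = 0,
                            artifactTimesS = numeric(),
                            artifactAmp = 0,
                            artifactDurS = 0.5,
                            artifactFreqHz = 12,
                            lineNoiseAmp = 0,
                            waveform = c("sine", "pulse"),
                            pulseWidthMs = 5) {
  waveform <- match.arg(waveform)
  if (length(stimFreqsHz) == 0 || any(stimFreqsHz <= 0))
    .stopConfig("stimFreqsHz", "must be positive drive frequencies")
  if (fsHz <= 2 * max(max(stimFreqsHz), 61))
    .stopConfig("fsHz", "must exceed twice max(stim frequency, 61 Hz)")
  for (nm in c("noiseAmp", "stimAmp", "sharedZeroLagAmp", "artifactAmp",
               "lineNoiseAmp")) {
    if (get(nm) < 0) .stopConfig(nm, "must be >= 0")
  }

  .withSeed(seed, {
    if (is.null(stimSchedule))
      stimSchedule <- .defaultSchedule(stimFreqsHz, nRepeats, epochDurS, gapS)
    stimSchedule <- stimSchedule[order(stimSchedule$onset_s), , drop = FALSE]
    if (is.null(durationS))
      durationS <- max(stimSchedule$offset_s) + gapS
    if (durationS <= 0) .stopConfig("durationS", "must be positive")
    if (any(stimSchedule$onset_s < 0) ||
        any(stimSchedule$offset_s > durationS))
      .stopConfig("stimSchedule", "epochs must lie within [0, durationS)")
    if (nrow(stimSchedule) > 1 &&
        any(stimSchedule$onset_s[-1] < stimSchedule$offset_s[-nrow(stimSchedule)]))
      .stopConfig("stimSchedule", "epochs must not overlap")

    n <- round(durationS * fsHz)
    t <- (seq_len(n) - 1) / fsHz

    ch1 <- .pinkNoise(n, fsHz, noiseExponent, noiseAmp)
    ch2 <- .pinkNoise(n, fsHz, noiseExponent, noiseAmp)
    if (sharedZeroLagAmp > 0) {
      shared <- .pinkNoise(n, fsHz, noiseExponent, sharedZeroLagAmp)
      ch1 <- ch1 + shared
      ch2 <- ch2 + shared
    }

    for (i in seq_len(nrow(stimSchedule))) {
      f <- stimSchedule$freq_hz[i]
      idx <- which(t >= stimSchedule$onset_s[i] & t < stimSchedule$offset_s[i])
      tt <- t[idx] - stimSchedule$onset_s[i]
      if (waveform == "sine") {
        ch1[idx] <- ch1[idx] + stimAmp * sin(2 * pi * f * tt)
        ch2[idx] <- ch2[idx] + stimAmp * sin(2 * pi * f * tt - phaseLagRad)
      } else {
        width <- pulseWidthMs / 1000
        pulse1 <- (tt %% (1 / f)) < width
        tlag <- tt - phaseLagRad / (2 * pi * f)
        pulse2 <- tlag >= 0 & (tlag %% (1 / f)) < width
        ch1[idx] <- ch1[idx] + stimAmp * pulse1
        ch2[idx] <- ch2[idx] + stimAmp * pulse2
      }
    }

    if (lineNoiseAmp > 0) {
      line <- lineNoiseAmp * sin(2 * pi * 60 * t)
      ch1 <- ch1 + line
      ch2 <- ch2 + line
    }

    if (length(artifactTimesS) && artifactAmp > 0) {
      for (a in artifactTimesS) {
        idx <- which(t >= a & t < a + artifactDurS)
        tt <- t[idx] - a
        # oscillatory burst under a half-sine envelope: keeps the artifact
        # inside the analysis band so it survives the 1-250 Hz filter
        bump <- artifactAmp * sin(pi * tt / artifactDurS) *
          cos(2 * pi * artifactFreqHz * tt)
        ch1[idx] <- ch1[idx] + bump
        ch2[idx] <- ch2[idx] + bump
      }
    }

    rec <- LFPRecording(rbind(ch1, ch2), fsHz = fsHz,
                        channelLabels = c("BLA", "mPFC"))
    proto <- StimProtocol(data.frame(
      onset_s = stimSchedule$onset_s,
      offset_s = stimSchedule$offset_s,
      freq_hz = stimSchedule$freq_hz,
      pulse_width_ms = pulseWidthMs
    ))
    list(recording = rec, protocol = proto)
  })
}
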