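# Ground-truth generator for dopamine-sensor (dF/F) trial sessions.

# Difference-of-exponentials kernel normalized to unit peak, with its peak
# time, peak value (pre-normalization) and unit-peak integral.
.transientKernel <- function(riseS, decayS) {
  if (riseS <= 0 || decayS <= riseS)
    .stopConfig("kernel", "needs 0 < riseS < decayS")
  tp <- riseS * decayS / (decayS - riseS) * log(decayS / riseS)
  peak <- exp(-tp / decayS) - exp(-tp / riseS)
  list(
    fn = function(t) ifelse(t < 0, 0,
                            (exp(-t / decayS) - exp(-t / riseS)) / peak),
    peakTimeS = tp,
    integral = (decayS - riseS) / peak
  )
}

#' Simulate a dopamine-sensor photometry session
#'
#' Builds each ROI trace as a quadratic photobleaching trend plus a train of
#' stimulation-evoked transients plus Gaussian noise. The default layout
#' mirrors a standard trial design: 15 trials of 5 s stimulation initiated
#' every 30 s, sampled at 20 frames per second, with the first onset one full
#' trial period into the session. Transients are difference-of-exponentials
#' kernels (unit peak) aligned to each onset and scaled by `transientAmp`,
#' which may be a per-trial vector (e.g., decaying across trials to emulate
#' dopamine depletion).
#'
#' The returned session stores its ground truth: the noise-free transient
#' trace, the trend, per-trial amplitudes, and the closed-form area under
#' each trial's transient (`amp * (decayS - riseS) / kernel peak`).
#'
#' @param seed integer RNG seed.
#' @param nTrials number of stimulation trials (default 15).
#' @param trialPeriodS trial spacing (s, default 30).
#' @param stimDurS stimulation duration per trial (s, default 5).
#' @param frameRateHz frames per second (default 20).
#' @param bleachCoeffs quadratic trend coefficients `c(a, b, c)` evaluated as
#'   `a*t^2 + b*t + c` with t in seconds.
#' @param riseS,decayS kernel time constants (s).
#' @param transientAmp peak dF/F amplitude per trial; scalar or length
#'   `nTrials`.
#' @param noiseSd Gaussian noise SD (dF/F units).
#' @param nRois number of ROIs; transients are shared, noise independent.
#' @return A [PhotometrySession-class] with ground truth attached.
#' @examples
#' ses <- simulatePhotometry(seed = 1)
#' stimEvents(ses)[1:3, ]
#' @export
simulatePhotometry <- function(seed,
                               nTrials = 15,
                               trialPeriodS = 30,
                               stimDurS = 5,
                               frameRateHz = 20,
                               bleachCoeffs = c(2e-7, -5e-4, 1),
                               riseS = 0.2,
                               decayS = 1.5,
                               transientAmp = 0.2,
                               noiseSd = 0.02,
                               nRois = 1) {
  if (nTrials < 1) .stopConfig("nTrials", "must be >= 1")
  if (frameRateHz <= 0) .stopConfig("frameRateHz", "must be positive")
  if (trialPeriodS <= stimDurS)
    .stopConfig("trialPeriodS", "must exceed stimDurS")
  if (length(transientAmp) == 1) transientAmp <- rep(transientAmp, nTrials)
  if (length(transientAmp) != nTrials)
    .stopConfig("transientAmp", "must be scalar or one value per trial")
  if (any(transientAmp < 0)) .stopConfig("transientAmp", "must be >= 0")
  if (noiseSd < 0) .stopConfig("noiseSd", "must be >= 0")

  kern <- .transientKernel(riseS, decayS)
  durationS <- trialPeriodS * (nTrials + 1)
  nFrames <- round(durationS * frameRateHz)
  t <- (seq_len(nFrames) - 1) / frameRateHz
  onsets <- trialPeriodS * seq_len(nTrials)

  trend <- bleachCoeffs[1] * t^2 + bleachCoeffs[2] * t + bleachCoeffs[3]
  transient <- numeric(nFrames)
  for (i in seq_len(nTrials))
    transient <- transient + transientAmp[i] * kern$fn(t - onsets[i])

  .withSeed(seed, {
    traces <- matrix(NA_real_, nrow = nRois, ncol = nFrames)
    for (r in seq_len(nRois))
      traces[r, ] <- trend + transient + stats::rnorm(nFrames, sd = noiseSd)
    PhotometrySession(
      traces, frameRateHz = frameRateHz,
      events = data.frame(onset_s = onsets, offset_s = onsets + stimDurS),
      groundTruth = list(
        transientTrace = transient,
        trend = trend,
        transientAmp = transientAmp,
        aucPerTrial = transientAmp * kern$integral,
        kernel = list(riseS = riseS, decayS = decayS,
                      peakTimeS = kern$peakTimeS,
                      unitIntegral = kern$integral)
      )
    )
  })
}
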