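#' @import methods
NULL

#' Multichannel LFP recording
#'
#' Container for a multichannel local field potential recording: a
#' channels x samples matrix in microvolts plus its sampling rate, channel
#' labels, and the time of the first sample.
#'
#' @slot data numeric matrix, channels x samples, in microvolts.
#' @slot fsHz sampling rate in samples per second.
#' @slot channelLabels character vector, one label per channel (row).
#' @slot startTimeS time of the first sample in seconds (default 0).
#'
#' @seealso [LFPRecording()] for the constructor, [bandPass()],
#'   [computeSTFT()], [narrowbandPhase()]
#' @export
setClass("LFPRecording",
  slots = c(
    data = "matrix",
    fsHz = "numeric",
    channelLabels = "character",
    startTimeS = "numeric"
  ),
  prototype = prototype(startTimeS = 0)
)

setValidity("LFPRecording", function(object) {
  msg <- character()
  if (length(object@fsHz) != 1L || !is.finite(object@fsHz) || object@fsHz <= 0)
    msg <- c(msg, "fsHz must be a single positive number")
  if (nrow(object@data) != length(object@channelLabels))
    msg <- c(msg, "one channel label per data row is required")
  if (anyDuplicated(object@channelLabels))
    msg <- c(msg, "channel labels must be unique")
  if (any(!is.finite(object@data)))
    msg <- c(msg, "data contains non-finite samples")
  if (length(object@startTimeS) != 1L || !is.finite(object@startTimeS))
    msg <- c(msg, "startTimeS must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' Construct an LFPRecording
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param fsHz sampling rate (samples/s).
#' @param channelLabels character vector of channel names; defaults to
#'   `ch1, ch2, ...`.
#' @param startTimeS time of the first sample in seconds.
#' @return An [LFPRecording-class] object.
#' @examples
#' rec <- LFPRecording(matrix(rnorm(2000), nrow = 2), fsHz = 1000,
#'                     channelLabels = c("BLA", "mPFC"))
#' nChannels(rec)
#' @export
LFPRecording <- function(data, fsHz, channelLabels = NULL, startTimeS = 0) {
  data <- as.matrix(data)
  if (is.null(channelLabels))
    channelLabels <- paste0("ch", seq_len(nrow(data)))
  new("LFPRecording", data = data, fsHz = as.numeric(fsHz),
      channelLabels = as.character(channelLabels),
      startTimeS = as.numeric(startTimeS))
}

#' Stimulation protocol
#'
#' Ordered table of stimulation epochs. Epochs are half-open intervals
#' `[onset_s, offset_s)` in seconds from recording start; `repeat_idx`
#' numbers the presentations of each frequency in order (1-based).
#'
#' @slot epochs data.frame with columns `onset_s`, `offset_s`, `freq_hz`,
#'   `pulse_width_ms`, `repeat_idx`, sorted by onset.
#' @seealso [StimProtocol()], [powerRatio()], [coherenceRatio()]
#' @export
setClass("StimProtocol", slots = c(epochs = "data.frame"))

setValidity("StimProtocol", function(object) {
  ep <- object@epochs
  need <- c("onset_s", "offset_s", "freq_hz", "pulse_width_ms", "repeat_idx")
  if (!all(need %in% names(ep)))
    return(paste("epochs must have columns:", paste(need, collapse = ", ")))
  msg <- character()
  if (nrow(ep)) {
    if (any(ep$offset_s <= ep$onset_s))
      msg <- c(msg, "every epoch must have offset_s > onset_s")
    if (is.unsorted(ep$onset_s, strictly = TRUE) && nrow(ep) > 1)
      msg <- c(msg, "epochs must be sorted by onset_s")
    if (nrow(ep) > 1 && any(ep$onset_s[-1] < ep$offset_s[-nrow(ep)]))
      msg <- c(msg, "epochs must not overlap")
    if (any(ep$freq_hz <= 0)) msg <- c(msg, "freq_hz must be positive")
    if (any(ep$repeat_idx < 1)) msg <- c(msg, "repeat_idx must be >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a StimProtocol
#'
#' @param epochs data.frame with columns `onset_s`, `offset_s`, `freq_hz`,
#'   and optionally `pulse_width_ms` (default 5) and `repeat_idx`
#'   (default: presentation count of each frequency, in onset order).
#' @return A [StimProtocol-class] object.
#' @export
StimProtocol <- function(epochs) {
  epochs <- as.data.frame(epochs)
  if (is.null(epochs$pulse_width_ms)) epochs$pulse_width_ms <- 5
  epochs <- epochs[order(epochs$onset_s), , drop = FALSE]
  if (is.null(epochs$repeat_idx)) {
    epochs$repeat_idx <- stats::ave(seq_len(nrow(epochs)), epochs$freq_hz,
                                    FUN = seq_along)
  }
  rownames(epochs) <- NULL
  new("StimProtocol", epochs = epochs)
}

#' Time-frequency power spectrogram
#'
#' One channel's short-time power decomposition: a time x frequency matrix
#' of power spectral density (uV^2/Hz) with bin-center metadata and a
#' per-time-bin outlier mask.
#'
#' @slot power numeric matrix, time bins x frequency bins, uV^2/Hz.
#' @slot timesS time-bin centers (s), strictly increasing.
#' @slot freqsHz frequency-bin centers (Hz), strictly increasing.
#' @slot windowS analysis window length (s).
#' @slot overlapFrac fractional overlap between consecutive windows.
#' @slot outlierMask logical, one flag per time bin (TRUE = replaced).
#' @slot channelLabel source channel.
#' @seealso [computeSTFT()], [removeLineNoise()], [detectOutliers()],
#'   [bandPower()]
#' @export
setClass("Spectrogram",
  slots = c(
    power = "matrix",
    timesS = "numeric",
    freqsHz = "numeric",
    windowS = "numeric",
    overlapFrac = "numeric",
    outlierMask = "logical",
    channelLabel = "character"
  )
)

setValidity("Spectrogram", function(object) {
  msg <- character()
  if (nrow(object@power) != length(object@timesS))
    msg <- c(msg, "power must have one row per time bin")
  if (ncol(object@power) != length(object@freqsHz))
    msg <- c(msg, "power must have one column per frequency bin")
  if (any(object@power < 0)) msg <- c(msg, "power must be non-negative")
  if (length(object@timesS) > 1 && is.unsorted(object@timesS, strictly = TRUE))
    msg <- c(msg, "times must be strictly increasing")
  if (length(object@freqsHz) > 1 && is.unsorted(object@freqsHz, strictly = TRUE))
    msg <- c(msg, "frequencies must be strictly increasing")
  if (length(object@outlierMask) != length(object@timesS))
    msg <- c(msg, "outlierMask must have one entry per time bin")
  if (length(msg)) msg else TRUE
})

#' Construct a Spectrogram
#'
#' Mostly used internally by [computeSTFT()]; exposed so tests and callers
#' can build spectrograms with known bin contents.
#'
#' @param power time x frequency matrix of non-negative power.
#' @param timesS,freqsHz bin centers.
#' @param windowS,overlapFrac window metadata.
#' @param outlierMask per-time-bin logical; defaults to all FALSE.
#' @param channelLabel source channel name.
#' @return A [Spectrogram-class] object.
#' @export
Spectrogram <- function(power, timesS, freqsHz, windowS = NA_real_,
                        overlapFrac = NA_real_, outlierMask = NULL,
                        channelLabel = "ch1") {
  power <- as.matrix(power)
  if (is.null(outlierMask)) outlierMask <- rep(FALSE, nrow(power))
  new("Spectrogram", power = power, timesS = as.numeric(timesS),
      freqsHz = as.numeric(freqsHz), windowS = as.numeric(windowS),
      overlapFrac = as.numeric(overlapFrac),
      outlierMask = as.logical(outlierMask),
      channelLabel = as.character(channelLabel))
}

#' Narrowband instantaneous phase series
#'
#' Instantaneous phase of one channel after zero-phase narrowband filtering,
#' in radians in (-pi, pi]. `edgeMask` flags samples near the window edges
#' (filter transients) that are excluded from phase averaging.
#'
#' @slot timesS sample times (s).
#' @slot phaseRad instantaneous phase (rad) in (-pi, pi].
#' @slot centerHz,halfWidthHz band definition (Hz).
#' @slot channelLabel source channel.
#' @slot edgeMask logical; TRUE = edge sample, excluded from averages.
#' @seealso [narrowbandPhase()], [plv()], [iplv()]
#' @export
setClass("PhaseSeries",
  slots = c(
    timesS = "numeric",
    phaseRad = "numeric",
    centerHz = "numeric",
    halfWidthHz = "numeric",
    channelLabel = "character",
    edgeMask = "logical"
  )
)

setValidity("PhaseSeries", function(object) {
  msg <- character()
  if (length(object@phaseRad) != length(object@timesS))
    msg <- c(msg, "phase and times must have equal length")
  if (length(object@edgeMask) != length(object@timesS))
    msg <- c(msg, "edgeMask must have one entry per sample")
  if (any(object@phaseRad > pi + 1e-9) || any(object@phaseRad <= -pi - 1e-9))
    msg <- c(msg, "phase must lie in (-pi, pi]")
  if (length(msg)) msg else TRUE
})

#' Dopamine-sensor photometry session
#'
#' dF/F traces for one or more ROIs at a fixed frame rate, together with the
#' stimulation event table. Synthetic sessions carry their ground truth
#' (noise-free transient trace, trend, per-trial amplitudes) in
#' `groundTruth`.
#'
#' @slot frameRateHz frames per second.
#' @slot traces ROI x frame matrix of dF/F (unitless).
#' @slot roiIds one id per trace row.
#' @slot events data.frame with columns `onset_s`, `offset_s`.
#' @slot groundTruth list; empty for real data.
#' @seealso [simulatePhotometry()], [detrendQuadratic()], [parseTrials()]
#' @export
setClass("PhotometrySession",
  slots = c(
    frameRateHz = "numeric",
    traces = "matrix",
    roiIds = "character",
    events = "data.frame",
    groundTruth = "list"
  ),
  prototype = prototype(groundTruth = list())
)

setValidity("PhotometrySession", function(object) {
  msg <- character()
  if (length(object@frameRateHz) != 1L || object@frameRateHz <= 0)
    msg <- c(msg, "frameRateHz must be a single positive number")
  if (nrow(object@traces) != length(object@roiIds))
    msg <- c(msg, "one roi id per trace row is required")
  if (nrow(object@events)) {
    if (!all(c("onset_s", "offset_s") %in% names(object@events)))
      msg <- c(msg, "events needs columns onset_s, offset_s")
    else {
      dur <- ncol(object@traces) / object@frameRateHz
      if (any(object@events$onset_s < 0) || any(object@events$offset_s > dur))
        msg <- c(msg, "events must lie within the session span")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PhotometrySession
#' @param traces ROI x frame dF/F matrix (a vector is treated as one ROI).
#' @param frameRateHz frames per second (default 20).
#' @param events data.frame of stimulation epochs (`onset_s`, `offset_s`).
#' @param roiIds ROI names; default `roi1, ...`.
#' @param groundTruth optional list (synthetic sessions only).
#' @return A [PhotometrySession-class] object.
#' @export
PhotometrySession <- function(traces, frameRateHz = 20, events = NULL,
                              roiIds = NULL, groundTruth = list()) {
  if (is.vector(traces)) traces <- matrix(traces, nrow = 1)
  if (is.null(roiIds)) roiIds <- paste0("roi", seq_len(nrow(traces)))
  if (is.null(events))
    events <- data.frame(onset_s = numeric(), offset_s = numeric())
  new("PhotometrySession", frameRateHz = as.numeric(frameRateHz),
      traces = as.matrix(traces), roiIds = as.character(roiIds),
      events = as.data.frame(events), groundTruth = groundTruth)
}

#' Trial-aligned photometry matrix
#'
#' Trials x frames matrix of baseline-normalized dF/F aligned at stimulation
#' onset (t = 0), spanning `-preS` to `+postS` seconds around each onset.
#'
#' @slot data trials x frames normalized response (baseline = 1).
#' @slot timesS frame times relative to onset (s).
#' @slot preS,postS window extent (s).
#' @slot stimDurS stimulation duration per trial (s).
#' @slot onsetsS absolute onset time of each retained trial (s).
#' @seealso [parseTrials()], [binnedResponse()], [sessionAverage()]
#' @export
setClass("TrialMatrix",
  slots = c(
    data = "matrix",
    timesS = "numeric",
    preS = "numeric",
    postS = "numeric",
    stimDurS = "numeric",
    onsetsS = "numeric"
  )
)

setValidity("TrialMatrix", function(object) {
  msg <- character()
  if (ncol(object@data) != length(object@timesS))
    msg <- c(msg, "data must have one column per relative time point")
  if (nrow(object@data) != length(object@onsetsS))
    msg <- c(msg, "data must have one row per trial onset")
  if (length(msg)) msg else TRUE
})

#' Three-chamber arena geometry
#'
#' Rectangular arena split into three equal-width chambers along x, with one
#' inverted wire cup centered in each outer chamber. The interaction zone
#' around a cup is all points within `cupRadiusCm + zoneMarginCm` of its
#' center (7 cm at defaults).
#'
#' @slot widthCm,depthCm arena dimensions (cm); default 71 x 30.
#' @slot cupCenters 2 x 2 matrix, rows = left/right cup, cols = x/y (cm).
#' @slot cupRadiusCm wire-cup radius (cm), default 4 (8 cm diameter).
#' @slot zoneMarginCm interaction-zone margin beyond the cup (cm), default 3.
#' @seealso [ArenaGeometry()], [zoneOccupancy()], [chamberTimes()]
#' @export
setClass("ArenaGeometry",
  slots = c(
    widthCm = "numeric",
    depthCm = "numeric",
    cupCenters = "matrix",
    cupRadiusCm = "numeric",
    zoneMarginCm = "numeric"
  )
)

setValidity("ArenaGeometry", function(object) {
  msg <- character()
  if (object@zoneMarginCm <= 0) msg <- c(msg, "zoneMarginCm must be positive")
  cc <- object@cupCenters
  if (!all(dim(cc) == c(2, 2)))
    msg <- c(msg, "cupCenters must be a 2 x 2 matrix (left/right x x/y)")
  else {
    r <- object@cupRadiusCm
    inside <- cc[, 1] - r >= 0 & cc[, 1] + r <= object@widthCm &
      cc[, 2] - r >= 0 & cc[, 2] + r <= object@depthCm
    if (!all(inside)) msg <- c(msg, "cups must lie inside the arena")
    third <- object@widthCm / 3
    if (!(cc[1, 1] < third && cc[2, 1] > 2 * third))
      msg <- c(msg, "left/right cups must sit in their outer chambers")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ArenaGeometry
#'
#' Defaults reproduce the standard three-chamber social-interaction arena:
#' 71 x 30 cm, 8 cm-diameter cups centered in the outer chambers, 3 cm
#' interaction-zone margin.
#'
#' @param widthCm,depthCm arena dimensions (cm).
#' @param cupRadiusCm cup radius (cm).
#' @param zoneMarginCm zone margin beyond the cup (cm).
#' @param cupCenters optional 2 x 2 matrix (left/right rows, x/y columns);
#'   default centers each cup in its outer chamber.
#' @return An [ArenaGeometry-class] object.
#' @examples
#' geom <- ArenaGeometry()
#' zoneRadius(geom)  # 7 cm
#' @export
ArenaGeometry <- function(widthCm = 71, depthCm = 30, cupRadiusCm = 4,
                          zoneMarginCm = 3, cupCenters = NULL) {
  if (is.null(cupCenters)) {
    cupCenters <- rbind(
      left  = c(widthCm / 6, depthCm / 2),
      right = c(5 * widthCm / 6, depthCm / 2)
    )
  }
  colnames(cupCenters) <- c("x", "y")
  new("ArenaGeometry", widthCm = as.numeric(widthCm),
      depthCm = as.numeric(depthCm), cupCenters = as.matrix(cupCenters),
      cupRadiusCm = as.numeric(cupRadiusCm),
      zoneMarginCm = as.numeric(zoneMarginCm))
}

#' Behavioral tracking session
#'
#' Nose-position trajectory for one trial of the three-chamber task, plus
#' the trial descriptors needed for preference scoring. Synthetic sessions
#' record ground-truth zone occupancy in `groundTruth`.
#'
#' @slot samples data.frame with columns `time_s`, `nose_x_cm`, `nose_y_cm`,
#'   times strictly increasing.
#' @slot stimSide `"left"`, `"right"`, or `"none"` (habituation).
#' @slot trialType `"habituation"` or `"testing"`.
#' @slot sessionType `"ToyToy"` or `"ToyFemale"`.
#' @slot groundTruth list; empty for real data.
#' @seealso [simulateTrajectory()], [zoneOccupancy()], [preferenceScore()]
#' @export
setClass("BehaviorSession",
  slots = c(
    samples = "data.frame",
    stimSide = "character",
    trialType = "character",
    sessionType = "character",
    groundTruth = "list"
  ),
  prototype = prototype(stimSide = "none", trialType = "habituation",
                        sessionType = "ToyToy", groundTruth = list())
)

setValidity("BehaviorSession", function(object) {
  msg <- character()
  need <- c("time_s", "nose_x_cm", "nose_y_cm")
  if (!all(need %in% names(object@samples)))
    msg <- c(msg, paste("samples needs columns:", paste(need, collapse = ", ")))
  else if (nrow(object@samples) > 1 &&
           is.unsorted(object@samples$time_s, strictly = TRUE))
    msg <- c(msg, "sample times must be strictly increasing")
  if (!object@stimSide %in% c("left", "right", "none"))
    msg <- c(msg, "stimSide must be 'left', 'right' or 'none'")
  if (!object@trialType %in% c("habituation", "testing"))
    msg <- c(msg, "trialType must be 'habituation' or 'testing'")
  if (!object@sessionType %in% c("ToyToy", "ToyFemale"))
    msg <- c(msg, "sessionType must be 'ToyToy' or 'ToyFemale'")
  if (length(msg)) msg else TRUE
})

#' Construct a BehaviorSession
#' @param samples data.frame `time_s`, `nose_x_cm`, `nose_y_cm`.
#' @param stimSide stimulation side (`"left"`, `"right"`, `"none"`).
#' @param trialType `"habituation"` or `"testing"`.
#' @param sessionType `"ToyToy"` or `"ToyFemale"`.
#' @param groundTruth optional list (synthetic sessions only).
#' @return A [BehaviorSession-class] object.
#' @export
BehaviorSession <- function(samples, stimSide = "none",
                            trialType = "habituation",
                            sessionType = "ToyToy", groundTruth = list()) {
  new("BehaviorSession", samples = as.data.frame(samples),
      stimSide = stimSide, trialType = trialType,
      sessionType = sessionType, groundTruth = groundTruth)
}
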