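# Accessor generics and methods; slot access stays internal to the package.

#' @rdname LFPRecording-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("fsHz", function(x) standardGeneric("fsHz"))

#' @rdname LFPRecording-class
#' @export
setMethod("fsHz", "LFPRecording", function(x) x@fsHz)

#' @rdname PhotometrySession-class
#' @export
setMethod("fsHz", "PhotometrySession", function(x) x@frameRateHz)

#' @rdname LFPRecording-class
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname LFPRecording-class
#' @export
setMethod("channelLabels", "LFPRecording", function(x) x@channelLabels)

#' @rdname LFPRecording-class
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname LFPRecording-class
#' @export
setMethod("nChannels", "LFPRecording", function(x) nrow(x@data))

#' @rdname LFPRecording-class
#' @param channel channel index or label.
#' @export
setGeneric("lfpData", function(x, channel = NULL) standardGeneric("lfpData"))

#' @rdname LFPRecording-class
#' @export
setMethod("lfpData", "LFPRecording", function(x, channel = NULL) {
  if (is.null(channel)) return(x@data)
  x@data[.channelIndex(x, channel), ]
})

#' @rdname LFPRecording-class
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' @rdname LFPRecording-class
#' @export
setMethod("duration", "LFPRecording", function(x) ncol(x@data) / x@fsHz)

#' @rdname LFPRecording-class
#' @export
setGeneric("sampleTimes", function(x) standardGeneric("sampleTimes"))

#' @rdname LFPRecording-class
#' @export
setMethod("sampleTimes", "LFPRecording", function(x) {
  x@startTimeS + (seq_len(ncol(x@data)) - 1L) / x@fsHz
})

.channelIndex <- function(rec, channel) {
  if (is.character(channel)) {
    idx <- match(channel, rec@channelLabels)
    if (is.na(idx)) stop("unknown channel label: ", channel, call. = FALSE)
    idx
  } else as.integer(channel)
}

#' @rdname StimProtocol-class
#' @param x a StimProtocol.
#' @export
setGeneric("epochs", function(x) standardGeneric("epochs"))

#' @rdname StimProtocol-class
#' @export
setMethod("epochs", "StimProtocol", function(x) x@epochs)

#' @rdname StimProtocol-class
#' @export
setGeneric("stimFrequencies", function(x) standardGeneric("stimFrequencies"))

#' @rdname StimProtocol-class
#' @export
setMethod("stimFrequencies", "StimProtocol",
          function(x) sort(unique(x@epochs$freq_hz)))

#' @rdname Spectrogram-class
#' @param x a Spectrogram.
#' @export
setGeneric("specPower", function(x) standardGeneric("specPower"))

#' @rdname Spectrogram-class
#' @export
setMethod("specPower", "Spectrogram", function(x) x@power)

#' @rdname Spectrogram-class
#' @export
setGeneric("specTimes", function(x) standardGeneric("specTimes"))

#' @rdname Spectrogram-class
#' @export
setMethod("specTimes", "Spectrogram", function(x) x@timesS)

#' @rdname Spectrogram-class
#' @export
setGeneric("specFreqs", function(x) standardGeneric("specFreqs"))

#' @rdname Spectrogram-class
#' @export
setMethod("specFreqs", "Spectrogram", function(x) x@freqsHz)

#' @rdname Spectrogram-class
#' @export
setGeneric("outlierMask", function(x) standardGeneric("outlierMask"))

#' @rdname Spectrogram-class
#' @export
setMethod("outlierMask", "Spectrogram", function(x) x@outlierMask)

#' @rdname Spectrogram-class
#' @export
setGeneric("channelLabel", function(x) standardGeneric("channelLabel"))

#' @rdname Spectrogram-class
#' @export
setMethod("channelLabel", "Spectrogram", function(x) x@channelLabel)

#' @rdname PhaseSeries-class
#' @param x a PhaseSeries.
#' @export
setGeneric("phaseRad", function(x) standardGeneric("phaseRad"))

#' @rdname PhaseSeries-class
#' @export
setMethod("phaseRad", "PhaseSeries", function(x) x@phaseRad)

#' @rdname PhaseSeries-class
#' @export
setGeneric("phaseTimes", function(x) standardGeneric("phaseTimes"))

#' @rdname PhaseSeries-class
#' @export
setMethod("phaseTimes", "PhaseSeries", function(x) x@timesS)

#' @rdname PhaseSeries-class
#' @export
setGeneric("edgeMask", function(x) standardGeneric("edgeMask"))

#' @rdname PhaseSeries-class
#' @export
setMethod("edgeMask", "PhaseSeries", function(x) x@edgeMask)

#' @rdname PhotometrySession-class
#' @param x the object.
#' @export
setGeneric("roiTraces", function(x) standardGeneric("roiTraces"))

#' @rdname PhotometrySession-class
#' @export
setMethod("roiTraces", "PhotometrySession", function(x) x@traces)

#' @rdname PhotometrySession-class
#' @export
setGeneric("stimEvents", function(x) standardGeneric("stimEvents"))

#' @rdname PhotometrySession-class
#' @export
setMethod("stimEvents", "PhotometrySession", function(x) x@events)

#' @rdname PhotometrySession-class
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname PhotometrySession-class
#' @export
setMethod("groundTruth", "PhotometrySession", function(x) x@groundTruth)

#' @rdname BehaviorSession-class
#' @export
setMethod("groundTruth", "BehaviorSession", function(x) x@groundTruth)

#' @rdname TrialMatrix-class
#' @param x a TrialMatrix.
#' @export
setGeneric("trialData", function(x) standardGeneric("trialData"))

#' @rdname TrialMatrix-class
#' @export
setMethod("trialData", "TrialMatrix", function(x) x@data)

#' @rdname TrialMatrix-class
#' @export
setGeneric("trialTimes", function(x) standardGeneric("trialTimes"))

#' @rdname TrialMatrix-class
#' @export
setMethod("trialTimes", "TrialMatrix", function(x) x@timesS)

#' @rdname TrialMatrix-class
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @rdname TrialMatrix-class
#' @export
setMethod("nTrials", "TrialMatrix", function(x) nrow(x@data))

#' @rdname TrialMatrix-class
#' @export
setGeneric("stimDuration", function(x) standardGeneric("stimDuration"))

#' @rdname TrialMatrix-class
#' @export
setMethod("stimDuration", "TrialMatrix", function(x) x@stimDurS)

#' @rdname ArenaGeometry-class
#' @param x an ArenaGeometry.
#' @export
setGeneric("zoneRadius", function(x) standardGeneric("zoneRadius"))

#' @rdname ArenaGeometry-class
#' @export
setMethod("zoneRadius", "ArenaGeometry",
          function(x) x@cupRadiusCm + x@zoneMarginCm)

#' @rdname ArenaGeometry-class
#' @export
setGeneric("cupCenters", function(x) standardGeneric("cupCenters"))

#' @rdname ArenaGeometry-class
#' @export
setMethod("cupCenters", "ArenaGeometry", function(x) x@cupCenters)

#' @rdname BehaviorSession-class
#' @param x a BehaviorSession.
#' @export
setGeneric("trajectory", function(x) standardGeneric("trajectory"))

#' @rdname BehaviorSession-class
#' @export
setMethod("trajectory", "BehaviorSession", function(x) x@samples)

#' @rdname BehaviorSession-class
#' @export
setGeneric("stimSide", function(x) standardGeneric("stimSide"))

#' @rdname BehaviorSession-class
#' @export
setMethod("stimSide", "BehaviorSession", function(x) x@stimSide)

# ---- show methods -----------------------------------------------------------

setMethod("show", "LFPRecording", function(object) {
  cat("LFPRecording:", nrow(object@data), "channel(s) x",
      ncol(object@data), "samples @", object@fsHz, "Hz (",
      sprintf("%.1f", ncol(object@data) / object@fsHz), "s )\n")
  cat("  channels:", paste(object@channelLabels, collapse = ", "), "\n")
})

setMethod("show", "StimProtocol", function(object) {
  ep <- object@epochs
  cat("StimProtocol:", nrow(ep), "epoch(s)")
  if (nrow(ep))
    cat("; frequencies:", paste(sort(unique(ep$freq_hz)), collapse = ", "),
        "Hz")
  cat("\n")
})

setMethod("show", "Spectrogram", function(object) {
  cat("Spectrogram [", object@channelLabel, "]: ",
      length(object@timesS), " time bins x ", length(object@freqsHz),
      " frequency bins\n", sep = "")
  cat(sprintf("  window %.3g s, overlap %.0f%%, %d bin(s) flagged as outliers\n",
              object@windowS, 100 * object@overlapFrac,
              sum(object@outlierMask)))
})

setMethod("show", "PhaseSeries", function(object) {
  cat(sprintf("PhaseSeries [%s]: %d samples, band %.3g +/- %.3g Hz\n",
              object@channelLabel, length(object@phaseRad),
              object@centerHz, object@halfWidthHz))
})

setMethod("show", "PhotometrySession", function(object) {
  cat("PhotometrySession:", nrow(object@traces), "ROI(s) x",
      ncol(object@traces), "frames @", object@frameRateHz, "fps;",
      nrow(object@events), "stimulation event(s)\n")
})

setMethod("show", "TrialMatrix", function(object) {
  cat(sprintf("TrialMatrix: %d trial(s) x %d frames (-%g to +%g s around onset)\n",
              nrow(object@data), ncol(object@data), object@preS, object@postS))
})

setMethod("show", "ArenaGeometry", function(object) {
  cat(sprintf("ArenaGeometry: %g x %g cm, cup radius %g cm, zone radius %g cm\n",
              object@widthCm, object@depthCm, object@cupRadiusCm,
              zoneRadius(object)))
})

setMethod("show", "BehaviorSession", function(object) {
  n <- nrow(object@samples)
  dur <- if (n) diff(range(object@samples$time_s)) else 0
  cat(sprintf("BehaviorSession [%s/%s]: %d samples over %.1f s, stim side: %s\n",
              object@sessionType, object@trialType, n, dur, object@stimSide))
})
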