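# Delimited-text readers/writers for recordings, protocols, photometry,
# trajectories and spectrograms.

.checkFile <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  path
}

#' Write / read an LFP recording as delimited text
#'
#' Column layout: `time_s` followed by one column per channel (header row
#' required); values in microvolts. The sampling rate is recovered on read
#' as the reciprocal of the median inter-sample interval.
#'
#' @param rec an [LFPRecording-class].
#' @param path file path.
#' @return `writeLFPText` returns `path` invisibly; `readLFPText` returns
#'   an [LFPRecording-class].
#' @export
writeLFPText <- function(rec, path) {
  stopifnot(is(rec, "LFPRecording"))
  df <- data.frame(time_s = sampleTimes(rec), t(lfpData(rec)))
  names(df) <- c("time_s", channelLabels(rec))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLFPText
#' @export
readLFPText <- function(path) {
  df <- utils::read.csv(.checkFile(path), check.names = FALSE)
  if (names(df)[1] != "time_s")
    stop("first column must be 'time_s'", call. = FALSE)
  fs <- 1 / stats::median(diff(df$time_s))
  LFPRecording(t(as.matrix(df[, -1, drop = FALSE])), fsHz = fs,
               channelLabels = names(df)[-1], startTimeS = df$time_s[1])
}

#' Write / read a stimulation protocol CSV
#'
#' Columns: `onset_s`, `offset_s`, `freq_hz`, `pulse_width_ms`,
#' `repeat_idx`.
#'
#' @param protocol a [StimProtocol-class].
#' @param path file path.
#' @return `writeProtocolCSV` returns `path` invisibly; `readProtocolCSV`
#'   returns a [StimProtocol-class].
#' @export
writeProtocolCSV <- function(protocol, path) {
  stopifnot(is(protocol, "StimProtocol"))
  utils::write.csv(epochs(protocol), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeProtocolCSV
#' @export
readProtocolCSV <- function(path) {
  StimProtocol(utils::read.csv(.checkFile(path)))
}

#' Write / read photometry traces and events as CSV
#'
#' Traces are stored long: `time_s`, `roi_id`, `dff`; events as `onset_s`,
#' `offset_s`.
#'
#' @param session a [PhotometrySession-class].
#' @param tracesPath,eventsPath file paths.
#' @return `writePhotometryCSV` returns the paths invisibly;
#'   `readPhotometryCSV` returns a [PhotometrySession-class] (frame rate
#'   recovered from the time stamps).
#' @export
writePhotometryCSV <- function(session, tracesPath, eventsPath) {
  stopifnot(is(session, "PhotometrySession"))
  tr <- roiTraces(session)
  t <- (seq_len(ncol(tr)) - 1) / fsHz(session)
  long <- do.call(rbind, lapply(seq_len(nrow(tr)), function(r) {
    data.frame(time_s = t, roi_id = session@roiIds[r], dff = tr[r, ])
  }))
  utils::write.csv(long, tracesPath, row.names = FALSE)
  utils::write.csv(stimEvents(session), eventsPath, row.names = FALSE)
  invisible(c(tracesPath, eventsPath))
}

#' @rdname writePhotometryCSV
#' @export
readPhotometryCSV <- function(tracesPath, eventsPath) {
  long <- utils::read.csv(.checkFile(tracesPath))
  events <- utils::read.csv(.checkFile(eventsPath))
  rois <- unique(long$roi_id)
  t <- sort(unique(long$time_s))
  fr <- 1 / stats::median(diff(t))
  traces <- t(vapply(rois, function(r) {
    sub <- long[long$roi_id == r, ]
    sub$dff[order(sub$time_s)]
  }, numeric(length(t))))
  PhotometrySession(traces, frameRateHz = fr, events = events,
                    roiIds = as.character(rois))
}

#' Write / read a behavioral trajectory CSV
#'
#' Columns: `time_s`, `nose_x_cm`, `nose_y_cm`.
#'
#' @param session a [BehaviorSession-class].
#' @param path file path.
#' @param stimSide,trialType,sessionType descriptors attached on read.
#' @return `writeTrajectoryCSV` returns `path` invisibly;
#'   `readTrajectoryCSV` returns a [BehaviorSession-class].
#' @export
writeTrajectoryCSV <- function(session, path) {
  stopifnot(is(session, "BehaviorSession"))
  utils::write.csv(trajectory(session), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrajectoryCSV
#' @export
readTrajectoryCSV <- function(path, stimSide = "none",
                              trialType = "habituation",
                              sessionType = "ToyToy") {
  BehaviorSession(utils::read.csv(.checkFile(path)), stimSide = stimSide,
                  trialType = trialType, sessionType = sessionType)
}

#' Persist / load a spectrogram as a CSV bundle
#'
#' Writes the power matrix in long format (`time_s`, `freq_hz`, `power`,
#' `outlier`) with window metadata in a YAML sidecar (`<path>.meta.yaml`).
#'
#' @param spec a [Spectrogram-class].
#' @param path CSV file path.
#' @return `writeSpectrogramCSV` returns `path` invisibly;
#'   `readSpectrogramCSV` returns a [Spectrogram-class].
#' @export
writeSpectrogramCSV <- function(spec, path) {
  stopifnot(is(spec, "Spectrogram"))
  t <- specTimes(spec)
  f <- specFreqs(spec)
  long <- data.frame(
    time_s = rep(t, times = length(f)),
    freq_hz = rep(f, each = length(t)),
    power = as.vector(specPower(spec)),
    outlier = rep(outlierMask(spec), times = length(f))
  )
  utils::write.csv(long, path, row.names = FALSE)
  yaml::write_yaml(list(window_s = spec@windowS,
                        overlap_frac = spec@overlapFrac,
                        channel = channelLabel(spec)),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname writeSpectrogramCSV
#' @export
readSpectrogramCSV <- function(path) {
  long <- utils::read.csv(.checkFile(path))
  meta <- yaml::read_yaml(paste0(.checkFile(path), ".meta.yaml"))
  t <- sort(unique(long$time_s))
  f <- sort(unique(long$freq_hz))
  long <- long[order(long$freq_hz, long$time_s), ]
  Spectrogram(matrix(long$power, nrow = length(t), ncol = length(f)),
              timesS = t, freqsHz = f,
              windowS = if (is.null(meta$window_s)) NA_real_ else meta$window_s,
              overlapFrac = if (is.null(meta$overlap_frac)) NA_real_
                            else meta$overlap_frac,
              outlierMask = long$outlier[seq_along(t)],
              channelLabel = meta$channel)
}
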