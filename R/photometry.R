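# Dopamine-sensor (dF/F) trial analysis: detrend, baseline-normalize,
# parse into trials, bin, and summarize.

#' Quadratic detrend of a photometry trace
#'
#' Fits a least-squares second-degree polynomial in time to the full trace
#' (the photobleaching model) and subtracts it. The output is zero-mean up
#' to fit residual.
#'
#' @param trace numeric dF/F vector (>= 3 frames, all finite).
#' @return Detrended numeric vector.
#' @export
detrendQuadratic <- function(trace) {
  bad <- which(!is.finite(trace))
  if (length(bad))
    stop("trace has non-finite frames at indices: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  n <- length(trace)
  if (n < 3) stop("need at least 3 frames to fit a quadratic", call. = FALSE)
  t <- seq_len(n) - 1
  fit <- stats::lm.fit(cbind(1, t, t^2), trace)
  as.numeric(fit$residuals)
}

# Frame indices of the union of pre-onset baseline windows.
.baselineFrames <- function(n, events, preS, frameRateHz) {
  sel <- logical(n)
  t <- (seq_len(n) - 1) / frameRateHz
  for (i in seq_len(nrow(events))) {
    on <- events$onset_s[i]
    if (on - preS < -1e-9)
      stop("event at ", on, " s lacks ", preS, " s of pre-onset data",
           call. = FALSE)
    sel <- sel | (t >= on - preS & t < on)
  }
  if (!any(sel)) stop("baseline windows contain no frames", call. = FALSE)
  which(sel)
}

#' Normalize a trace to its pre-stimulation baseline
#'
#' Maps the mean over the union of all pre-onset baseline windows to 1.
#' Because a detrended dF/F trace is near zero-mean, the divisor is taken
#' from the raw trace: with `m` the baseline mean of `baselineRef` (the raw
#' trace; defaults to `trace` itself) and `b` the baseline mean of `trace`,
#' the result is `(trace - b + m) / m`. This is invariant to positive
#' rescaling of the raw trace, and the baseline level maps exactly to 1.
#'
#' @param trace numeric vector (typically detrended dF/F).
#' @param events data.frame of stimulation epochs (`onset_s`, `offset_s`).
#' @param preS baseline window length before each onset (s), default 5.
#' @param frameRateHz frames per second.
#' @param baselineRef raw trace supplying the divisor; default `trace`.
#' @return Normalized numeric vector (baseline = 1).
#' @export
normalizeToBaseline <- function(trace, events, preS = 5, frameRateHz = 20,
                                baselineRef = trace) {
  idx <- .baselineFrames(length(trace), events, preS, frameRateHz)
  m <- mean(baselineRef[idx])
  if (!is.finite(m) || m <= 0)
    stop("baseline divisor is not strictly positive (", signif(m, 4),
         "); cannot normalize", call. = FALSE)
  b <- mean(trace[idx])
  (trace - b + m) / m
}

#' Parse a trace into onset-aligned trials
#'
#' Cuts a window from `preS` before to `postS` after each stimulation onset
#' and stacks the windows as rows of a [TrialMatrix-class], aligned at
#' t = 0. Trials whose window would be truncated by the session edge are
#' dropped with a warning.
#'
#' @param trace numeric vector (typically normalized dF/F).
#' @param events data.frame (`onset_s`, `offset_s`).
#' @param preS,postS window extent around onset (s), defaults 5 and 10.
#' @param frameRateHz frames per second.
#' @return A [TrialMatrix-class].
#' @export
parseTrials <- function(trace, events, preS = 5, postS = 10,
                        frameRateHz = 20) {
  nPre <- round(preS * frameRateHz)
  nPost <- round(postS * frameRateHz)
  n <- length(trace)
  keep <- logical(nrow(events))
  rows <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    i0 <- round(events$onset_s[i] * frameRateHz) + 1L   # frame at onset
    lo <- i0 - nPre
    hi <- i0 + nPost - 1L
    if (lo < 1L || hi > n) {
      warning("trial at ", events$onset_s[i],
              " s dropped: window extends past the session edge")
      next
    }
    keep[i] <- TRUE
    rows[[i]] <- trace[lo:hi]
  }
  if (!any(keep)) stop("no trial has a complete window", call. = FALSE)
  stimDur <- stats::median(events$offset_s - events$onset_s)
  new("TrialMatrix",
      data = do.call(rbind, rows[keep]),
      timesS = (seq_len(nPre + nPost) - 1 - nPre) / frameRateHz,
      preS = preS, postS = postS, stimDurS = stimDur,
      onsetsS = events$onset_s[keep])
}

#' Per-second binned response during stimulation
#'
#' Means of the normalized response in consecutive `binS`-second bins across
#' the stimulation window `[0, stimDurS)` of each trial (5 bins per trial at
#' the 5 s / 1 s defaults), plus the trial average and SEM per bin.
#'
#' @param tm a [TrialMatrix-class].
#' @param binS bin width (s), default 1.
#' @return list: `binStartS`, `perTrial` (trials x bins), `trialMean`,
#'   `sem`.
#' @export
binnedResponse <- function(tm, binS = 1) {
  stopifnot(is(tm, "TrialMatrix"))
  if (tm@stimDurS < binS)
    stop("stimulation window is shorter than one bin", call. = FALSE)
  nBins <- floor(tm@stimDurS / binS)
  t <- trialTimes(tm)
  perTrial <- sapply(seq_len(nBins), function(b) {
    idx <- t >= (b - 1) * binS & t < b * binS
    rowMeans(trialData(tm)[, idx, drop = FALSE])
  })
  perTrial <- matrix(perTrial, nrow = nTrials(tm))
  mu <- colMeans(perTrial)
  sem <- apply(perTrial, 2, stats::sd) / sqrt(nrow(perTrial))
  list(binStartS = (seq_len(nBins) - 1) * binS, perTrial = perTrial,
       trialMean = mu, sem = sem)
}

#' Session-averaged stimulation response
#'
#' Mean normalized response over the stimulation window `[0, stimDurS)` of
#' each trial (the per-trial observations used for statistics) and their
#' session mean.
#'
#' Because the normalized baseline sits at 1, the evoked component of each
#' trial is its mean minus 1; `perTrialEvoked` and `sessionEvoked` report
#' that baseline-subtracted response alongside the raw means.
#'
#' @param tm a [TrialMatrix-class].
#' @return list: `perTrial`, `sessionMean`, `perTrialEvoked`,
#'   `sessionEvoked`.
#' @export
sessionAverage <- function(tm) {
  stopifnot(is(tm, "TrialMatrix"))
  t <- trialTimes(tm)
  idx <- t >= 0 & t < tm@stimDurS
  perTrial <- rowMeans(trialData(tm)[, idx, drop = FALSE])
  list(perTrial = perTrial, sessionMean = mean(perTrial),
       perTrialEvoked = perTrial - 1, sessionEvoked = mean(perTrial) - 1)
}

#' Full photometry processing pipeline
#'
#' Runs the fixed processing order on a session: quadratic detrend per ROI,
#' baseline normalization per ROI (divisor from the raw trace), equal-weight
#' averaging across ROIs, trial parsing, per-second binning, and the session
#' average. The order matters: normalizing before detrending lets the
#' bleaching trend contaminate the baseline estimate, which is why the
#' pipeline does not expose a reordering switch.
#'
#' @param session a [PhotometrySession-class].
#' @param preS,postS trial window (s), defaults 5 and 10.
#' @param binS bin width (s), default 1.
#' @return list: `trials` ([TrialMatrix-class]), `bins` (from
#'   [binnedResponse()]), `summary` (from [sessionAverage()]),
#'   `normalized` (the ROI-averaged normalized trace).
#' @export
photometryPipeline <- function(session, preS = 5, postS = 10, binS = 1) {
  stopifnot(is(session, "PhotometrySession"))
  ev <- stimEvents(session)
  if (!nrow(ev)) stop("session has no stimulation events", call. = FALSE)
  fr <- fsHz(session)
  traces <- roiTraces(session)
  norm <- t(apply(traces, 1, function(raw) {
    det <- detrendQuadratic(raw)
    normalizeToBaseline(det, ev, preS, fr, baselineRef = raw)
  }))
  avg <- colMeans(norm)
  tm <- parseTrials(avg, ev, preS, postS, fr)
  list(trials = tm, bins = binnedResponse(tm, binS),
       summary = sessionAverage(tm), normalized = avg)
}
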