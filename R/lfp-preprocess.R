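# Filtering, STFT, line-noise handling and two-stage spectrogram cleaning.

#' Zero-phase Chebyshev Type II band-pass filter
#'
#' Applies an order-4 Chebyshev Type II band-pass (40 dB stopband
#' attenuation) forward and backward (zero phase) to every channel.
#' Passband gain is within 1 dB of unity at band center.
#'
#' @param rec an [LFPRecording-class].
#' @param lowHz,highHz band edges (Hz); must satisfy
#'   `0 < lowHz < highHz < fsHz/2`.
#' @param order filter order (default 4).
#' @param stopbandDb stopband attenuation (dB, default 40).
#' @return A filtered [LFPRecording-class].
#' @examples
#' rec <- LFPRecording(matrix(sin(2 * pi * 20 * (0:9999) / 1000), 1), 1000)
#' filt <- bandPass(rec, 1, 250)
#' @export
bandPass <- function(rec, lowHz, highHz, order = 4, stopbandDb = 40) {
  stopifnot(is(rec, "LFPRecording"))
  fs <- fsHz(rec)
  if (!(lowHz > 0 && lowHz < highHz && highHz < fs / 2))
    stop("band (", lowHz, ", ", highHz,
         ") Hz must satisfy 0 < low < high < fs/2 = ", fs / 2, call. = FALSE)
  bf <- signal::cheby2(order, stopbandDb, c(lowHz, highHz) * 2 / fs,
                       type = "pass")
  out <- t(apply(lfpData(rec), 1, function(x) signal::filtfilt(bf, x)))
  LFPRecording(out, fsHz = fs, channelLabels = channelLabels(rec),
               startTimeS = rec@startTimeS)
}

#' Short-time Fourier power spectrogram
#'
#' One-sided power spectral density (uV^2/Hz) of one channel using a Hann
#' window. Frequency-bin spacing is `1/windowS` Hz; the time step between
#' bin centers is `windowS * (1 - overlapFrac)` seconds. Whole-session
#' spectrograms conventionally use a 5 s window at 50% overlap;
#' stimulation-trial analysis uses 1 s bins at 50% overlap.
#'
#' @param rec an [LFPRecording-class].
#' @param windowS window length (s), default 5.
#' @param overlapFrac fractional overlap in `[0, 1)`, default 0.5.
#' @param channel channel index or label (default first channel).
#' @return A [Spectrogram-class].
#' @examples
#' rec <- LFPRecording(matrix(sin(2 * pi * 20 * (0:29999) / 1000), 1), 1000)
#' sp <- computeSTFT(rec, windowS = 1)
#' specFreqs(sp)[1:5]
#' @export
computeSTFT <- function(rec, windowS = 5, overlapFrac = 0.5, channel = 1) {
  stopifnot(is(rec, "LFPRecording"))
  fs <- fsHz(rec)
  L <- round(windowS * fs)
  if (L < 2) stop("window must span at least 2 samples", call. = FALSE)
  if (overlapFrac < 0 || overlapFrac >= 1)
    stop("overlapFrac must lie in [0, 1)", call. = FALSE)
  x <- lfpData(rec, channel)
  n <- length(x)
  if (n < L)
    stop("recording (", n, " samples) is shorter than one window (", L,
         " samples)", call. = FALSE)
  hop <- max(1L, round(L * (1 - overlapFrac)))
  starts <- seq(1L, n - L + 1L, by = hop)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, L - 1) / L))  # periodic Hann
  seg <- vapply(starts, function(s) x[s:(s + L - 1L)] * w, numeric(L))
  X <- stats::mvfft(seg)
  nf <- floor(L / 2) + 1L
  P <- abs(X[seq_len(nf), , drop = FALSE])^2 / (fs * sum(w^2))
  scale2 <- rep(2, nf)
  scale2[1] <- 1
  if (L %% 2 == 0) scale2[nf] <- 1
  P <- P * scale2
  lab <- if (is.character(channel)) channel else channelLabels(rec)[channel]
  Spectrogram(
    power = t(P),
    timesS = rec@startTimeS + (starts - 1 + (L - 1) / 2) / fs,
    freqsHz = (seq_len(nf) - 1) * fs / L,
    windowS = windowS, overlapFrac = overlapFrac,
    channelLabel = lab
  )
}

#' Remove power-line noise from a spectrogram
#'
#' Replaces power at every frequency bin whose center lies inside `band`
#' (59-61 Hz by default) with the value of the nearest out-of-band bin,
#' separately for each time bin (nearest interpolation along frequency).
#'
#' @param spec a [Spectrogram-class].
#' @param band numeric length-2, the closed band (Hz) to excise.
#' @return A [Spectrogram-class] with in-band bins filled.
#' @export
removeLineNoise <- function(spec, band = c(59, 61)) {
  stopifnot(is(spec, "Spectrogram"))
  f <- specFreqs(spec)
  inBand <- f >= band[1] & f <= band[2]
  if (!any(inBand)) {
    warning("no frequency bins inside [", band[1], ", ", band[2],
            "] Hz; spectrogram returned unchanged")
    return(spec)
  }
  if (all(inBand))
    stop("band [", band[1], ", ", band[2],
         "] Hz covers every frequency bin", call. = FALSE)
  outIdx <- which(!inBand)
  P <- specPower(spec)
  for (j in which(inBand)) {
    nearest <- outIdx[which.min(abs(f[outIdx] - f[j]))]
    P[, j] <- P[, nearest]
  }
  methods::initialize(spec, power = P)
}

# Rolling one-sided high threshold: window median + k * 1.4826 * window MAD,
# window centered on each bin (truncated at edges). MAD = 0 flags nothing.
.rollingMadFlags <- function(m, halfBins, k) {
  n <- length(m)
  flag <- logical(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - halfBins)
    hi <- min(n, i + halfBins)
    win <- m[lo:hi]
    med <- stats::median(win)
    s <- 1.4826 * stats::median(abs(win - med))
    if (s > 0) flag[i] <- m[i] > med + k * s
  }
  flag
}

#' Two-stage spectrogram outlier rejection
#'
#' Stage 1 screens the mean-power-across-frequencies time series for large
#' deviations (greater than its mean plus `globalK` standard deviations);
#' flagged time bins have their power columns replaced with the
#' per-frequency median over non-flagged bins. Stage 2 re-screens the
#' mean-power series of the repaired spectrogram with a sliding local
#' criterion: a bin is flagged when it exceeds its centered `windowMin`
#' minute window's median plus `madK` times the scaled (1.4826) median
#' absolute deviation (one-sided high; a zero-MAD window flags nothing).
#' Stage-2 bins are replaced by the most recent preceding clean bin
#' (forward fill; leading bins fall back to the nearest following clean
#' bin). The returned mask is the union of both stages.
#'
#' Spectrograms shorter than one stage-2 window run stage 1 only, with a
#' warning.
#'
#' @param spec a [Spectrogram-class].
#' @param globalK stage-1 threshold in SDs (default 4).
#' @param madK stage-2 threshold in scaled MADs (default 5).
#' @param windowMin stage-2 window length in minutes (default 5).
#' @return A [Spectrogram-class] with repaired power and `outlierMask` set.
#' @export
detectOutliers <- function(spec, globalK = 4, madK = 5, windowMin = 5) {
  stopifnot(is(spec, "Spectrogram"))
  P <- specPower(spec)
  times <- specTimes(spec)
  nT <- nrow(P)

  m <- rowMeans(P)
  sdM <- stats::sd(m)
  flag1 <- if (nT >= 2 && is.finite(sdM) && sdM > 0)
    m > mean(m) + globalK * sdM else rep(FALSE, nT)
  if (all(flag1))
    stop("every time bin flagged as an outlier; spectrogram is degenerate",
         call. = FALSE)
  if (any(flag1)) {
    colMed <- apply(P[!flag1, , drop = FALSE], 2, stats::median)
    P[flag1, ] <- matrix(colMed, nrow = sum(flag1), ncol = ncol(P),
                         byrow = TRUE)
  }

  flag2 <- rep(FALSE, nT)
  spanS <- if (nT > 1) times[nT] - times[1] else 0
  if (spanS < windowMin * 60) {
    warning("spectrogram spans ", round(spanS), " s < ", windowMin,
            " min; local (stage-2) outlier screening skipped")
  } else {
    binStep <- stats::median(diff(times))
    halfBins <- max(1L, round(windowMin * 60 / binStep / 2))
    m2 <- rowMeans(P)
    flag2 <- .rollingMadFlags(m2, halfBins, madK)
    mask <- flag1 | flag2
    if (all(mask))
      stop("every time bin flagged as an outlier; spectrogram is degenerate",
           call. = FALSE)
    if (any(flag2)) {
      clean <- which(!mask)
      for (i in which(flag2)) {
        prev <- clean[clean < i]
        src <- if (length(prev)) max(prev) else min(clean[clean > i])
        P[i, ] <- P[src, ]
      }
    }
  }

  methods::initialize(spec, power = P, outlierMask = flag1 | flag2)
}
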