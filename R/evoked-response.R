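# Stimulation-evoked band power: quantification, inclusion screening,
# repeat averaging, and Morse-wavelet visualization.

#' Mean band power in a time window
#'
#' Mean power over all spectrogram cells whose frequency-bin center falls in
#' the closed band `[centerHz - halfWidthHz, centerHz + halfWidthHz]` and
#' whose time-bin center falls in the half-open window `[tWindow[1],
#' tWindow[2])`.
#'
#' @param spec a [Spectrogram-class].
#' @param centerHz band center (Hz).
#' @param halfWidthHz band half-width (Hz), default 1.
#' @param tWindow numeric length-2 time window (s); default the whole span.
#' @return Mean power (uV^2/Hz), a scalar.
#' @export
bandPower <- function(spec, centerHz, halfWidthHz = 1, tWindow = NULL) {
  stopifnot(is(spec, "Spectrogram"))
  f <- specFreqs(spec)
  t <- specTimes(spec)
  if (is.null(tWindow)) tWindow <- c(t[1], t[length(t)] + 1e-9)
  fIdx <- which(f >= centerHz - halfWidthHz & f <= centerHz + halfWidthHz)
  tIdx <- which(t >= tWindow[1] & t < tWindow[2])
  if (!length(fIdx))
    stop("no frequency bins in band ", centerHz, " +/- ", halfWidthHz,
         " Hz", call. = FALSE)
  if (!length(tIdx))
    stop("no time bins in window [", tWindow[1], ", ", tWindow[2], ") s",
         call. = FALSE)
  mean(specPower(spec)[tIdx, fIdx])
}

#' Stimulation/baseline power ratio per epoch
#'
#' For every stimulation epoch, computes the mean power in a +/-
#' `halfWidthHz` band around the epoch's drive frequency during the
#' stimulation window and during the pre-onset baseline window (both
#' epoch-relative: the defaults are 0-120 s after onset versus the 30 s
#' immediately preceding onset), and their ratio. Results are reported both
#' as the raw ratio and as `ratio - 1`, so "no change from baseline" is 0.
#'
#' Epochs without enough pre-onset data are skipped with a warning; epochs
#' with zero baseline power are marked invalid.
#'
#' @param spec a [Spectrogram-class] (one channel). Stimulation-trial
#'   analysis conventionally uses the 1 s-bin STFT.
#' @param protocol a [StimProtocol-class].
#' @param stimWindowS,baseWindowS epoch-relative windows (s), defaults
#'   `c(0, 120)` and `c(-30, 0)`.
#' @param halfWidthHz band half-width (Hz), default 1.
#' @return data.frame with one row per epoch: `channel`, `freq_hz`,
#'   `repeat_idx`, `onset_s`, `stim_power`, `base_power`, `ratio`,
#'   `ratio_minus_1`, `deviation_score` (filled by [inclusionFilter()]),
#'   `included`, `valid`.
#' @export
powerRatio <- function(spec, protocol, stimWindowS = c(0, 120),
                       baseWindowS = c(-30, 0), halfWidthHz = 1) {
  stopifnot(is(spec, "Spectrogram"), is(protocol, "StimProtocol"))
  ep <- epochs(protocol)
  # data coverage starts half a window before the first bin center
  halfSpan <- if (is.finite(spec@windowS)) spec@windowS / 2
              else stats::median(diff(specTimes(spec))) / 2
  t0 <- specTimes(spec)[1] - halfSpan
  rows <- vector("list", nrow(ep))
  for (i in seq_len(nrow(ep))) {
    on <- ep$onset_s[i]
    if (on + baseWindowS[1] < t0 - 1e-9) {
      warning("epoch at ", on, " s skipped: needs ", -baseWindowS[1],
              " s of pre-onset data")
      next
    }
    sp <- bandPower(spec, ep$freq_hz[i], halfWidthHz, on + stimWindowS)
    bp <- bandPower(spec, ep$freq_hz[i], halfWidthHz, on + baseWindowS)
    valid <- bp > 0
    rows[[i]] <- data.frame(
      channel = channelLabel(spec), freq_hz = ep$freq_hz[i],
      repeat_idx = ep$repeat_idx[i], onset_s = on,
      stim_power = sp, base_power = bp,
      ratio = if (valid) sp / bp else NA_real_,
      ratio_minus_1 = if (valid) sp / bp - 1 else NA_real_,
      deviation_score = NA_real_, included = valid, valid = valid
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop("no epoch had sufficient pre-onset data", call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Inclusion screen on power ratios
#'
#' Within each (channel, frequency) group of repeats, computes the group
#' mean and SD of the ratio and marks repeats whose ratio deviates from the
#' group mean by strictly more than `k` SDs as excluded
#' (`included = FALSE`). `deviation_score` (signed SDs from the group mean)
#' is populated for every row. A zero-SD group excludes nothing; a group of
#' size 1 passes through with a warning.
#'
#' @param results data.frame from [powerRatio()] (rows from several channels
#'   may be concatenated).
#' @param k exclusion threshold in SDs (default 2).
#' @return The input with `deviation_score` and `included` filled in.
#' @export
inclusionFilter <- function(results, k = 2) {
  stopifnot(all(c("channel", "freq_hz", "ratio") %in% names(results)))
  key <- interaction(results$channel, results$freq_hz, drop = TRUE)
  for (g in levels(key)) {
    idx <- which(key == g & results$valid)
    if (!length(idx)) next
    r <- results$ratio[idx]
    if (length(r) == 1) {
      warning("group ", g, " has a single repeat; retained unscreened")
      results$deviation_score[idx] <- 0
      next
    }
    mu <- mean(r)
    sdev <- stats::sd(r)
    if (sdev > 0) {
      z <- (r - mu) / sdev
      results$deviation_score[idx] <- z
      results$included[idx] <- abs(z) <= k  # strict > excludes
    } else {
      results$deviation_score[idx] <- 0
    }
  }
  results
}

#' Average power ratios over included repeats
#'
#' @param results screened data.frame from [inclusionFilter()].
#' @return data.frame per (channel, frequency): `mean_ratio`,
#'   `mean_ratio_minus_1`, `n_included`. Groups with no included repeat are
#'   reported missing (dropped) with a warning.
#' @export
averageRepeats <- function(results) {
  key <- interaction(results$channel, results$freq_hz, drop = TRUE)
  rows <- lapply(levels(key), function(g) {
    sub <- results[key == g, , drop = FALSE]
    inc <- sub[sub$included & sub$valid, , drop = FALSE]
    if (!nrow(inc)) {
      warning("group ", g, " has no included repeats; reported as missing")
      return(NULL)
    }
    data.frame(channel = inc$channel[1], freq_hz = inc$freq_hz[1],
               mean_ratio = mean(inc$ratio),
               mean_ratio_minus_1 = mean(inc$ratio_minus_1),
               n_included = nrow(inc))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out <- out[order(out$channel, out$freq_hz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mean ratio by presentation position
#'
#' Tabulates the mean power ratio per presentation position (repeat index)
#' within each channel and frequency, for downstream order-effect testing.
#' No inferential statistic is computed.
#'
#' @param results data.frame from [powerRatio()].
#' @return data.frame: `channel`, `freq_hz`, `position`, `mean_ratio`, `n`.
#' @export
presentationOrderEffect <- function(results) {
  agg <- stats::aggregate(
    ratio ~ channel + freq_hz + repeat_idx,
    data = results[results$valid, , drop = FALSE],
    FUN = mean
  )
  n <- stats::aggregate(
    ratio ~ channel + freq_hz + repeat_idx,
    data = results[results$valid, , drop = FALSE],
    FUN = length
  )
  out <- data.frame(channel = agg$channel, freq_hz = agg$freq_hz,
                    position = agg$repeat_idx, mean_ratio = agg$ratio,
                    n = n$ratio)
  out[order(out$channel, out$freq_hz, out$position), , drop = FALSE]
}

#' Generalized Morse wavelet time-frequency magnitude
#'
#' Continuous wavelet transform with generalized Morse wavelets
#' (gamma = 3, beta = 20 by default) over logarithmically spaced
#' frequencies, returning the transform magnitude for visualization of
#' stimulation-evoked responses. The magnitude is linear in signal
#' amplitude; quantitative band-power analysis uses [computeSTFT()] and
#' [powerRatio()] instead.
#'
#' @param rec an [LFPRecording-class].
#' @param freqRangeHz numeric length-2, frequency range (Hz), inside
#'   `(0, fs/2)`.
#' @param nFreqs number of (log-spaced) frequencies, default 48.
#' @param gamma,beta Morse shape parameters.
#' @param channel channel index or label.
#' @param timeStride keep every `timeStride`-th sample along time
#'   (default 1 = all samples).
#' @return A [Spectrogram-class] whose `power` slot holds the magnitude
#'   (time x frequency).
#' @export
morseSpectrogram <- function(rec, freqRangeHz, nFreqs = 48, gamma = 3,
                             beta = 20, channel = 1, timeStride = 1L) {
  stopifnot(is(rec, "LFPRecording"))
  fs <- fsHz(rec)
  if (freqRangeHz[1] <= 0 || freqRangeHz[2] >= fs / 2 ||
      freqRangeHz[1] >= freqRangeHz[2])
    stop("frequency range must lie inside (0, fs/2) with min < max",
         call. = FALSE)
  x <- lfpData(rec, channel)
  n <- length(x)
  X <- stats::fft(x)
  wk <- 2 * pi * (seq_len(n) - 1) / n       # radians/sample, [0, 2pi)
  pos <- wk > 0 & wk <= pi
  wp <- (beta / gamma)^(1 / gamma)          # peak radian frequency
  freqs <- exp(seq(log(freqRangeHz[1]), log(freqRangeHz[2]),
                   length.out = nFreqs))
  keep <- seq(1L, n, by = as.integer(timeStride))
  mag <- matrix(0, nrow = length(keep), ncol = nFreqs)
  peakVal <- wp^beta * exp(-wp^gamma)
  for (j in seq_len(nFreqs)) {
    s <- wp / (2 * pi * freqs[j] / fs)      # scale mapping peak -> target
    H <- numeric(n)
    sw <- s * wk[pos]
    H[pos] <- 2 * (sw^beta * exp(-sw^gamma)) / peakVal
    y <- stats::fft(X * H, inverse = TRUE) / n
    mag[, j] <- Mod(y)[keep]
  }
  Spectrogram(power = mag,
              timesS = rec@startTimeS + (keep - 1) / fs,
              freqsHz = freqs, windowS = NA_real_, overlapFrac = NA_real_,
              channelLabel = if (is.character(channel)) channel
                             else channelLabels(rec)[channel])
}
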