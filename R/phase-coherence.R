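# Narrowband instantaneous phase and PLV / imaginary-PLV coherence.

# Analytic signal by the standard FFT construction: negative frequencies
# zeroed, positive doubled.
.analyticSignal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Narrowband instantaneous phase
#'
#' Zero-phase band-pass at `centerHz +/- halfWidthHz` (Chebyshev Type II,
#' order 2 for these 2 Hz-wide bands) followed by the instantaneous phase of
#' the analytic signal. The first and last `edgeFrac` of samples are flagged
#' in the edge mask and excluded from phase averaging, suppressing filter
#' transients.
#'
#' @param rec an [LFPRecording-class] longer than 10 cycles of `centerHz`.
#' @param centerHz band center (Hz).
#' @param halfWidthHz band half-width (Hz), default 1.
#' @param channel channel index or label.
#' @param edgeFrac edge fraction to flag (default 0.05).
#' @param order filter order (default 2).
#' @return A [PhaseSeries-class].
#' @export
narrowbandPhase <- function(rec, centerHz, halfWidthHz = 1, channel = 1,
                            edgeFrac = 0.05, order = 2) {
  stopifnot(is(rec, "LFPRecording"))
  fs <- fsHz(rec)
  lo <- centerHz - halfWidthHz
  hi <- centerHz + halfWidthHz
  if (!(lo > 0 && hi < fs / 2))
    stop("band ", lo, "-", hi, " Hz must lie inside (0, fs/2)", call. = FALSE)
  if (duration(rec) < 10 / centerHz)
    stop("recording must span at least 10 cycles of ", centerHz, " Hz",
         call. = FALSE)
  bf <- signal::cheby2(order, 40, c(lo, hi) * 2 / fs, type = "pass")
  y <- signal::filtfilt(bf, lfpData(rec, channel))
  ph <- Arg(.analyticSignal(y))
  n <- length(ph)
  # filter transients decay within ~1/bandwidth; cap the flagged margin at
  # 2 s so long recordings keep their early baseline windows usable
  nEdge <- min(floor(edgeFrac * n), round(2 * fs))
  edge <- rep(FALSE, n)
  if (nEdge > 0) edge[c(seq_len(nEdge), n - seq_len(nEdge) + 1L)] <- TRUE
  new("PhaseSeries", timesS = sampleTimes(rec), phaseRad = ph,
      centerHz = centerHz, halfWidthHz = halfWidthHz,
      channelLabel = if (is.character(channel)) channel
                     else channelLabels(rec)[channel],
      edgeMask = edge)
}

# Interior phase-difference samples of two aligned series within a window,
# with an additional per-window edge exclusion.
.phaseDiffWindow <- function(a, b, tWindow = NULL, windowEdgeFrac = 0.05) {
  stopifnot(is(a, "PhaseSeries"), is(b, "PhaseSeries"))
  if (length(a@timesS) != length(b@timesS) ||
      max(abs(a@timesS - b@timesS)) > 1e-9)
    stop("phase series are not sample-aligned", call. = FALSE)
  if (abs(a@centerHz - b@centerHz) > 1e-9 ||
      abs(a@halfWidthHz - b@halfWidthHz) > 1e-9)
    stop("phase series were extracted in different bands", call. = FALSE)
  sel <- !(a@edgeMask | b@edgeMask)
  if (!is.null(tWindow))
    sel <- sel & a@timesS >= tWindow[1] & a@timesS < tWindow[2]
  idx <- which(sel)
  if (!length(idx))
    stop("window contains no interior samples", call. = FALSE)
  if (windowEdgeFrac > 0 && length(idx) > 2) {
    nDrop <- floor(windowEdgeFrac * length(idx))
    if (nDrop > 0)
      idx <- idx[(nDrop + 1):(length(idx) - nDrop)]
  }
  a@phaseRad[idx] - b@phaseRad[idx]
}

.meanPhasor <- function(dphi) mean(exp(1i * dphi))

#' Phase locking value
#'
#' PLV between two narrowband phase series: the modulus of the
#' time-averaged unit phasor of the phase difference,
#' `|mean(exp(i * (phi_a - phi_b)))|`. 1 indicates perfect locking, values
#' near 0 independence.
#'
#' @param a,b aligned [PhaseSeries-class] objects in the same band.
#' @param tWindow optional half-open time window (s).
#' @param windowEdgeFrac fraction of window samples dropped at each end
#'   before averaging (default 0.05).
#' @return Scalar in `[0, 1]`.
#' @seealso [iplv()] for the volume-conduction-insensitive variant.
#' @export
plv <- function(a, b, tWindow = NULL, windowEdgeFrac = 0.05) {
  Mod(.meanPhasor(.phaseDiffWindow(a, b, tWindow, windowEdgeFrac)))
}

#' Imaginary phase locking value
#'
#' iPLV: the absolute imaginary part of the mean phase-difference phasor,
#' `|Im mean(exp(i * (phi_a - phi_b)))|`. Zero-lag (instantaneous) synchrony
#' such as volume conduction yields a purely real mean phasor and hence
#' iPLV = 0, so iPLV isolates noninstantaneous phase relationships.
#' Always `iplv(a, b) <= plv(a, b)`.
#'
#' @inheritParams plv
#' @return Scalar in `[0, 1]`.
#' @export
iplv <- function(a, b, tWindow = NULL, windowEdgeFrac = 0.05) {
  abs(Im(.meanPhasor(.phaseDiffWindow(a, b, tWindow, windowEdgeFrac))))
}

#' Stimulation/baseline coherence ratios per drive frequency
#'
#' For every drive frequency, extracts both channels' narrowband phases
#' (+/- `halfWidthHz`), computes PLV and iPLV during the epoch-relative
#' stimulation and baseline windows of each epoch, averages over epochs
#' (optionally restricted to repeats retained by the evoked-power inclusion
#' screen), and reports stimulation/baseline ratios, where 1 means no change
#' from baseline.
#'
#' @param rec an [LFPRecording-class] with two channels.
#' @param protocol a [StimProtocol-class].
#' @param freqs drive frequencies to analyze; default all in the protocol.
#' @param halfWidthHz band half-width (Hz), default 1.
#' @param stimWindowS,baseWindowS epoch-relative windows (s), defaults
#'   `c(0, 120)` and `c(-30, 0)`.
#' @param channels length-2 indices/labels of the channel pair.
#' @param includedRepeats optional data.frame (`freq_hz`, `repeat_idx`) of
#'   repeats to keep, e.g. derived from [inclusionFilter()] output; default
#'   all repeats.
#' @return list with `table` (data.frame per frequency: `freq_hz`,
#'   `plv_base`, `plv_stim`, `iplv_base`, `iplv_stim`, `plv_ratio`,
#'   `iplv_ratio`, `n_epochs`) and `phaseDiff` (per frequency, the pooled
#'   baseline and stimulation phase-difference samples for histogramming).
#' @export
coherenceRatio <- function(rec, protocol, freqs = NULL, halfWidthHz = 1,
                           stimWindowS = c(0, 120), baseWindowS = c(-30, 0),
                           channels = c(1, 2), includedRepeats = NULL) {
  stopifnot(is(rec, "LFPRecording"), is(protocol, "StimProtocol"))
  ep <- epochs(protocol)
  if (is.null(freqs)) freqs <- sort(unique(ep$freq_hz))
  rows <- vector("list", length(freqs))
  phaseDiff <- stats::setNames(vector("list", length(freqs)),
                               as.character(freqs))
  for (k in seq_along(freqs)) {
    f <- freqs[k]
    pa <- narrowbandPhase(rec, f, halfWidthHz, channels[1])
    pb <- narrowbandPhase(rec, f, halfWidthHz, channels[2])
    sub <- ep[ep$freq_hz == f, , drop = FALSE]
    if (!is.null(includedRepeats)) {
      keep <- paste(sub$freq_hz, sub$repeat_idx) %in%
        paste(includedRepeats$freq_hz, includedRepeats$repeat_idx)
      sub <- sub[keep, , drop = FALSE]
    }
    if (!nrow(sub)) next
    pb_ <- ps_ <- ib_ <- is_ <- numeric(nrow(sub))
    dBase <- dStim <- list()
    for (i in seq_len(nrow(sub))) {
      on <- sub$onset_s[i]
      db <- .phaseDiffWindow(pa, pb, on + baseWindowS)
      ds <- .phaseDiffWindow(pa, pb, on + stimWindowS)
      mb <- .meanPhasor(db)
      ms <- .meanPhasor(ds)
      pb_[i] <- Mod(mb); ps_[i] <- Mod(ms)
      ib_[i] <- abs(Im(mb)); is_[i] <- abs(Im(ms))
      dBase[[i]] <- db; dStim[[i]] <- ds
    }
    plvB <- mean(pb_); plvS <- mean(ps_)
    iplvB <- mean(ib_); iplvS <- mean(is_)
    rows[[k]] <- data.frame(
      freq_hz = f, plv_base = plvB, plv_stim = plvS,
      iplv_base = iplvB, iplv_stim = iplvS,
      plv_ratio = if (plvB > 0) plvS / plvB else NA_real_,
      iplv_ratio = if (iplvB > 0) iplvS / iplvB else NA_real_,
      n_epochs = nrow(sub)
    )
    phaseDiff[[as.character(f)]] <- list(
      base = unlist(dBase), stim = unlist(dStim))
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  list(table = table, phaseDiff = phaseDiff)
}

#' Phase-difference histogram
#'
#' Bins wrapped phase differences into `nBins` uniform bins over
#' `(-pi, pi]`; counts sum to the number of input samples.
#'
#' @param dphi numeric vector of phase differences (rad, any branch).
#' @param nBins number of bins (>= 4), default 36.
#' @return data.frame: `bin_center_rad`, `count`.
#' @export
phaseHistogram <- function(dphi, nBins = 36) {
  if (nBins < 4) stop("nBins must be >= 4", call. = FALSE)
  wrapped <- Arg(exp(1i * dphi))                 # (-pi, pi]
  idx <- ceiling((wrapped + pi) / (2 * pi) * nBins)
  idx[idx < 1] <- 1
  idx[idx > nBins] <- nBins
  counts <- tabulate(idx, nbins = nBins)
  edges <- seq(-pi, pi, length.out = nBins + 1)
  data.frame(bin_center_rad = (edges[-1] + edges[-(nBins + 1)]) / 2,
             count = counts)
}
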