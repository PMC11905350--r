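# Evoked band power, inclusion screening, repeat averaging, Morse wavelets.

test_that("band power averages the constructed bins", {
  flat <- flatSpectrogram(3.5)
  expect_equal(bandPower(flat, 20, 1), 3.5)
  expect_equal(bandPower(flat, 20, 1, c(10, 50)), 3.5)

  # ridge of 10 at 20 Hz on background 1; band 19-21 Hz holds 3 bins
  sp <- flatSpectrogram(1, nF = 50, freqStepHz = 1)
  P <- specPower(sp)
  P[, specFreqs(sp) == 20] <- 10
  ridge <- Spectrogram(P, specTimes(sp), specFreqs(sp))
  expect_equal(bandPower(ridge, 20, 1), (10 + 1 + 1) / 3)
  expect_error(bandPower(ridge, 200, 1), "band")
})

test_that("the +/-1 Hz band holds exactly 3 bins on the 1 s-bin grid", {
  rec <- toneRecording(40, durationS = 20)
  sp <- computeSTFT(rec, windowS = 1, overlapFrac = 0.5)
  for (f in c(5, 10, 20, 40)) {
    nBins <- sum(specFreqs(sp) >= f - 1 & specFreqs(sp) <= f + 1)
    expect_identical(nBins, 3L)
  }
})

test_that("power ratio detects injected drive and is zero-centred without it", {
  sim <- simulateLFPPair(seed = 21, epochDurS = 30, gapS = 30,
                         noiseAmp = 20, stimAmp = 2 * 20 * sqrt(2))
  sp <- computeSTFT(sim$recording, 1, 0.5, 1)
  pr <- powerRatio(sp, sim$protocol, c(0, 30), c(-30, 0))
  expect_identical(nrow(pr), 12L)  # 4 frequencies x 3 repeats
  expect_true(all(pr$ratio_minus_1 > 0))
  expect_equal(pr$ratio_minus_1, pr$ratio - 1)

  # stim window vs baseline on a 40 Hz epoch: stim exceeds baseline power
  one <- pr[pr$freq_hz == 40, ][1, ]
  expect_gt(one$stim_power, one$base_power)
})

test_that("power ratio is invariant to global amplitude scaling", {
  sim <- simulateLFPPair(seed = 22, stimFreqsHz = c(10, 40), nRepeats = 1,
                         epochDurS = 30, gapS = 30, noiseAmp = 20,
                         stimAmp = 40)
  rec2 <- LFPRecording(lfpData(sim$recording) * 3.7,
                       fsHz = fsHz(sim$recording),
                       channelLabels = channelLabels(sim$recording))
  pr1 <- powerRatio(computeSTFT(sim$recording, 1, 0.5, 1), sim$protocol,
                    c(0, 30), c(-30, 0))
  pr2 <- powerRatio(computeSTFT(rec2, 1, 0.5, 1), sim$protocol,
                    c(0, 30), c(-30, 0))
  expect_equal(pr1$ratio, pr2$ratio, tolerance = 1e-9)
})

test_that("stronger drive yields larger ratios", {
  hits <- vapply(1:20, function(s) {
    a <- simulateLFPPair(seed = s, stimFreqsHz = 20, nRepeats = 1,
                         epochDurS = 30, gapS = 30, noiseAmp = 20,
                         stimAmp = 30)
    b <- simulateLFPPair(seed = s, stimFreqsHz = 20, nRepeats = 1,
                         epochDurS = 30, gapS = 30, noiseAmp = 20,
                         stimAmp = 60)
    ra <- powerRatio(computeSTFT(a$recording, 1, 0.5, 1), a$protocol,
                     c(0, 30), c(-30, 0))$ratio
    rb <- powerRatio(computeSTFT(b$recording, 1, 0.5, 1), b$protocol,
                     c(0, 30), c(-30, 0))$ratio
    rb > ra
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("inclusion screen excludes gross deviants and fills deviation scores", {
  mk <- function(r) data.frame(channel = "BLA", freq_hz = 20,
                               repeat_idx = seq_along(r), onset_s = 0,
                               stim_power = r, base_power = 1, ratio = r,
                               ratio_minus_1 = r - 1,
                               deviation_score = NA_real_,
                               included = TRUE, valid = TRUE)
  # group large enough that a gross outlier can exceed 2 sample SDs
  r <- c(rep(1, 9) + seq(-0.04, 0.04, by = 0.01), 30)
  out <- inclusionFilter(mk(r), k = 2)
  # oracle: direct mean/SD of the constructed ratios
  z <- (r - mean(r)) / sd(r)
  expect_equal(out$deviation_score, z)
  expect_identical(out$included, abs(z) <= 2)
  expect_false(out$included[10])

  # all equal: SD = 0, none excluded
  eq <- inclusionFilter(mk(rep(1.3, 5)), k = 2)
  expect_true(all(eq$included))
  expect_equal(eq$deviation_score, rep(0, 5))

  # k = Inf keeps everything
  inf <- inclusionFilter(mk(r), k = Inf)
  expect_true(all(inf$included))

  # singleton group passes through with a warning
  expect_warning(one <- inclusionFilter(mk(5)), "single repeat")
  expect_true(one$included)
})

test_that("a lone extreme repeat in a group of five cannot exceed 2 sample SDs", {
  # |z| is bounded by (n-1)/sqrt(n) ~ 1.79 at n = 5, so the screen keeps it
  mk <- function(r) data.frame(channel = "BLA", freq_hz = 20,
                               repeat_idx = seq_along(r), onset_s = 0,
                               stim_power = r, base_power = 1, ratio = r,
                               ratio_minus_1 = r - 1,
                               deviation_score = NA_real_,
                               included = TRUE, valid = TRUE)
  out <- inclusionFilter(mk(c(1.0, 1.1, 0.9, 1.0, 9.0)), k = 2)
  expect_true(all(out$included))
  expect_lt(max(abs(out$deviation_score)), 2)
})

test_that("repeat averaging uses included repeats only", {
  res <- data.frame(channel = "BLA", freq_hz = 20, repeat_idx = 1:3,
                    onset_s = 0, stim_power = c(2, 4, 100),
                    base_power = 1, ratio = c(2, 4, 100),
                    ratio_minus_1 = c(1, 3, 99), deviation_score = 0,
                    included = c(TRUE, TRUE, FALSE), valid = TRUE)
  avg <- averageRepeats(res)
  expect_equal(avg$mean_ratio, 3)
  expect_identical(avg$n_included, 2L)

  solo <- res[1, ]
  expect_equal(averageRepeats(solo)$mean_ratio, 2)

  none <- res
  none$included <- FALSE
  expect_warning(out <- averageRepeats(none), "missing")
  expect_null(out)
})

test_that("presentation-order table reflects constructed position effects", {
  res <- data.frame(channel = "BLA", freq_hz = rep(20, 3),
                    repeat_idx = 1:3, onset_s = 0,
                    stim_power = c(1, 2, 3), base_power = 1,
                    ratio = c(1, 2, 3), ratio_minus_1 = c(0, 1, 2),
                    deviation_score = 0, included = TRUE, valid = TRUE)
  tab <- presentationOrderEffect(res)
  expect_equal(tab$mean_ratio, c(1, 2, 3))
  expect_true(all(diff(tab$mean_ratio) > 0))

  one <- presentationOrderEffect(res[1, ])
  expect_identical(nrow(one), 1L)
})

test_that("Morse magnitude peaks at the tone frequency and scales linearly", {
  rec <- toneRecording(20, durationS = 8, fsHz = 500)
  m <- morseSpectrogram(rec, c(5, 60), nFreqs = 40, timeStride = 10L)
  interior <- specTimes(m) > 2 & specTimes(m) < 6
  ridge <- specFreqs(m)[apply(specPower(m)[interior, ], 1, which.max)]
  expect_lt(max(abs(ridge - 20)) / 20, 0.06)  # log grid spacing ~6%

  rec2 <- toneRecording(20, durationS = 8, fsHz = 500, amp = 2)
  m2 <- morseSpectrogram(rec2, c(5, 60), nFreqs = 40, timeStride = 10L)
  expect_equal(specPower(m2), 2 * specPower(m), tolerance = 1e-9)

  expect_error(morseSpectrogram(rec, c(5, 400)), "range")
})

test_that("Morse ridge follows a chirp upward", {
  fs <- 500
  t <- (seq_len(20 * fs) - 1) / fs
  # linear chirp 5 -> 40 Hz over 20 s
  x <- sin(2 * pi * (5 * t + (35 / 20) * t^2 / 2))
  rec <- LFPRecording(matrix(x, 1), fs)
  m <- morseSpectrogram(rec, c(4, 50), nFreqs = 48, timeStride = 25L)
  interior <- specTimes(m) > 2 & specTimes(m) < 18
  ridge <- specFreqs(m)[apply(specPower(m)[interior, ], 1, which.max)]
  expect_gt(cor(seq_along(ridge), ridge, method = "spearman"), 0.95)
})
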