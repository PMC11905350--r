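# Filtering, STFT, line-noise fill, and two-stage outlier rejection.

test_that("band-pass preserves in-band tones and rejects out-of-band content", {
  rec <- toneRecording(20, durationS = 10)
  out <- bandPass(rec, 1, 250)
  mid <- 3000:7000
  expect_equal(max(abs(lfpData(out, 1)[mid])), 1, tolerance = 0.01)

  # 0.1 Hz tone: attenuation computed from the designed filter response
  slow <- toneRecording(0.1, durationS = 60)
  att <- bandPass(slow, 1, 250)
  resid <- max(abs(lfpData(att, 1)[20000:40000]))
  expect_gt(-20 * log10(resid), 20)  # attenuated by at least 20 dB

  dc <- toneRecording(20, durationS = 10, dc = 5)
  outDc <- bandPass(dc, 3, 300)
  expect_lt(abs(mean(lfpData(outDc, 1)[mid])), 0.05)
})

test_that("band-pass rejects bands outside Nyquist", {
  rec <- toneRecording(20)
  expect_error(bandPass(rec, 1, 600), "fs/2")
  expect_error(bandPass(rec, 0, 250), "0 < low")
})

test_that("STFT places a tone's power at its frequency bin with 1/window spacing", {
  rec <- toneRecording(20, durationS = 30)
  sp <- computeSTFT(rec, windowS = 5, overlapFrac = 0.5)
  expect_equal(diff(specFreqs(sp))[1], 1 / 5)
  peaks <- specFreqs(sp)[apply(specPower(sp), 1, which.max)]
  expect_true(all(abs(peaks - 20) < 1e-9))

  sp1 <- computeSTFT(rec, windowS = 1)
  expect_equal(diff(specFreqs(sp1))[1], 1)
  expect_equal(diff(specTimes(sp1))[1], 0.5)  # 50% overlap
})

test_that("STFT power is quadratic in amplitude", {
  rec1 <- toneRecording(20, durationS = 10)
  rec2 <- toneRecording(20, durationS = 10, amp = 2)
  p1 <- specPower(computeSTFT(rec1, 1))
  p2 <- specPower(computeSTFT(rec2, 1))
  expect_equal(p2, 4 * p1, tolerance = 1e-9)
})

test_that("white-noise spectrogram is flat across frequency", {
  set.seed(42)
  rec <- LFPRecording(matrix(rnorm(250 * 1000), nrow = 1), 1000)
  sp <- computeSTFT(rec, windowS = 1, overlapFrac = 0.5)  # ~500 windows
  mu <- colMeans(specPower(sp))
  interior <- 2:(length(mu) - 1)  # DC/Nyquist scaled differently
  expect_lt(sd(mu[interior]) / mean(mu[interior]), 0.2)
})

test_that("recordings shorter than one window are refused", {
  rec <- toneRecording(20, durationS = 2)
  expect_error(computeSTFT(rec, windowS = 5), "shorter")
})

test_that("line-noise removal fills in-band bins from the nearest neighbor", {
  sp <- flatSpectrogram(1, nT = 20, nF = 100, freqStepHz = 1)
  P <- specPower(sp)
  P[, specFreqs(sp) == 60] <- 10
  ridge <- Spectrogram(P, specTimes(sp), specFreqs(sp))
  out <- removeLineNoise(ridge, c(59, 61))
  f <- specFreqs(out)
  expect_true(all(specPower(out)[, f >= 59 & f <= 61] == 1))
  expect_equal(specPower(out)[, f < 59 | f > 61],
               specPower(ridge)[, f < 59 | f > 61])

  # flat input unchanged
  flat <- flatSpectrogram(3, nF = 100, freqStepHz = 1)
  expect_equal(specPower(removeLineNoise(flat)), specPower(flat))

  # no in-band bins: warn and return unchanged
  coarse <- flatSpectrogram(1, nF = 10, freqStepHz = 10)  # 0,10,...,90
  coarse@freqsHz <- coarse@freqsHz + 5                    # 5,15,...,95
  expect_warning(out2 <- removeLineNoise(coarse), "unchanged")
  expect_equal(specPower(out2), specPower(coarse))
})

test_that("stage 1 flags and repairs a single large deviation", {
  # mean-power series of 1000 bins at 1.0 with one bin at 50
  sp <- flatSpectrogram(1, nT = 1000, nF = 10, binStepS = 2.5)
  P <- specPower(sp)
  P[500, ] <- 50
  spiky <- Spectrogram(P, specTimes(sp), specFreqs(sp))
  # independent oracle: direct mean/SD computation on the series
  m <- rowMeans(P)
  expect_true(m[500] > mean(m) + 4 * sd(m))
  out <- detectOutliers(spiky)
  expect_true(outlierMask(out)[500])
  expect_equal(sum(outlierMask(out)), 1)
  expect_true(all(specPower(out)[500, ] == 1))   # column median of clean bins
  expect_equal(specPower(out)[-500, ], P[-500, ])
})

test_that("constant spectrograms pass through cleaning untouched", {
  sp <- flatSpectrogram(2, nT = 200, nF = 20, binStepS = 2.5)
  out <- detectOutliers(sp)
  expect_equal(sum(outlierMask(out)), 0)
  expect_equal(specPower(out), specPower(sp))
})

test_that("short spectrograms run stage 1 only, with a warning", {
  sp <- flatSpectrogram(1, nT = 50, nF = 10, binStepS = 2.5)  # 125 s < 5 min
  expect_warning(detectOutliers(sp), "stage-2")
})

test_that("injected artifacts are flagged with few false positives", {
  artTimes <- c(60, 150, 260, 370, 480)
  sim <- simulateLFPPair(seed = 9, stimAmp = 0, noiseAmp = 20,
                         stimFreqsHz = 20, nRepeats = 1,
                         epochDurS = 10, gapS = 10, durationS = 560,
                         stimSchedule = data.frame(onset_s = 10,
                                                   offset_s = 20,
                                                   freq_hz = 20),
                         artifactTimesS = artTimes, artifactAmp = 200)
  rec <- bandPass(sim$recording, 1, 250)
  sp <- computeSTFT(rec, windowS = 5, overlapFrac = 0.5)
  out <- detectOutliers(sp)
  centers <- specTimes(sp)
  # a bin carries the artifact when it overlaps the central half of the
  # Hann window; edge overlap is suppressed by the taper
  isArt <- Reduce(`|`, lapply(artTimes, function(a)
    centers > a - 1.25 & centers < a + 0.5 + 1.25))
  mask <- outlierMask(out)
  expect_gte(mean(mask[isArt]), 0.9)
  expect_lt(mean(mask[!isArt]), 0.01)
})

test_that("cleaning is idempotent and conserves power of clean input", {
  sim <- simulateLFPPair(seed = 10, stimAmp = 0, noiseAmp = 20,
                         stimFreqsHz = 20, nRepeats = 1, epochDurS = 10,
                         gapS = 10, durationS = 400,
                         stimSchedule = data.frame(onset_s = 10,
                                                   offset_s = 20,
                                                   freq_hz = 20))
  sp <- computeSTFT(bandPass(sim$recording, 1, 250), windowS = 5)
  out1 <- detectOutliers(sp)
  # artifact-free input: total power nearly conserved
  expect_lt(abs(sum(specPower(out1)) - sum(specPower(sp))) /
              sum(specPower(sp)), 0.001)
  # second pass adds no stage-1 flags
  out2 <- detectOutliers(out1)
  m <- rowMeans(specPower(out1))
  expect_false(any(m > mean(m) + 4 * sd(m)))
})
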