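# dF/F processing: detrend, normalize, parse, bin, summarize.

test_that("quadratic detrend removes exact quadratics", {
  t <- 0:999
  quad <- 3e-6 * t^2 - 2e-3 * t + 0.8
  out <- detrendQuadratic(quad)
  expect_lt(max(abs(out)), 1e-9 * max(abs(quad)))
  expect_lt(max(abs(detrendQuadratic(rep(2.5, 100)))), 1e-12)
  expect_error(detrendQuadratic(c(1, NA, 3)), "non-finite")
  expect_error(detrendQuadratic(c(1, 2)), "3 frames")
})

test_that("detrending recovers transients under strong bleaching", {
  # noise set from the transient's own RMS so the trace has SNR 5
  gtRms <- sd(groundTruth(simulatePhotometry(seed = 31, noiseSd = 0,
                                             transientAmp = 0.2))$transientTrace)
  ses <- simulatePhotometry(seed = 31, noiseSd = gtRms / 5,
                            transientAmp = 0.2,
                            bleachCoeffs = c(2e-6, -2e-3, 1))
  gt <- groundTruth(ses)
  det <- detrendQuadratic(roiTraces(ses)[1, ])
  expect_gte(cor(det, gt$transientTrace), 0.95)
})

test_that("baseline normalization maps baseline to 1 and is scale invariant", {
  ev <- data.frame(onset_s = 10, offset_s = 15)
  fr <- 20
  n <- 20 * fr
  # constant trace
  expect_equal(normalizeToBaseline(rep(3, n), ev, 5, fr), rep(1, n))
  # baseline 1, plateau 2 during stim
  t <- (seq_len(n) - 1) / fr
  tr <- ifelse(t >= 10 & t < 15, 2, 1)
  norm <- normalizeToBaseline(tr, ev, 5, fr)
  expect_equal(unique(norm[t >= 10 & t < 15]), 2)
  expect_equal(unique(norm[t < 10]), 1)
  # positive rescaling of the raw trace changes nothing
  expect_equal(normalizeToBaseline(5 * tr, ev, 5, fr), norm)
  # insufficient pre-onset data
  expect_error(normalizeToBaseline(tr, data.frame(onset_s = 2,
                                                  offset_s = 7), 5, fr),
               "pre-onset")
})

test_that("trial parsing yields the expected matrix and drops truncated trials", {
  ses <- simulatePhotometry(seed = 32, noiseSd = 0)
  tm <- parseTrials(roiTraces(ses)[1, ], stimEvents(ses))
  expect_identical(dim(trialData(tm)), c(15L, 300L))  # (5+10) s x 20 fps
  expect_identical(nTrials(tm), 15L)

  # an event too close to session start is dropped with a warning
  ev <- rbind(data.frame(onset_s = 2, offset_s = 7), stimEvents(ses))
  expect_warning(tm2 <- parseTrials(roiTraces(ses)[1, ], ev), "dropped")
  expect_identical(nTrials(tm2), 15L)

  # trial-mean trace peaks inside the stimulation window
  res <- photometryPipeline(ses)
  mu <- colMeans(trialData(res$trials))
  tPk <- trialTimes(res$trials)[which.max(mu)]
  expect_gte(tPk, 0)
  expect_lt(tPk, stimDuration(res$trials))
})

test_that("per-second bins match the analytic kernel on noiseless input", {
  amp <- 0.25
  fr <- 20
  ses <- simulatePhotometry(seed = 33, noiseSd = 0, transientAmp = amp,
                            bleachCoeffs = c(0, 0, 1), frameRateHz = fr)
  gt <- groundTruth(ses)
  # bypass detrending: trace = 1 + transient exactly, baseline exactly 1
  tr <- 1 + gt$transientTrace
  norm <- normalizeToBaseline(tr, stimEvents(ses), 5, fr)
  tm <- parseTrials(norm, stimEvents(ses), 5, 10, fr)
  bins <- binnedResponse(tm, 1)
  # oracle: analytic kernel evaluated at the same frame times
  k <- gt$kernel
  peak <- exp(-k$peakTimeS / k$decayS) - exp(-k$peakTimeS / k$riseS)
  kfun <- function(t) (exp(-t / k$decayS) - exp(-t / k$riseS)) / peak
  tRel <- trialTimes(tm)
  expected <- vapply(1:5, function(b) {
    idx <- tRel >= b - 1 & tRel < b
    1 + amp * mean(kfun(tRel[idx]))
  }, numeric(1))
  expect_equal(unname(bins$trialMean), expected, tolerance = 1e-6)

  # constant normalized trace gives bins of exactly 1
  flat <- binnedResponse(parseTrials(rep(1, length(tr)), stimEvents(ses),
                                     5, 10, fr), 1)
  expect_true(all(abs(flat$perTrial - 1) < 1e-12))

  # a ramp over the stim window yields strictly increasing bins
  t <- (seq_along(tr) - 1) / fr
  ramp <- 1 + pmax(0, pmin((t %% 30) / 30, 1))  # rises within each trial
  rb <- binnedResponse(parseTrials(ramp, stimEvents(ses), 5, 10, fr), 1)
  expect_true(all(diff(rb$trialMean) > 0))
})

test_that("session averages track per-trial amplitudes", {
  tm <- new("TrialMatrix", data = matrix(c(1, 2, 3), 3, 10), timesS =
              seq(0, 4.5, by = 0.5), preS = 0, postS = 5, stimDurS = 5,
            onsetsS = c(10, 40, 70))
  s <- sessionAverage(tm)
  expect_equal(s$perTrial, c(1, 2, 3))
  expect_equal(s$sessionMean, 2)
  expect_equal(s$sessionEvoked, 1)

  # depletion-like decaying amplitudes appear as decreasing trial means
  amps <- seq(0.3, 0.1, length.out = 15)
  ses <- simulatePhotometry(seed = 34, noiseSd = 0, transientAmp = amps)
  res <- photometryPipeline(ses)
  pt <- res$summary$perTrial
  expect_true(all(diff(pt) < 0))
  expect_true(res$summary$sessionMean < pt[1] &&
                res$summary$sessionMean > pt[15])
})

test_that("amplitude ratios between sessions are recovered by session averages", {
  ratios <- vapply(1:10, function(s) {
    a <- simulatePhotometry(seed = s, transientAmp = 0.4,
                            noiseSd = 0.2 * 0.4)
    b <- simulatePhotometry(seed = s + 1000, transientAmp = 0.2,
                            noiseSd = 0.2 * 0.4)
    ra <- photometryPipeline(a)$summary$sessionEvoked
    rb <- photometryPipeline(b)$summary$sessionEvoked
    ra / rb
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 2), 0.2)
})

test_that("normalizing before detrending breaks the baseline anchor", {
  # regression guard for the fixed pipeline order: detrending after
  # normalization re-centres the trace near zero, so the baseline no longer
  # maps to 1 and evoked amplitudes are misestimated
  ses <- simulatePhotometry(seed = 35, noiseSd = 0.02, transientAmp = 0.2,
                            bleachCoeffs = c(4e-6, -4e-3, 1))
  raw <- roiTraces(ses)[1, ]
  ev <- stimEvents(ses)
  fr <- fsHz(ses)
  gtAmp <- mean(groundTruth(ses)$transientTrace)
  good <- normalizeToBaseline(detrendQuadratic(raw), ev, 5, fr,
                              baselineRef = raw)
  badOrder <- detrendQuadratic(normalizeToBaseline(raw, ev, 5, fr))
  t <- (seq_along(raw) - 1) / fr
  baseIdx <- Reduce(`|`, lapply(ev$onset_s, function(o) t >= o - 5 & t < o))
  expect_lt(abs(mean(good[baseIdx]) - 1), 0.01)
  expect_gt(abs(mean(badOrder[baseIdx]) - 1), 0.5)
  # evoked level (trace mean minus baseline-anchor 1) recovered only in order
  errGood <- abs((mean(good) - 1) - gtAmp)
  errBad <- abs((mean(badOrder) - 1) - gtAmp)
  expect_gt(errBad, 10 * errGood)
})
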