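# Zone occupancy, closed-loop epochs, preference scores, chamber times,
# protocol validation.

test_that("zone membership follows the 7 cm radial rule", {
  geom <- ArenaGeometry()
  lc <- cupCenters(geom)["left", ]
  inside <- stationarySession(lc["x"] + 5, lc["y"], durationS = 60)
  occ <- zoneOccupancy(inside, geom)
  expect_equal(unname(occ$zoneSeconds["left"]), 60, tolerance = 0.2)
  expect_equal(unname(occ$zoneSeconds["right"]), 0)

  outside <- stationarySession(lc["x"] + 8, lc["y"], durationS = 60)
  occ2 <- zoneOccupancy(outside, geom)
  expect_equal(unname(occ2$zoneSeconds["left"]), 0)
})

test_that("samples far outside the arena are clipped with a warning", {
  geom <- ArenaGeometry()
  s <- data.frame(time_s = 0:9 / 10, nose_x_cm = c(rep(10, 9), -5),
                  nose_y_cm = 15)
  expect_warning(zoneOccupancy(BehaviorSession(s), geom), "clipped")
  expect_error(zoneOccupancy(BehaviorSession(
    data.frame(time_s = numeric(), nose_x_cm = numeric(),
               nose_y_cm = numeric())), geom), "empty")
})

test_that("synthetic occupancy matches the generator ground truth", {
  ses <- simulateTrajectory(seed = 2, durationS = 120)
  occ <- zoneOccupancy(ses, ArenaGeometry())
  expect_equal(occ$zoneSeconds, groundTruth(ses)$zoneSeconds)
  # intervals and per-sample seconds agree
  ivLeft <- occ$intervals[occ$intervals$side == "left", ]
  expect_equal(sum(ivLeft$end_s - ivLeft$start_s),
               unname(occ$zoneSeconds["left"]), tolerance = 0.05)
})

test_that("closed-loop epochs equal stimulation-side zone intervals", {
  occ <- list(intervals = data.frame(side = c("left", "left", "right"),
                                     start_s = c(10, 40, 100),
                                     end_s = c(20, 45, 110)))
  cl <- closedLoopEpochs(occ, "left")
  expect_equal(cl$epochs$onset_s, c(10, 40))
  expect_equal(cl$totalStimS, 15)
  expect_identical(nrow(closedLoopEpochs(occ, "right")$epochs), 1L)
  none <- list(intervals = data.frame(side = "right", start_s = 1,
                                      end_s = 2))
  expect_identical(nrow(closedLoopEpochs(none, "left")$epochs), 0L)
})

test_that("closed-loop total stimulation time equals T_S by construction", {
  ses <- simulateTrajectory(seed = 3, durationS = 120, sideBias = 0.7,
                            stimSide = "right", trialType = "testing")
  occ <- zoneOccupancy(ses, ArenaGeometry())
  cl <- closedLoopEpochs(occ, "right")
  expect_equal(cl$totalStimS, unname(occ$zoneSeconds["right"]),
               tolerance = 0.05)
})

test_that("preference scores follow their defining formulas", {
  expect_equal(preferenceScore(30, 30), 50)
  expect_equal(preferenceScore(60, 40), 60)
  expect_equal(preferenceScore(0, 50), 0)
  expect_warning(expect_true(is.na(preferenceScore(0, 0))), "undefined")
  expect_error(preferenceScore(-1, 5), ">= 0")

  expect_equal(normalizedPreference(50, 50), 100)
  expect_equal(normalizedPreference(60, 50), 120)
  expect_equal(normalizedPreference(25, 50), 50)
  expect_warning(expect_true(is.na(normalizedPreference(50, 0))),
                 "undefined")
})

test_that("preference score complementarity holds for random inputs", {
  set.seed(8)
  for (i in 1:50) {
    tS <- runif(1, 0.1, 300)
    tNS <- runif(1, 0.1, 300)
    expect_equal(preferenceScore(tS, tNS) + preferenceScore(tNS, tS), 100)
  }
})

test_that("chamber times partition the session duration", {
  geom <- ArenaGeometry()
  centerSes <- stationarySession(geom@widthCm / 2, 15, durationS = 60)
  ct <- chamberTimes(centerSes, geom)
  expect_equal(unname(ct), c(0, 60, 0), tolerance = 0.2)

  ses <- simulateTrajectory(seed = 4, durationS = 120)
  ct2 <- chamberTimes(ses, geom)
  dur <- diff(range(trajectory(ses)$time_s)) + 1 / 25
  expect_equal(sum(ct2), dur, tolerance = 1 / 25 + 1e-9)
})

test_that("biased walks spend more time in the favored chamber", {
  hits <- vapply(1:20, function(s) {
    ses <- simulateTrajectory(seed = s, durationS = 240, sideBias = 0.8,
                              biasSide = "right")
    ct <- chamberTimes(ses, ArenaGeometry())
    unname(ct["right"] > ct["left"])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("protocol validation accepts the counterbalanced 4-trial layout", {
  check <- sessionProtocolCheck(validProtocolTable())
  expect_true(check$valid)
  expect_identical(sum(check$counterbalance$stim_side), 4L)

  # testing without a side is invalid
  bad <- validProtocolTable()
  bad$stim_side[2] <- "-"
  c2 <- sessionProtocolCheck(bad)
  expect_false(c2$valid)
  expect_match(c2$messages, "stim side", all = FALSE)

  # duplicated testing trial in a session type
  dup <- validProtocolTable()
  dup$trial[1] <- "Testing"
  dup$stim[1] <- "On"
  dup$stim_side[1] <- "R"
  c3 <- sessionProtocolCheck(dup)
  expect_false(c3$valid)
  expect_match(c3$messages, "exactly one", all = FALSE)
})

test_that("avoidance scenarios push NS below 100 and neutral ones do not", {
  nsAvoid <- vapply(1:30, function(s) {
    hab <- simulateTrajectory(seed = s, durationS = 240, sideBias = 0.7,
                              biasSide = "right")
    test <- simulateTrajectory(seed = s + 500, durationS = 240,
                               sideBias = 0.3, biasSide = "right",
                               stimSide = "right", trialType = "testing")
    zh <- groundTruth(hab)$zoneSeconds
    zt <- groundTruth(test)$zoneSeconds
    suppressWarnings(normalizedPreference(
      preferenceScore(zt["right"], zt["left"]),
      preferenceScore(zh["right"], zh["left"])))
  }, numeric(1))
  expect_gte(mean(nsAvoid < 100, na.rm = TRUE), 0.9)

  nsNeutral <- vapply(1:30, function(s) {
    hab <- simulateTrajectory(seed = s, durationS = 240, sideBias = 0.5)
    test <- simulateTrajectory(seed = s + 500, durationS = 240,
                               sideBias = 0.5, stimSide = "right",
                               trialType = "testing")
    zh <- groundTruth(hab)$zoneSeconds
    zt <- groundTruth(test)$zoneSeconds
    if (sum(zh) == 0 || sum(zt) == 0) return(NA_real_)
    suppressWarnings(normalizedPreference(
      preferenceScore(zt["right"], zt["left"]),
      preferenceScore(zh["right"], zh["left"])))
  }, numeric(1))
  # neutral: no systematic shift away from 100 across seeds
  m <- mean(nsNeutral, na.rm = TRUE)
  mc <- sd(nsNeutral, na.rm = TRUE) / sqrt(sum(!is.na(nsNeutral)))
  expect_lt(abs(m - 100), 3 * mc + 10)
})
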