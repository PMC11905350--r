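# Ground-truth trajectory generator for the three-chamber task.

#' Simulate a nose-position trajectory in the three-chamber arena
#'
#' Generates a reflected Gaussian random walk with two tunable behavioral
#' features: a drift toward one cup controlled by `sideBias` (0.5 = no bias;
#' values above 0.5 pull toward `biasSide`, below 0.5 push away), and a
#' zone-stickiness factor that shortens steps while the nose is inside an
#' interaction zone, emulating dwell. The construction is symmetric at
#' `sideBias = 0.5`, so the expected zone-time share on either side is 0.5.
#'
#' Ground-truth cumulative interaction-zone occupancy (same sample-and-hold
#' convention as [zoneOccupancy()]) is stored in the session's
#' `groundTruth`.
#'
#' @param seed integer RNG seed.
#' @param durationS session length (s, default 600 = 10 min trial).
#' @param sampleRateHz tracking rate (default 25, typical video tracking).
#' @param geometry an [ArenaGeometry-class]; default standard arena.
#' @param sideBias in `[0, 1]`; probability weighting toward `biasSide`.
#' @param biasSide `"left"` or `"right"`; the side favored when
#'   `sideBias > 0.5`. Defaults to `stimSide` when that is not `"none"`,
#'   else `"right"`.
#' @param stepSdCm random-walk step SD per sample (cm).
#' @param driftCm maximum drift per sample toward the favored cup (cm),
#'   scaled by `2 * (sideBias - 0.5)`.
#' @param stickiness in `[0, 1)`; step shrink factor inside a zone.
#' @param stimSide,trialType,sessionType trial descriptors stored on the
#'   session (see [BehaviorSession-class]).
#' @return A [BehaviorSession-class] with ground truth attached.
#' @examples
#' ses <- simulateTrajectory(seed = 1, durationS = 60)
#' groundTruth(ses)$zoneSeconds
#' @export
simulateTrajectory <- function(seed,
                               durationS = 600,
                               sampleRateHz = 25,
                               geometry = ArenaGeometry(),
                               sideBias = 0.5,
                               biasSide = NULL,
                               stepSdCm = 1.2,
                               driftCm = 0.35,
                               stickiness = 0.6,
                               stimSide = "none",
                               trialType = "habituation",
                               sessionType = "ToyToy") {
  if (durationS <= 0) .stopConfig("durationS", "must be positive")
  if (sampleRateHz <= 0) .stopConfig("sampleRateHz", "must be positive")
  if (sideBias < 0 || sideBias > 1)
    .stopConfig("sideBias", "must lie in [0, 1]")
  if (stickiness < 0 || stickiness >= 1)
    .stopConfig("stickiness", "must lie in [0, 1)")
  if (is.null(biasSide))
    biasSide <- if (stimSide == "none") "right" else stimSide
  if (!biasSide %in% c("left", "right"))
    .stopConfig("biasSide", "must be 'left' or 'right'")

  n <- max(2L, round(durationS * sampleRateHz))
  w <- geometry@widthCm
  d <- geometry@depthCm
  cups <- cupCenters(geometry)
  rZone <- zoneRadius(geometry)
  target <- cups[biasSide, ]
  driftGain <- driftCm * 2 * (sideBias - 0.5)

  .withSeed(seed, {
    xs <- numeric(n)
    ys <- numeric(n)
    x <- w / 2
    y <- d / 2
    dx <- stats::rnorm(n, sd = stepSdCm)
    dy <- stats::rnorm(n, sd = stepSdCm)
    for (i in seq_len(n)) {
      inZone <- min(sqrt((x - cups[, 1])^2 + (y - cups[, 2])^2)) <= rZone
      shrink <- if (inZone) 1 - stickiness else 1
      vx <- target[1] - x
      vy <- target[2] - y
      vn <- sqrt(vx^2 + vy^2)
      if (vn > 1e-9) {
        vx <- vx / vn
        vy <- vy / vn
      } else vx <- vy <- 0
      x <- x + shrink * (dx[i] + driftGain * vx)
      y <- y + shrink * (dy[i] + driftGain * vy)
      # reflect at walls
      if (x < 0) x <- -x
      if (x > w) x <- 2 * w - x
      if (y < 0) y <- -y
      if (y > d) y <- 2 * d - y
      x <- min(max(x, 0), w)
      y <- min(max(y, 0), d)
      xs[i] <- x
      ys[i] <- y
    }
    samples <- data.frame(
      time_s = (seq_len(n) - 1) / sampleRateHz,
      nose_x_cm = xs,
      nose_y_cm = ys
    )
    ses <- BehaviorSession(samples, stimSide = stimSide,
                           trialType = trialType, sessionType = sessionType)
    occ <- zoneOccupancy(ses, geometry)
    ses@groundTruth <- list(zoneSeconds = occ$zoneSeconds,
                            sideBias = sideBias, biasSide = biasSide)
    ses
  })
}
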