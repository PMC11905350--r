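# Three-chamber task scoring: zone occupancy, closed-loop epochs,
# preference scores, chamber times, and protocol validation.

# Sample-and-hold span per sample: each sample represents the interval up to
# the next sample; the last sample gets the median inter-sample interval.
.sampleSpans <- function(timeS) {
  n <- length(timeS)
  if (n == 1) return(1)
  dt <- diff(timeS)
  c(dt, stats::median(dt))
}

#' Interaction-zone occupancy
#'
#' The nose is inside a cup's interaction zone when its Euclidean distance
#' to the cup center is at most `cupRadiusCm + zoneMarginCm` (7 cm at the
#' default geometry). Occupancy time integrates sample-and-hold between
#' samples; entry/exit intervals are reported on half-open sample spans.
#' Samples outside the arena by more than 1 cm are clipped to the walls
#' with a warning.
#'
#' @param session a [BehaviorSession-class].
#' @param geometry an [ArenaGeometry-class].
#' @return list: `zoneSeconds` (named `left`/`right` cumulative seconds),
#'   `intervals` (data.frame `side`, `start_s`, `end_s`), `inZone`
#'   (data.frame of per-sample logicals).
#' @export
zoneOccupancy <- function(session, geometry) {
  stopifnot(is(session, "BehaviorSession"), is(geometry, "ArenaGeometry"))
  s <- trajectory(session)
  if (!nrow(s)) stop("trajectory is empty", call. = FALSE)
  x <- s$nose_x_cm
  y <- s$nose_y_cm
  w <- geometry@widthCm
  d <- geometry@depthCm
  out <- x < -1 | x > w + 1 | y < -1 | y > d + 1
  if (any(out))
    warning(sum(out), " sample(s) fell > 1 cm outside the arena; clipped")
  x <- pmin(pmax(x, 0), w)
  y <- pmin(pmax(y, 0), d)
  cups <- cupCenters(geometry)
  r <- zoneRadius(geometry)
  spans <- .sampleSpans(s$time_s)
  inZone <- data.frame(
    left = sqrt((x - cups["left", 1])^2 + (y - cups["left", 2])^2) <= r,
    right = sqrt((x - cups["right", 1])^2 + (y - cups["right", 2])^2) <= r
  )
  zoneSeconds <- c(left = sum(spans[inZone$left]),
                   right = sum(spans[inZone$right]))
  intervals <- do.call(rbind, lapply(c("left", "right"), function(side) {
    flag <- inZone[[side]]
    if (!any(flag)) return(NULL)
    r_ <- rle(flag)
    ends <- cumsum(r_$lengths)
    starts <- ends - r_$lengths + 1L
    on <- which(r_$values)
    tEnd <- c(s$time_s[-1], s$time_s[nrow(s)] + spans[length(spans)])
    data.frame(side = side, start_s = s$time_s[starts[on]],
               end_s = tEnd[ends[on]])
  }))
  if (is.null(intervals))
    intervals <- data.frame(side = character(), start_s = numeric(),
                            end_s = numeric())
  rownames(intervals) <- NULL
  list(zoneSeconds = zoneSeconds, intervals = intervals, inZone = inZone)
}

#' Closed-loop stimulation epochs
#'
#' Emulates zone-triggered stimulation: the laser switches on at physical
#' entry into the stimulation-side interaction zone and stays on until the
#' animal leaves, so the stimulation epochs are exactly the stimulation-side
#' zone intervals and the total stimulation time equals T_S.
#'
#' @param occupancy output of [zoneOccupancy()].
#' @param stimSide `"left"` or `"right"`.
#' @return list: `epochs` (data.frame `onset_s`, `offset_s`),
#'   `totalStimS`.
#' @export
closedLoopEpochs <- function(occupancy, stimSide) {
  stopifnot(stimSide %in% c("left", "right"))
  iv <- occupancy$intervals
  iv <- iv[iv$side == stimSide, , drop = FALSE]
  epochs <- data.frame(onset_s = iv$start_s, offset_s = iv$end_s)
  rownames(epochs) <- NULL
  list(epochs = epochs, totalStimS = sum(epochs$offset_s - epochs$onset_s))
}

#' Preference score
#'
#' `PS = 100 * T_S / (T_NS + T_S)`: the percentage of interaction-zone time
#' spent on the stimulation side. 50 means equal time on both sides.
#'
#' @param tS cumulative seconds in the stimulation-side zone.
#' @param tNS cumulative seconds in the non-stimulation-side zone.
#' @return PS in `[0, 100]`, or `NA` (with a warning) when both times are
#'   zero.
#' @examples
#' preferenceScore(60, 40)  # 60
#' @export
preferenceScore <- function(tS, tNS) {
  if (tS < 0 || tNS < 0) stop("zone times must be >= 0", call. = FALSE)
  if (tS + tNS == 0) {
    warning("no interaction-zone time on either side; PS undefined")
    return(NA_real_)
  }
  100 * tS / (tNS + tS)
}

#' Normalized preference score
#'
#' `NS = 100 * PS_T / PS_H`: the testing-trial preference score relative to
#' the habituation-trial score. 100 means stimulation left the preference
#' unchanged; values below 100 indicate a shift away from the stimulation
#' side during testing.
#'
#' @param psT preference score during the testing trial.
#' @param psH preference score during the habituation trial.
#' @return NS (>= 0), or `NA` (with a warning) when `psH` is zero or
#'   missing.
#' @examples
#' normalizedPreference(60, 50)  # 120
#' @export
normalizedPreference <- function(psT, psH) {
  if (is.na(psT) || is.na(psH) || psH <= 0) {
    warning("habituation preference score is zero or missing; NS undefined")
    return(NA_real_)
  }
  100 * psT / psH
}

#' Time spent in each chamber
#'
#' Cumulative seconds in the left, center and right chambers (equal thirds
#' of the arena along x), integrating sample-and-hold between samples. The
#' three times sum to the session duration within one sample period.
#'
#' @param session a [BehaviorSession-class].
#' @param geometry an [ArenaGeometry-class].
#' @return Named numeric: `left`, `center`, `right` (seconds).
#' @export
chamberTimes <- function(session, geometry) {
  stopifnot(is(session, "BehaviorSession"), is(geometry, "ArenaGeometry"))
  s <- trajectory(session)
  if (!nrow(s)) stop("trajectory is empty", call. = FALSE)
  x <- pmin(pmax(s$nose_x_cm, 0), geometry@widthCm)
  third <- geometry@widthCm / 3
  spans <- .sampleSpans(s$time_s)
  c(left = sum(spans[x < third]),
    center = sum(spans[x >= third & x < 2 * third]),
    right = sum(spans[x >= 2 * third]))
}

# Standardize a protocol table's column names (tolerates Table-2 style
# headers like "Stim." / "Stim. Side").
.normalizeProtocolNames <- function(df) {
  nm <- tolower(gsub("[^[:alnum:]]+", "_", names(df)))
  nm <- sub("_+$", "", nm)
  nm[nm == "stim_side"] <- "stim_side"
  names(df) <- nm
  df
}

#' Validate a multi-session task protocol
#'
#' Checks that each animal's protocol follows the four-trial structure of
#' the task: a habituation and a testing trial for each of the ToyToy and
#' ToyFemale sessions, stimulation off (no side) during habituation, and
#' stimulation on with an assigned side during testing. Also tallies
#' counterbalancing of stimulation sides and session order across animals.
#'
#' @param protocol data.frame with columns `animal`, `session`
#'   (`ToyToy`/`ToyFemale`), `trial` (`Habituation`/`Testing`), `stim`
#'   (`On`/`Off`), `stim_side` (`L`/`R`/`-`); case and punctuation in the
#'   header are tolerated.
#' @return list: `valid` (logical), `messages` (character),
#'   `counterbalance` (list of tallies).
#' @export
sessionProtocolCheck <- function(protocol) {
  p <- .normalizeProtocolNames(as.data.frame(protocol))
  need <- c("animal", "session", "trial", "stim", "stim_side")
  if (!all(need %in% names(p)))
    stop("protocol needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  msgs <- character()
  norm <- function(x) tolower(trimws(as.character(x)))
  p$session <- norm(p$session)
  p$trial <- norm(p$trial)
  p$stim <- norm(p$stim)
  p$stim_side <- toupper(trimws(as.character(p$stim_side)))
  for (a in unique(p$animal)) {
    sub <- p[p$animal == a, , drop = FALSE]
    if (nrow(sub) != 4)
      msgs <- c(msgs, paste0(a, ": expected 4 trials, found ", nrow(sub)))
    for (ses in c("toytoy", "toyfemale")) {
      sses <- sub[gsub("[^a-z]", "", sub$session) == ses, , drop = FALSE]
      for (tr in c("habituation", "testing")) {
        st <- sses[sses$trial == tr, , drop = FALSE]
        if (nrow(st) != 1) {
          msgs <- c(msgs, paste0(a, ": ", ses, " must have exactly one ",
                                 tr, " trial (found ", nrow(st), ")"))
          next
        }
        if (tr == "habituation") {
          if (st$stim != "off")
            msgs <- c(msgs, paste0(a, ": ", ses,
                                   " habituation must have stim Off"))
          if (st$stim_side %in% c("L", "R"))
            msgs <- c(msgs, paste0(a, ": ", ses,
                                   " habituation must not assign a side"))
        } else {
          if (st$stim != "on")
            msgs <- c(msgs, paste0(a, ": ", ses,
                                   " testing must have stim On"))
          if (!st$stim_side %in% c("L", "R"))
            msgs <- c(msgs, paste0(a, ": ", ses,
                                   " testing must assign stim side L or R"))
        }
      }
    }
  }
  testing <- p[p$trial == "testing", , drop = FALSE]
  firstSession <- vapply(unique(p$animal), function(a) {
    p$session[p$animal == a][1]
  }, character(1))
  list(
    valid = length(msgs) == 0,
    messages = msgs,
    counterbalance = list(
      stim_side = table(testing$stim_side),
      first_session = table(firstSession)
    )
  )
}
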