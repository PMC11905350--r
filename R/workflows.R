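# End-to-end workflows: configuration handling plus the three composed
# analysis chains (LFP, photometry, behavior).

#' Default analysis parameters
#'
#' The full parameter set used by the workflows, at the standard values:
#' 1-250 Hz band, 5 s / 50% whole-session STFT, 1 s / 50% stimulation-trial
#' bins, 59-61 Hz line-noise band, 4 SD global and 5x MAD / 5 min local
#' outlier thresholds, +/- 1 Hz quantification band, 0-120 s stimulation vs
#' -30-0 s baseline windows, +/- 2 SD inclusion screen, 5 s / 1 s photometry
#' trial windows, and the standard arena geometry.
#'
#' @return Named list of parameters.
#' @export
runConfigDefaults <- function() {
  list(
    band_low_hz = 1, band_high_hz = 250,
    session_window_s = 5, opto_window_s = 1, overlap_frac = 0.5,
    line_band_hz = c(59, 61),
    global_k = 4, mad_k = 5, window_min = 5,
    half_width_hz = 1,
    stim_window_s = c(0, 120), base_window_s = c(-30, 0),
    inclusion_k = 2,
    pre_s = 5, post_s = 10, bin_s = 1,
    clean = TRUE
  )
}

# Merge user parameters over defaults; unknown keys are rejected.
.mergeParams <- function(params) {
  defaults <- runConfigDefaults()
  if (is.null(params)) return(defaults)
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  utils::modifyList(defaults, params)
}

#' Read a workflow configuration file
#'
#' YAML with top-level keys naming inputs/outputs (`lfp`, `protocol`,
#' `traces`, `events`, `behavior_protocol`, `out_dir`) and an optional
#' `params` block overriding [runConfigDefaults()].
#'
#' @param path YAML file path.
#' @return Configuration list with `params` merged over the defaults.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(.checkFile(path))
  cfg$params <- .mergeParams(cfg$params)
  cfg
}

# Run stages, removing this run's partial outputs on failure.
.withStageCleanup <- function(outFiles, expr) {
  tryCatch(expr, error = function(e) {
    existing <- outFiles[file.exists(outFiles)]
    if (length(existing)) unlink(existing)
    stop(conditionMessage(e), call. = FALSE)
  })
}

.writeManifest <- function(outDir, params, inputs) {
  yaml::write_yaml(
    list(package = "optoephys",
         version = as.character(utils::packageVersion("optoephys")),
         inputs = inputs, params = params),
    file.path(outDir, "manifest.yaml"))
}

#' Run the full LFP workflow
#'
#' Band-pass filter, per-channel stimulation-trial spectrograms (1 s bins)
#' with line-noise removal and two-stage outlier cleaning, evoked power
#' ratios with the inclusion screen and repeat averaging, presentation-order
#' table, and PLV/iPLV coherence ratios. All tables are written to
#' `out_dir` together with a parameter manifest; a failing stage aborts
#' with a stage-named error and removes this run's partial outputs.
#'
#' @param config list (or YAML path) with `lfp` (recording CSV path or an
#'   [LFPRecording-class]), `protocol` (CSV path or [StimProtocol-class]),
#'   `out_dir`, and optional `params` overriding [runConfigDefaults()].
#' @return list: `powerRatios`, `summary`, `orderEffect`, `coherence`,
#'   `spectrograms`, invisibly also written under `out_dir`.
#' @export
runLFPWorkflow <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  p <- .mergeParams(config$params)
  outDir <- config$out_dir
  if (is.null(outDir)) stop("config must name out_dir", call. = FALSE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  outFiles <- file.path(outDir, c("power_ratio.csv", "power_ratio_summary.csv",
                                  "order_effect.csv", "coherence.csv",
                                  "manifest.yaml"))
  .withStageCleanup(outFiles, {
    rec <- if (is(config$lfp, "LFPRecording")) config$lfp
           else readLFPText(config$lfp)
    proto <- if (is(config$protocol, "StimProtocol")) config$protocol
             else readProtocolCSV(config$protocol)

    filt <- tryCatch(bandPass(rec, p$band_low_hz, p$band_high_hz),
                     error = function(e) stop("stage 'bandpass': ",
                                              conditionMessage(e)))
    specs <- lapply(seq_len(nChannels(filt)), function(ch) {
      tryCatch({
        sp <- computeSTFT(filt, p$opto_window_s, p$overlap_frac, ch)
        sp <- removeLineNoise(sp, p$line_band_hz)
        if (isTRUE(p$clean))
          sp <- suppressWarnings(
            detectOutliers(sp, p$global_k, p$mad_k, p$window_min))
        sp
      }, error = function(e) stop("stage 'spectrogram' (channel ", ch,
                                  "): ", conditionMessage(e)))
    })

    results <- tryCatch({
      do.call(rbind, lapply(specs, function(sp)
        powerRatio(sp, proto, p$stim_window_s, p$base_window_s,
                   p$half_width_hz)))
    }, error = function(e) stop("stage 'power-ratio': ",
                                conditionMessage(e)))
    results <- inclusionFilter(results, p$inclusion_k)
    summary <- averageRepeats(results)
    order <- presentationOrderEffect(results)

    coh <- tryCatch({
      inc <- results[results$included & results$valid,
                     c("freq_hz", "repeat_idx")]
      inc <- inc[duplicated(inc) | !duplicated(inc), , drop = FALSE]
      keep <- stats::aggregate(
        rep(1, nrow(results[results$included & results$valid, ])),
        by = list(freq_hz = results$freq_hz[results$included & results$valid],
                  repeat_idx = results$repeat_idx[results$included &
                                                    results$valid]),
        FUN = sum)
      # keep a repeat only if included on every channel
      keep <- keep[keep$x == nChannels(filt), c("freq_hz", "repeat_idx")]
      coherenceRatio(rec, proto, halfWidthHz = p$half_width_hz,
                     stimWindowS = p$stim_window_s,
                     baseWindowS = p$base_window_s,
                     includedRepeats = keep)
    }, error = function(e) stop("stage 'coherence': ", conditionMessage(e)))

    utils::write.csv(results, outFiles[1], row.names = FALSE)
    utils::write.csv(summary, outFiles[2], row.names = FALSE)
    utils::write.csv(order, outFiles[3], row.names = FALSE)
    utils::write.csv(coh$table, outFiles[4], row.names = FALSE)
    .writeManifest(outDir, p,
                   list(lfp = if (is.character(config$lfp)) config$lfp
                              else "<in-memory>",
                        protocol = if (is.character(config$protocol))
                          config$protocol else "<in-memory>"))
    list(powerRatios = results, summary = summary, orderEffect = order,
         coherence = coh, spectrograms = specs)
  })
}

#' Run the full photometry workflow
#'
#' Detrend, baseline-normalize, parse into trials, bin per second, and
#' summarize; writes the per-trial per-bin table, a JSON session summary,
#' and a manifest to `out_dir`.
#'
#' @param config list (or YAML path) with `traces` + `events` (CSV paths)
#'   or `session` (a [PhotometrySession-class]), `out_dir`, optional
#'   `params`.
#' @return The [photometryPipeline()] result list.
#' @export
runPhotometryWorkflow <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  p <- .mergeParams(config$params)
  outDir <- config$out_dir
  if (is.null(outDir)) stop("config must name out_dir", call. = FALSE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  outFiles <- file.path(outDir, c("trials.csv", "summary.json",
                                  "manifest.yaml"))
  .withStageCleanup(outFiles, {
    ses <- if (!is.null(config$session)) config$session
           else readPhotometryCSV(config$traces, config$events)
    if (!nrow(stimEvents(ses)))
      stop("stage 'photometry': session has no stimulation events")
    res <- tryCatch(photometryPipeline(ses, p$pre_s, p$post_s, p$bin_s),
                    error = function(e) stop("stage 'photometry': ",
                                             conditionMessage(e)))
    bins <- res$bins
    trialTable <- data.frame(
      trial = rep(seq_len(nrow(bins$perTrial)), times = ncol(bins$perTrial)),
      bin_start_s = rep(bins$binStartS, each = nrow(bins$perTrial)),
      normalized_response = as.vector(bins$perTrial)
    )
    utils::write.csv(trialTable, outFiles[1], row.names = FALSE)
    jsonlite::write_json(
      list(n_trials = nTrials(res$trials),
           per_trial_mean = res$summary$perTrial,
           session_mean = res$summary$sessionMean,
           bin_trial_mean = bins$trialMean,
           bin_sem = bins$sem),
      outFiles[2], auto_unbox = TRUE, digits = NA)
    .writeManifest(outDir, p,
                   list(traces = if (is.null(config$traces)) "<in-memory>"
                                 else config$traces,
                        events = if (is.null(config$events)) "<in-memory>"
                                 else config$events))
    res
  })
}

#' Run the full behavior workflow
#'
#' Validates the task protocol, scores every trial's interaction-zone
#' occupancy and preference score (habituation trials are scored against
#' the side assigned in the matching testing trial), derives closed-loop
#' stimulation epochs for testing trials, computes normalized preference
#' scores per animal and session, and tabulates chamber times. Tables and a
#' manifest are written to `out_dir`.
#'
#' @param config list (or YAML path) with `protocol` (CSV path or
#'   data.frame with columns `animal`, `session`, `trial`, `stim`,
#'   `stim_side`, `traj_path`, or in-memory `sessions` as a named list of
#'   [BehaviorSession-class] keyed by `animal/session/trial`), `out_dir`,
#'   optional `geometry` ([ArenaGeometry-class]) and `params`.
#' @return list: `scores`, `ns`, `chambers`, `check`.
#' @export
runBehaviorWorkflow <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  p <- .mergeParams(config$params)
  outDir <- config$out_dir
  if (is.null(outDir)) stop("config must name out_dir", call. = FALSE)
  geometry <- if (is.null(config$geometry)) ArenaGeometry()
              else config$geometry
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  outFiles <- file.path(outDir, c("scores.csv", "ns.csv", "chambers.csv",
                                  "manifest.yaml"))
  .withStageCleanup(outFiles, {
    proto <- if (is.character(config$protocol))
      utils::read.csv(.checkFile(config$protocol)) else
        as.data.frame(config$protocol)
    proto <- .normalizeProtocolNames(proto)
    check <- sessionProtocolCheck(proto)
    if (!check$valid)
      stop("stage 'protocol-check': ",
           paste(check$messages, collapse = "; "))

    getSession <- function(row) {
      key <- paste(row$animal, row$session, row$trial, sep = "/")
      if (!is.null(config$sessions)) {
        ses <- config$sessions[[key]]
        if (is.null(ses)) stop("no session supplied for ", key)
        ses
      } else {
        readTrajectoryCSV(row$traj_path)
      }
    }

    sideOf <- function(code) if (toupper(code) == "L") "left" else "right"
    scores <- list()
    chambers <- list()
    for (i in seq_len(nrow(proto))) {
      row <- proto[i, , drop = FALSE]
      ses <- getSession(row)
      # habituation is scored against the side stimulated in testing
      mt <- proto[proto$animal == row$animal &
                    proto$session == row$session &
                    tolower(proto$trial) == "testing", , drop = FALSE]
      scoreSide <- sideOf(mt$stim_side[1])
      occ <- zoneOccupancy(ses, geometry)
      tS <- unname(occ$zoneSeconds[scoreSide])
      tNS <- unname(occ$zoneSeconds[setdiff(c("left", "right"), scoreSide)])
      stim <- tolower(row$stim) == "on"
      stimS <- if (stim) closedLoopEpochs(occ, scoreSide)$totalStimS else 0
      scores[[i]] <- data.frame(
        animal = row$animal, session = row$session, trial = row$trial,
        score_side = scoreSide, t_s = tS, t_ns = tNS,
        ps = suppressWarnings(preferenceScore(tS, tNS)),
        stim_total_s = stimS)
      ct <- chamberTimes(ses, geometry)
      chambers[[i]] <- data.frame(
        animal = row$animal, session = row$session, trial = row$trial,
        left_s = ct["left"], center_s = ct["center"], right_s = ct["right"])
    }
    scores <- do.call(rbind, scores)
    chambers <- do.call(rbind, chambers)
    rownames(scores) <- rownames(chambers) <- NULL

    nsRows <- list()
    for (a in unique(scores$animal)) {
      for (ses in unique(scores$session[scores$animal == a])) {
        sub <- scores[scores$animal == a & scores$session == ses, ]
        psH <- sub$ps[tolower(sub$trial) == "habituation"]
        psT <- sub$ps[tolower(sub$trial) == "testing"]
        nsRows[[paste(a, ses)]] <- data.frame(
          animal = a, session = ses, ps_h = psH, ps_t = psT,
          ns = suppressWarnings(normalizedPreference(psT, psH)))
      }
    }
    ns <- do.call(rbind, nsRows)
    rownames(ns) <- NULL

    utils::write.csv(scores, outFiles[1], row.names = FALSE)
    utils::write.csv(ns, outFiles[2], row.names = FALSE)
    utils::write.csv(chambers, outFiles[3], row.names = FALSE)
    .writeManifest(outDir, p,
                   list(protocol = if (is.character(config$protocol))
                     config$protocol else "<in-memory>"))
    list(scores = scores, ns = ns, chambers = chambers, check = check)
  })
}
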