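#' Epoch a conditioned signal around train onsets
#'
#' Cuts the signal into onset-locked rows over `window` (seconds relative
#' to onset, half-open).  Epochs that extend past the recording edges are
#' returned with `NA` padding and flagged as partial rather than silently
#' truncated.
#'
#' @param sig a [vns_signal()].
#' @param events a [stim_trains()] table.
#' @param window `(start, end)` seconds relative to onset.
#' @return an `epoch_matrix`: trials x time matrix with attributes `time`
#'   (relative time axis) and `partial` (logical per trial).
#' @export
epoch_signal <- function(sig, events, window = c(-20, 60)) {
  rate <- sig$rate
  rel <- seq(window[1], window[2] - 1 / rate, by = 1 / rate)
  n_ev <- nrow(events)
  out <- matrix(NA_real_, n_ev, length(rel))
  partial <- logical(n_ev)
  n <- length(sig$values)
  for (i in seq_len(n_ev)) {
    idx0 <- round((events$onset_s[i] + window[1] - sig$t0) * rate) + 1
    idx <- idx0 + seq_along(rel) - 1L
    ok <- idx >= 1L & idx <= n
    partial[i] <- !all(ok)
    out[i, ok] <- sig$values[idx[ok]]
  }
  structure(out, time = rel, partial = partial, rate = rate,
            window = window, class = c("epoch_matrix", "matrix", "array"))
}

#' Evoked scalar responses from an epoch matrix
#'
#' Per trial: mean over the response window minus mean over the baseline
#' window (both half-open, seconds relative to onset).  This is the evoked
#' response measure used throughout: e.g. mean pupil over 2.5--7.5 s after
#' onset minus the 5 s pre-onset baseline (standard luminance), or
#' 10--30 s minus a 20 s baseline (imaging luminance).
#'
#' @param epochs an [epoch_signal()] matrix.
#' @param response_window,baseline_window windows in seconds.
#' @return data frame with `baseline` and `response` per trial (response is
#'   baseline-subtracted).
#' @export
evoked_scalar <- function(epochs, response_window = c(2.5, 7.5),
                          baseline_window = c(-5, 0)) {
  tm <- attr(epochs, "time")
  check_window <- function(w, nm) {
    if (w[1] < tm[1] - 1e-9 || w[2] > tm[length(tm)] + 1 / attr(epochs, "rate") + 1e-9) {
      stop(nm, " window lies outside the epoch span")
    }
  }
  check_window(response_window, "response")
  check_window(baseline_window, "baseline")
  rsel <- tm >= response_window[1] & tm < response_window[2]
  bsel <- tm >= baseline_window[1] & tm < baseline_window[2]
  base <- rowMeans(epochs[, bsel, drop = FALSE])
  resp <- rowMeans(epochs[, rsel, drop = FALSE])
  data.frame(baseline = base, response = resp - base)
}

#' Walking metrics per train
#'
#' Mean treadmill speed over the walk window (default 0--10 s after onset,
#' i.e. the train itself) and the walked flag: |speed| strictly greater
#' than the threshold (a trial at exactly 0.05 cm/s counts as not walked).
#'
#' @param sig conditioned velocity [vns_signal()] (cm/s), or `NULL`.
#' @param events a [stim_trains()] table.
#' @param threshold walking threshold, cm/s.
#' @param window window relative to onset, seconds.
#' @return data frame with `walk_speed` and `walked` per trial (all `NA`
#'   when the velocity channel is absent).
#' @export
walk_metrics <- function(sig, events, threshold = 0.05, window = c(0, 10)) {
  n_ev <- nrow(events)
  if (is.null(sig)) {
    return(data.frame(walk_speed = rep(NA_real_, n_ev),
                      walked = rep(NA, n_ev)))
  }
  ep <- epoch_signal(sig, events, window)
  speed <- rowMeans(ep, na.rm = TRUE)
  data.frame(walk_speed = speed, walked = abs(speed) > threshold)
}

#' Build the per-train trial table for a session
#'
#' Epochs every conditioned channel around the trains and assembles one row
#' per train: stimulation parameters, baseline and evoked scalars for
#' pupil / eyelid / calcium, walking metrics and artifact flags.
#' Rejection flags trials, it never deletes rows.
#'
#' @param conditioned named list from [condition_session()].
#' @param session the originating [vns_session()] (for events and
#'   luminance class).
#' @param config a [vns_config()].
#' @return a `vns_trials` data frame.
#' @export
build_trial_table <- function(conditioned, session, config = vns_config()) {
  events <- session$events
  wins <- window_for(config, session$meta$luminance_class)
  n_ev <- nrow(events)
  tt <- data.frame(
    trial = seq_len(n_ev),
    onset_s = events$onset_s,
    amplitude_ma = events$amplitude_ma,
    width_ms = events$width_ms,
    rate_hz = events$rate_hz,
    charge_upc = events$charge_upc
  )
  partial <- logical(n_ev)
  for (chan in c("pupil", "eyelid", "fluorescence")) {
    sig <- conditioned[[chan]]
    out_base <- paste0("baseline_", sub("fluorescence", "calcium", chan))
    out_resp <- paste0("response_", sub("fluorescence", "calcium", chan))
    if (is.null(sig)) {
      tt[[out_base]] <- rep(NA_real_, n_ev)
      tt[[out_resp]] <- rep(NA_real_, n_ev)
      next
    }
    ep <- epoch_signal(sig, events, config$epoch_window)
    partial <- partial | attr(ep, "partial")
    sc <- evoked_scalar(ep, wins$response, wins$baseline)
    tt[[out_base]] <- sc$baseline
    tt[[out_resp]] <- sc$response
  }
  wm <- walk_metrics(conditioned$velocity, events,
                     config$walk_threshold_cms, config$walk_window)
  tt$walk_speed <- wm$walk_speed
  tt$walked <- wm$walked
  tt$partial <- partial
  tt$artifact <- FALSE
  tt$artifact_reason <- ""
  class(tt) <- c("vns_trials", "data.frame")
  tt <- reject_artifacts(tt, conditioned$pupil, session, config)
  attr(tt, "luminance_class") <- session$meta$luminance_class
  attr(tt, "experiment_kind") <- session$meta$experiment_kind
  attr(tt, "session_id") <- session$meta$session_id
  tt
}

#' Flag artifact trials
#'
#' A trial is flagged (never deleted) when the pupil could not be measured
#' reliably -- operationalized as more than `artifact_max_gap_frac`
#' (default 25 percent) interpolated samples inside the combined baseline
#' and response windows -- when its epoch is partial, or (imaging) when the
#' image moved more than `motion_limit_um` (2 um) in x or y.
#'
#' @param trials a trial table from [build_trial_table()].
#' @param pupil_sig conditioned pupil [vns_signal()] with its gap mask.
#' @param session the [vns_session()].
#' @param config a [vns_config()].
#' @param motion optional per-trial data frame with `x_um`, `y_um` motion.
#' @return the trial table with updated `artifact` flags and reasons.
#' @export
reject_artifacts <- function(trials, pupil_sig, session,
                             config = vns_config(), motion = NULL) {
  wins <- window_for(config, session$meta$luminance_class)
  flag <- function(i, reason) {
    trials$artifact[i] <<- TRUE
    trials$artifact_reason[i] <<- paste0(trials$artifact_reason[i],
      if (nzchar(trials$artifact_reason[i])) ";" else "", reason)
  }
  if (!is.null(pupil_sig)) {
    gap <- vns_signal(as.numeric(pupil_sig$gap_mask), pupil_sig$rate,
                      pupil_sig$t0, kind = "gap")
    ep <- epoch_signal(gap, session$events, config$epoch_window)
    tm <- attr(ep, "time")
    sel <- (tm >= wins$baseline[1] & tm < wins$baseline[2]) |
      (tm >= wins$response[1] & tm < wins$response[2])
    frac <- rowMeans(ep[, sel, drop = FALSE], na.rm = TRUE)
    for (i in which(frac > config$artifact_max_gap_frac)) {
      flag(i, "pupil_gap")
    }
  }
  if (any(trials$partial)) {
    for (i in which(trials$partial)) flag(i, "partial_epoch")
  }
  if (!is.null(motion)) {
    over <- abs(motion$x_um) > config$motion_limit_um |
      abs(motion$y_um) > config$motion_limit_um
    for (i in which(over)) flag(i, "motion")
  }
  trials
}

#' @export
print.vns_trials <- function(x, ...) {
  cat(sprintf("VNS trial table: %d trains, %d flagged as artifact (%.1f%%)\n",
              nrow(x), sum(x$artifact), 100 * mean(x$artifact)))
  resp_cols <- grep("^response_", names(x), value = TRUE)
  for (rc in resp_cols) {
    v <- x[[rc]][!x$artifact]
    if (all(is.na(v))) next
    cat(sprintf("  %s: mean %.3f, sd %.3f\n", rc, mean(v, na.rm = TRUE),
                sd(v, na.rm = TRUE)))
  }
  if (!all(is.na(x$walked))) {
    cat(sprintf("  walked on %.1f%% of trains\n", 100 * mean(x$walked,
                                                             na.rm = TRUE)))
  }
  invisible(x)
}
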