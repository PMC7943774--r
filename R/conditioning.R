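#' Conditioned, uniformly sampled signals
#'
#' A `vns_signal` holds one conditioned channel: `values` on a uniform grid
#' at `rate` Hz starting at `t0` seconds, a logical `gap_mask` marking
#' samples whose values were interpolated (blinks, dropouts), and a
#' `provenance` character vector recording every applied step with its
#' parameters.
#'
#' @param values numeric vector, no missing values.
#' @param rate sampling rate, Hz.
#' @param t0 time of the first sample, seconds from session start.
#' @param gap_mask logical vector, same length as `values`.
#' @param kind channel kind string.
#' @param provenance character vector of applied steps.
#' @return a `vns_signal` object.
#' @export
vns_signal <- function(values, rate, t0 = 0, gap_mask = NULL,
                       kind = "unknown", provenance = character()) {
  values <- as.numeric(values)
  if (is.null(gap_mask)) gap_mask <- rep(FALSE, length(values))
  stopifnot(length(gap_mask) == length(values), rate > 0)
  structure(list(values = values, rate = rate, t0 = t0,
                 gap_mask = as.logical(gap_mask), kind = kind,
                 provenance = provenance),
            class = "vns_signal")
}

#' @export
print.vns_signal <- function(x, ...) {
  cat(sprintf("vns_signal [%s]: %d samples @ %g Hz, t = [%g, %g) s, %.2f%% interpolated\n",
              x$kind, length(x$values), x$rate, x$t0,
              x$t0 + length(x$values) / x$rate,
              100 * mean(x$gap_mask)))
  if (length(x$provenance)) {
    cat("  steps:", paste(x$provenance, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' Time axis of a conditioned signal
#' @param sig a [vns_signal()].
#' @export
signal_time <- function(sig) {
  sig$t0 + (seq_along(sig$values) - 1) / sig$rate
}

#' Resample a raw channel onto a uniform grid
#'
#' Linear interpolation of an (irregularly) sampled channel onto a uniform
#' grid at `target_rate` spanning the original time range.  Missing input
#' samples are tolerated: values are interpolated across them and the
#' affected grid samples are returned in the gap mask, so that downstream
#' blink handling can treat them as missing data.
#'
#' @param time,values raw timestamps (strictly increasing, seconds) and
#'   sample values (may contain `NA` for missing frames).
#' @param target_rate output rate, Hz (default 50).
#' @param kind channel kind carried into the output.
#' @return a [vns_signal()].
#' @export
resample_uniform <- function(time, values, target_rate = 50,
                             kind = "unknown") {
  if (length(time) < 2L) stop("need at least 2 samples to resample")
  if (any(diff(time) <= 0)) stop("timestamps must be strictly increasing")
  if (length(values) != length(time)) stop("time/values length mismatch")
  grid <- seq(time[1], time[length(time)], by = 1 / target_rate)
  ok <- !is.na(values)
  if (!any(ok)) stop("channel contains no valid samples")
  out <- approx(time[ok], values[ok], xout = grid, rule = 2)$y
  # a grid point is "missing" if any raw sample it interpolates across is NA
  if (all(ok)) {
    miss <- rep(FALSE, length(grid))
  } else {
    miss <- approx(time, as.numeric(!ok), xout = grid, rule = 2)$y > 0
  }
  vns_signal(out, target_rate, t0 = grid[1], gap_mask = miss, kind = kind,
             provenance = sprintf("resample(%g Hz)", target_rate))
}

#' Detect blinks and dropouts from the derivative of a signal
#'
#' Marks outliers in the z-scored first difference of the signal (the
#' derivative spikes produced by eyelid closure), merges them with samples
#' already flagged missing, and extends every bad span by `pad_s` seconds on
#' each side.
#'
#' @param sig a [vns_signal()].
#' @param z_threshold outlier threshold on |z| of the first difference.
#' @param pad_s pad added before and after each bad span, seconds
#'   (default 0.15).
#' @return integer matrix with columns `start`, `end` (sample indices,
#'   inclusive) of bad spans; zero rows if the signal is clean.
#' @export
detect_blinks <- function(sig, z_threshold = 3, pad_s = 0.15) {
  v <- sig$values
  n <- length(v)
  if (n < 3L) stop("need at least 3 samples")
  bad <- sig$gap_mask
  if (all(bad)) {
    return(cbind(start = 1L, end = n))
  }
  d <- diff(v)
  s <- sd(d, na.rm = TRUE)
  if (is.finite(s) && s > 0) {
    z <- (d - mean(d, na.rm = TRUE)) / s
    spike <- which(abs(z) > z_threshold)
    # a spike in diff between samples i and i+1 implicates both samples
    bad[spike] <- TRUE
    bad[spike + 1L] <- TRUE
  }
  if (!any(bad)) {
    return(cbind(start = integer(0), end = integer(0)))
  }
  pad <- ceiling(pad_s * sig$rate)
  runs <- rle_runs(bad)
  runs[, "start"] <- pmax(1L, runs[, "start"] - pad)
  runs[, "end"] <- pmin(n, runs[, "end"] + pad)
  merge_runs(runs)
}

rle_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

merge_runs <- function(runs) {
  if (nrow(runs) <= 1L) return(runs)
  runs <- runs[order(runs[, "start"]), , drop = FALSE]
  out <- runs[1, , drop = FALSE]
  for (i in seq_len(nrow(runs))[-1]) {
    if (runs[i, "start"] <= out[nrow(out), "end"] + 1L) {
      out[nrow(out), "end"] <- max(out[nrow(out), "end"], runs[i, "end"])
    } else {
      out <- rbind(out, runs[i, , drop = FALSE])
    }
  }
  out
}

#' Linearly interpolate bad spans of a signal
#'
#' Values inside each span are replaced by linear interpolation between the
#' nearest good neighbours; spans touching the signal edges are filled with
#' the nearest good value.  The gap mask is updated to flag exactly the
#' interpolated samples.
#'
#' @param sig a [vns_signal()].
#' @param intervals matrix from [detect_blinks()].
#' @return the interpolated [vns_signal()].
#' @export
interpolate_gaps <- function(sig, intervals) {
  v <- sig$values
  n <- length(v)
  bad <- rep(FALSE, n)
  if (nrow(intervals)) {
    for (i in seq_len(nrow(intervals))) {
      bad[intervals[i, "start"]:intervals[i, "end"]] <- TRUE
    }
  }
  bad <- bad | sig$gap_mask | is.na(v)
  if (all(bad)) stop("no good samples left to interpolate from")
  if (any(bad)) {
    idx <- seq_len(n)
    v[bad] <- approx(idx[!bad], v[!bad], xout = idx[bad], rule = 2)$y
  }
  vns_signal(v, sig$rate, sig$t0, gap_mask = bad, kind = sig$kind,
             provenance = c(sig$provenance, "interpolate_gaps"))
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies an order-`order` Butterworth low-pass forward and backward
#' (zero net phase shift, so evoked latencies are not displaced; the
#' effective magnitude response is the squared one-pass response).
#'
#' @param sig a uniformly sampled [vns_signal()].
#' @param order filter order (default 3).
#' @param cutoff_hz cut-off frequency, Hz (default 3); must be below the
#'   Nyquist frequency.
#' @return the filtered [vns_signal()].
#' @export
lowpass_zero_phase <- function(sig, order = 3, cutoff_hz = 3) {
  nyq <- sig$rate / 2
  if (cutoff_hz >= nyq) {
    stop(sprintf("cutoff (%g Hz) must be below Nyquist (%g Hz)",
                 cutoff_hz, nyq))
  }
  if (anyNA(sig$values)) stop("interpolate gaps before filtering")
  bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
  v <- signal::filtfilt(bf, sig$values)
  vns_signal(v, sig$rate, sig$t0, gap_mask = sig$gap_mask, kind = sig$kind,
             provenance = c(sig$provenance,
                            sprintf("butterworth(order=%d, cutoff=%g Hz, zero-phase)",
                                    order, cutoff_hz)))
}

normalize_percentile <- function(sig, prob = 0.999) {
  ref <- quantile(sig$values, prob, names = FALSE, type = 7)
  if (!is.finite(ref) || ref == 0) stop("degenerate percentile reference")
  vns_signal(100 * sig$values / ref, sig$rate, sig$t0, sig$gap_mask,
             sig$kind, c(sig$provenance,
                         sprintf("normalize(%% of %.1f percentile)", 100 * prob)))
}

normalize_zscore <- function(sig) {
  s <- sd(sig$values)
  if (!is.finite(s) || s == 0) stop("zero-variance signal cannot be z-scored")
  vns_signal((sig$values - mean(sig$values)) / s, sig$rate, sig$t0,
             sig$gap_mask, sig$kind, c(sig$provenance, "z-score"))
}

detrend_linear <- function(sig) {
  t <- signal_time(sig)
  fit <- lm.fit(cbind(1, t), sig$values)
  v <- sig$values - fit$coefficients[2] * (t - mean(t))
  vns_signal(v, sig$rate, sig$t0, sig$gap_mask, sig$kind,
             c(sig$provenance, "detrend(linear)"))
}

#' Condition one raw channel
#'
#' Applies the per-kind preprocessing chain:
#' \describe{
#'   \item{pupil, eyelid}{resample to the working rate, detect blinks on the
#'     z-scored derivative, linearly interpolate bad spans (padded by 150 ms
#'     each side), zero-phase 3 Hz low-pass, convert to percent of the
#'     99.9th percentile of the session.}
#'   \item{eye_position}{resample, interpolate the blink spans detected on
#'     the pupil channel (pass them via `blink_intervals`), convert to
#'     z-scores.}
#'   \item{velocity}{resample only (cm/s preserved).}
#'   \item{calcium}{resample, zero-phase low-pass, linear detrend of the
#'     bleaching rundown, percent of the 99.9th percentile.}
#' }
#'
#' @param time,values raw channel samples (see [resample_uniform()]).
#' @param kind one of `"pupil"`, `"eyelid"`, `"eye_position"`,
#'   `"velocity"`, `"calcium"`.
#' @param config a [vns_config()].
#' @param blink_intervals optional precomputed bad-span matrix (sample
#'   indices on the resampled grid), used for `eye_position`, whose blinks
#'   are defined by the pupil channel.
#' @return a [vns_signal()] with full provenance.
#' @export
condition_channel <- function(time, values,
                              kind = c("pupil", "eyelid", "eye_position",
                                       "velocity", "calcium"),
                              config = vns_config(),
                              blink_intervals = NULL) {
  kind <- match.arg(kind)
  sig <- resample_uniform(time, values, config$sample_rate_hz, kind = kind)
  if (kind %in% c("pupil", "eyelid")) {
    iv <- detect_blinks(sig, config$blink_z_threshold, config$interp_pad_s)
    sig <- interpolate_gaps(sig, iv)
    sig <- lowpass_zero_phase(sig, config$lowpass_order,
                              config$lowpass_cutoff_hz)
    sig <- normalize_percentile(sig)
  } else if (kind == "eye_position") {
    if (is.null(blink_intervals)) {
      blink_intervals <- cbind(start = integer(0), end = integer(0))
    }
    sig <- interpolate_gaps(sig, blink_intervals)
    sig <- normalize_zscore(sig)
  } else if (kind == "velocity") {
    sig <- interpolate_gaps(sig, cbind(start = integer(0), end = integer(0)))
  } else if (kind == "calcium") {
    sig <- interpolate_gaps(sig, cbind(start = integer(0), end = integer(0)))
    sig <- lowpass_zero_phase(sig, config$lowpass_order,
                              config$lowpass_cutoff_hz)
    sig <- detrend_linear(sig)
    sig <- normalize_percentile(sig)
  }
  sig
}

#' Condition every channel of a session
#'
#' Runs [condition_channel()] on all recognized channels of a session
#' record.  Eye-position channels reuse the blink spans detected on the
#' pupil channel, mapped onto the common working grid.
#'
#' @param session a session record from [read_session_bundle()] or
#'   [generate_session()].
#' @param config a [vns_config()].
#' @return named list of [vns_signal()] objects.
#' @export
condition_session <- function(session, config = vns_config()) {
  chans <- session$channels
  out <- list()
  kind_of <- function(nm) {
    switch(nm,
           pupil = "pupil", eyelid = "eyelid",
           eye_x = "eye_position", eye_y = "eye_position",
           velocity = "velocity", fluorescence = "calcium",
           NA_character_)
  }
  blink_iv <- NULL
  if (!is.null(chans$pupil)) {
    out$pupil <- condition_channel(chans$pupil$time, chans$pupil$values,
                                   "pupil", config)
    blink_iv <- rle_runs(out$pupil$gap_mask)
  }
  for (nm in setdiff(names(chans), "pupil")) {
    k <- kind_of(nm)
    if (is.na(k)) next   # unknown channels preserved raw, not conditioned
    out[[nm]] <- condition_channel(chans[[nm]]$time, chans[[nm]]$values, k,
                                   config, blink_intervals = blink_iv)
  }
  out
}
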