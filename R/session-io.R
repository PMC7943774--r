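#' Session records
#'
#' A `vns_session` bundles the raw channels of one recording session (each
#' a list with `time` and `values`), the ordered VNS event table (a
#' [stim_trains()] protocol) and session metadata (grounded flag, nerve
#' condition, experiment kind, luminance class).
#'
#' @param channels named list of channels, each `list(time, values)`.
#' @param events a [stim_trains()] table.
#' @param meta named list of metadata.
#' @return a `vns_session` object.
#' @export
vns_session <- function(channels, events, meta = list()) {
  meta <- validate_meta(meta)
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (is.null(ch$time) || is.null(ch$values) ||
        length(ch$time) != length(ch$values)) {
      stop("channel '", nm, "' must have equal-length time and values")
    }
    if (any(diff(ch$time) <= 0)) {
      stop("channel '", nm, "': timestamps must be strictly increasing")
    }
  }
  if (nrow(events)) {
    span <- range(unlist(lapply(channels, function(ch) range(ch$time))))
    if (any(events$onset_s < span[1]) || any(events$onset_s > span[2])) {
      stop("event onsets must lie within the recorded time span")
    }
    if (anyDuplicated(events$onset_s)) {
      warning("events table contains repeated onsets; keeping duplicates")
    }
  }
  structure(list(channels = channels, events = events, meta = meta),
            class = "vns_session")
}

validate_meta <- function(meta) {
  defaults <- list(grounded = FALSE, nerve_condition = "intact",
                   experiment_kind = "parameter_exploration",
                   luminance_class = "standard", session_id = "session")
  meta <- utils::modifyList(defaults, meta)
  match_field <- function(value, choices, field) {
    if (!value %in% choices) {
      stop("meta$", field, " must be one of: ",
           paste(choices, collapse = ", "), call. = FALSE)
    }
    value
  }
  meta$nerve_condition <- match_field(meta$nerve_condition,
    c("intact", "single_cut", "double_cut"), "nerve_condition")
  meta$experiment_kind <- match_field(meta$experiment_kind,
    c("parameter_exploration", "baseline_dependence", "axon_imaging",
      "light_control"), "experiment_kind")
  meta$luminance_class <- match_field(meta$luminance_class,
    c("standard", "imaging"), "luminance_class")
  meta$grounded <- isTRUE(meta$grounded)
  meta
}

#' @export
print.vns_session <- function(x, ...) {
  span <- range(unlist(lapply(x$channels, function(ch) range(ch$time))))
  cat(sprintf("VNS session '%s': %d channels (%s), %d events, %.1f min\n",
              x$meta$session_id, length(x$channels),
              paste(names(x$channels), collapse = ", "), nrow(x$events),
              diff(span) / 60))
  cat(sprintf("  %s, nerve %s, %s luminance, %s\n", x$meta$experiment_kind,
              x$meta$nerve_condition, x$meta$luminance_class,
              if (x$meta$grounded) "grounded" else "ungrounded"))
  invisible(x)
}

EVENT_COLS <- c("onset_s", "amplitude_ma", "width_ms", "rate_hz", "duration_s")

# Accept common non-canonical units and rename to (s, mA, ms, Hz).
# Normalization is idempotent: canonical columns pass through untouched.
normalize_event_units <- function(ev) {
  conv <- list(
    onset_ms = c("onset_s", 1e-3),
    amplitude_ua = c("amplitude_ma", 1e-3),
    width_us = c("width_ms", 1e-3),
    width_s = c("width_ms", 1e3),
    duration_ms = c("duration_s", 1e-3)
  )
  for (nm in intersect(names(conv), names(ev))) {
    target <- conv[[nm]][1]
    if (!target %in% names(ev)) {
      ev[[target]] <- ev[[nm]] * as.numeric(conv[[nm]][2])
    }
    ev[[nm]] <- NULL
  }
  ev
}

#' Read a session bundle from a directory
#'
#' A bundle is a directory holding `events.csv` (columns `onset_s`,
#' `amplitude_ma`, `width_ms`, `rate_hz`, `duration_s`), `meta.json`, and
#' signal tables: either a wide `signals.csv` (`time_s` plus one column per
#' channel) and/or per-channel `signals_<name>.csv` files (`time_s`,
#' `value`) for channels with distinct native rates.  Unknown channel names
#' are preserved.  Event units are normalized to mA/ms/Hz/s on read.
#'
#' @param path bundle directory.
#' @return a [vns_session()].
#' @export
read_session_bundle <- function(path) {
  if (!dir.exists(path)) stop("no such bundle directory: ", path)
  ev_path <- file.path(path, "events.csv")
  if (!file.exists(ev_path)) stop("bundle is missing events.csv")
  ev <- read.csv(ev_path)
  ev <- normalize_event_units(ev)
  missing <- setdiff(setdiff(EVENT_COLS, "duration_s"), names(ev))
  if (length(missing)) {
    stop("events.csv is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  if (!"duration_s" %in% names(ev)) ev$duration_s <- 10
  events <- if (nrow(ev)) {
    stim_trains(ev$onset_s, ev$amplitude_ma, ev$width_ms, ev$rate_hz,
                ev$duration_s)
  } else {
    stim_trains(numeric(0), numeric(0), numeric(0), numeric(0))
  }

  channels <- list()
  wide <- file.path(path, "signals.csv")
  if (file.exists(wide)) {
    sig <- read.csv(wide)
    if (!"time_s" %in% names(sig)) stop("signals.csv is missing column: time_s")
    for (nm in setdiff(names(sig), "time_s")) {
      channels[[nm]] <- list(time = sig$time_s, values = sig[[nm]])
    }
  }
  per <- list.files(path, pattern = "^signals_.*\\.csv$", full.names = TRUE)
  for (f in per) {
    nm <- sub("^signals_(.*)\\.csv$", "\\1", basename(f))
    sig <- read.csv(f)
    if (!all(c("time_s", "value") %in% names(sig))) {
      stop(basename(f), " is missing column: ",
           paste(setdiff(c("time_s", "value"), names(sig)), collapse = ", "))
    }
    channels[[nm]] <- list(time = sig$time_s, values = sig$value)
  }
  if (!length(channels)) stop("bundle contains no signal tables")

  meta <- list()
  mf <- file.path(path, "meta.json")
  if (file.exists(mf)) meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  sess <- vns_session(channels, events, meta)
  tf <- file.path(path, "truth.json")
  if (file.exists(tf)) {
    attr(sess, "truth") <- jsonlite::read_json(tf, simplifyVector = TRUE)
  }
  sess
}

#' Write a session bundle
#'
#' Inverse of [read_session_bundle()]: writes one `signals_<name>.csv` per
#' channel (robust to channels with different native rates), `events.csv`
#' and `meta.json`; if the session carries ground-truth annotations (from
#' [generate_session()]) these are written to `truth.json`.
#'
#' @param session a [vns_session()].
#' @param path output directory (created if needed).
#' @export
write_session_bundle <- function(session, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(session$channels)) {
    ch <- session$channels[[nm]]
    write.csv(data.frame(time_s = ch$time, value = ch$values),
              file.path(path, sprintf("signals_%s.csv", nm)),
              row.names = FALSE)
  }
  ev <- as.data.frame(session$events)[EVENT_COLS]
  write.csv(ev, file.path(path, "events.csv"), row.names = FALSE)
  jsonlite::write_json(session$meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  truth <- attr(session, "truth")
  if (!is.null(truth)) {
    jsonlite::write_json(truth, file.path(path, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Write trial table and fits to disk
#'
#' Tabular outputs are written as TSV, fit and bootstrap summaries as JSON.
#' The round trip through [read_trial_table()] / [read_fit_json()] is
#' lossless to full double precision.
#'
#' @param trials a trial table (see [build_trial_table()]).
#' @param fits named list of fitted objects with [coef()] methods (e.g.
#'   [loglogistic_fit()] results), or `NULL`.
#' @param path output directory.
#' @export
write_results <- function(trials, fits = NULL, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(trials)) {
    utils::write.table(as.data.frame(trials),
                       file.path(path, "trials.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  for (nm in names(fits)) {
    write_fit_json(fits[[nm]], file.path(path, paste0(nm, ".json")))
  }
  invisible(path)
}

#' @rdname write_results
#' @export
read_trial_table <- function(path) {
  df <- read.csv(path, sep = "\t")
  class(df) <- c("vns_trials", "data.frame")
  df
}

#' Serialize a fitted object to JSON
#'
#' Stores the class, coefficients, and any scalar diagnostic fields; arrays
#' (e.g. bootstrap draws) are stored verbatim.  `digits = NA` keeps full
#' precision, so read-back is lossless.
#'
#' @param fit a fitted object.
#' @param path output file.
#' @export
write_fit_json <- function(fit, path) {
  payload <- list(class = class(fit)[1])
  flat <- unclass(fit)
  keep <- vapply(flat, function(x) {
    is.numeric(x) || is.character(x) || is.logical(x) ||
      (is.list(x) && all(vapply(x, is.numeric, logical(1))))
  }, logical(1))
  # named atomic vectors are written as objects so names survive the trip
  payload$fields <- lapply(flat[keep], function(x) {
    if (is.atomic(x) && !is.null(names(x))) as.list(x) else x
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(payload$fields, function(x) {
    if (is.list(x) && length(x) && all(vapply(x, function(e) {
      is.numeric(e) && length(e) == 1L
    }, logical(1)))) unlist(x) else x
  })
  class(out) <- c(payload$class, "list")
  out
}
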