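#' Build a table of VNS trains
#'
#' A stimulation protocol is an ordered table of VNS trains, one row per
#' train, with onset (s from session start), pulse amplitude (mA), pulse
#' width (ms), pulse rate (Hz) and train duration (s).  The charge per pulse
#' (microcoulomb) is derived as `amplitude_ma * width_ms` and is the dose
#' axis used by the reduced dose-response model.
#'
#' @param onset_s numeric vector of train onsets, seconds from session start.
#' @param amplitude_ma pulse amplitude in mA (> 0).
#' @param width_ms pulse width in ms (> 0).
#' @param rate_hz pulse repetition rate in Hz (> 0).
#' @param duration_s train duration in seconds (default 10).
#' @return a `vns_protocol` data frame with a derived `charge_upc` column.
#' @examples
#' stim_trains(onset_s = c(60, 180), amplitude_ma = c(0.1, 0.9),
#'             width_ms = c(0.1, 0.8), rate_hz = c(5, 20))
#' @export
stim_trains <- function(onset_s, amplitude_ma, width_ms, rate_hz,
                        duration_s = 10) {
  n <- length(onset_s)
  df <- data.frame(
    onset_s = as.numeric(onset_s),
    amplitude_ma = rep_len(as.numeric(amplitude_ma), n),
    width_ms = rep_len(as.numeric(width_ms), n),
    rate_hz = rep_len(as.numeric(rate_hz), n),
    duration_s = rep_len(as.numeric(duration_s), n)
  )
  validate_trains(df)
  df$charge_upc <- df$amplitude_ma * df$width_ms
  class(df) <- c("vns_protocol", "data.frame")
  df
}

validate_trains <- function(df) {
  for (col in c("amplitude_ma", "width_ms", "rate_hz", "duration_s")) {
    if (any(!is.finite(df[[col]])) || any(df[[col]] <= 0)) {
      stop("all values of '", col, "' must be finite and > 0", call. = FALSE)
    }
  }
  invisible(df)
}

#' Generate a randomized full-factorial VNS protocol
#'
#' Crosses the amplitude, width and rate value sets into a full factorial
#' design, repeats each combination `repetitions` times, shuffles the order,
#' and schedules onsets with intertrain intervals drawn uniformly from
#' `iti_range` (default 106--130 s, mean 118 s, jittered to reduce
#' expectancy by the animal).
#'
#' The default grids reproduce the parameter-exploration design: five
#' amplitudes (0.1--0.9 mA), four widths (0.1--0.8 ms) and three rates
#' (5/10/20 Hz), i.e. 60 unique combinations per repetition.  The imaging
#' experiment uses the reduced grid `widths = c(0.1, 0.2, 0.4)`,
#' `rates = c(10, 20)` (30 combinations).
#'
#' @param amplitudes,widths,rates value sets to cross (mA, ms, Hz).
#' @param repetitions repeats of each unique combination.
#' @param seed integer seed for order shuffling and interval jitter.
#' @param iti_range uniform intertrain-interval range in seconds.
#' @param duration_s train duration, seconds.
#' @param first_onset_s onset of the first train, seconds from session
#'   start; the default leaves room for a full pre-train pseudo-trial window.
#' @return a [stim_trains()] protocol in randomized order.
#' @examples
#' p <- generate_protocol(seed = 1)
#' nrow(p)           # 60
#' @export
generate_protocol <- function(amplitudes = c(0.1, 0.3, 0.5, 0.7, 0.9),
                              widths = c(0.1, 0.2, 0.4, 0.8),
                              rates = c(5, 10, 20),
                              repetitions = 1,
                              seed = 1,
                              iti_range = c(106, 130),
                              duration_s = 10,
                              first_onset_s = 60) {
  combos <- expand.grid(amplitude_ma = amplitudes, width_ms = widths,
                        rate_hz = rates, KEEP.OUT.ATTRS = FALSE)
  combos <- combos[rep(seq_len(nrow(combos)), times = repetitions), ,
                   drop = FALSE]
  n <- nrow(combos)
  if (n == 0L) {
    return(stim_trains(numeric(0), numeric(0), numeric(0), numeric(0)))
  }
  ord <- seq_len(n)
  itis <- numeric(max(n - 1L, 0L))
  if (!is.null(seed)) {
    old <- local_rng(seed)
    on.exit(restore_rng(old), add = TRUE)
  }
  ord <- sample.int(n)
  if (n > 1L) itis <- runif(n - 1L, iti_range[1], iti_range[2])
  onsets <- first_onset_s + c(0, cumsum(itis))
  combos <- combos[ord, , drop = FALSE]
  stim_trains(onset_s = onsets,
              amplitude_ma = combos$amplitude_ma,
              width_ms = combos$width_ms,
              rate_hz = combos$rate_hz,
              duration_s = duration_s)
}

#' @export
print.vns_protocol <- function(x, ...) {
  cat(sprintf("VNS protocol: %d trains", nrow(x)))
  if (nrow(x)) {
    combos <- unique(x[c("amplitude_ma", "width_ms", "rate_hz")])
    cat(sprintf(", %d unique (amplitude, width, rate) combinations\n",
                nrow(combos)))
    cat(sprintf("  amplitude: %s mA\n",
                paste(sort(unique(x$amplitude_ma)), collapse = ", ")))
    cat(sprintf("  width:     %s ms\n",
                paste(sort(unique(x$width_ms)), collapse = ", ")))
    cat(sprintf("  rate:      %s Hz\n",
                paste(sort(unique(x$rate_hz)), collapse = ", ")))
    cat(sprintf("  charge/pulse range: %.3g-%.3g uC\n",
                min(x$charge_upc), max(x$charge_upc)))
  } else cat("\n")
  invisible(x)
}

# Seed handling: scoped use of a seed without clobbering the caller's RNG
# stream.  Returns the previous .Random.seed (or NULL).
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  invisible(old)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
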