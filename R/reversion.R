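#' Extract stimulus-free pseudo trials
#'
#' For every train with enough clean pre-onset data, carves a pseudo trial
#' out of the pre-stimulation period: a pseudo onset is placed so that the
#' pseudo response window ends exactly at the true onset, and pseudo
#' baseline / response scalars are computed with the same windows as the
#' real trials.  Because spontaneous pupil size is mean-reverting, pseudo
#' "responses" regress negatively on pseudo baselines; that relationship is
#' what the correction model estimates.
#'
#' @param sig conditioned [vns_signal()].
#' @param events a [stim_trains()] table.
#' @param response_window,baseline_window the real-trial windows (seconds
#'   relative to onset).
#' @param pre_span_s required clean pre-onset span, seconds (default 30;
#'   automatically extended to fit the windows).  Events closer than this
#'   to the session start or to the previous train are skipped.
#' @return data frame with `trial`, `baseline`, `response` for eligible
#'   events.
#' @export
extract_pseudo_trials <- function(sig, events,
                                  response_window = c(2.5, 7.5),
                                  baseline_window = c(-5, 0),
                                  pre_span_s = 30) {
  need <- max(pre_span_s,
              response_window[2] - baseline_window[1])
  onsets <- events$onset_s
  prev_end <- c(-Inf, onsets[-length(onsets)] +
                  events$duration_s[-length(onsets)])[seq_along(onsets)]
  t0 <- sig$t0
  eligible <- onsets - need >= t0 & onsets - need >= prev_end
  out <- data.frame(trial = which(eligible), baseline = NA_real_,
                    response = NA_real_)
  if (!nrow(out)) return(out)
  pseudo_onsets <- onsets[eligible] - response_window[2]
  pev <- stim_trains(pseudo_onsets,
                     events$amplitude_ma[eligible],
                     events$width_ms[eligible],
                     events$rate_hz[eligible],
                     events$duration_s[eligible])
  ep <- epoch_signal(sig, pev, c(baseline_window[1], response_window[2]))
  sc <- evoked_scalar(ep, response_window, baseline_window)
  out$baseline <- sc$baseline
  out$response <- sc$response
  out
}

#' Fit the reversion-to-the-mean correction
#'
#' Least-squares cubic of the pseudo response on the pseudo baseline,
#' fitted on trial-level pseudo data; eight equal-count baseline bins are
#' summarized alongside as diagnostics.  The fitted curve predicts the
#' spontaneous (stimulus-free) change over the measurement window expected
#' from a given baseline, which [apply_correction()] subtracts from the
#' observed evoked responses.
#'
#' @param pseudo data frame from [extract_pseudo_trials()] (possibly pooled
#'   across sessions of one experiment kind).
#' @param n_bins number of diagnostic baseline bins (default 8).
#' @return a `reversion_model` with print / coef / predict methods.
#' @export
reversion_model <- function(pseudo, n_bins = 8) {
  pseudo <- pseudo[is.finite(pseudo$baseline) & is.finite(pseudo$response), ]
  if (nrow(pseudo) < 20) stop("need at least 20 pseudo trials")
  if (sd(pseudo$baseline) == 0) {
    stop("constant pseudo baselines: rank-deficient cubic design")
  }
  b <- pseudo$baseline
  X <- cbind(1, b, b^2, b^3)
  fit <- lm.fit(X, pseudo$response)
  cf <- setNames(fit$coefficients, c("c0", "c1", "c2", "c3"))
  edges <- quantile(b, probs = seq(0, 1, length.out = n_bins + 1),
                    names = FALSE)
  grp <- cut(b, unique(edges), include.lowest = TRUE, labels = FALSE)
  bins <- data.frame(
    bin = sort(unique(grp)),
    mean_baseline = tapply(b, grp, mean),
    mean_response = tapply(pseudo$response, grp, mean),
    sem_response = tapply(pseudo$response, grp,
                          function(v) sd(v) / sqrt(length(v))),
    n = as.integer(table(grp))
  )
  structure(list(coefficients = cf, bins = bins,
                 baseline_range = range(b), n = nrow(pseudo),
                 grand_mean_baseline = mean(b)),
            class = "reversion_model")
}

#' @export
coef.reversion_model <- function(object, ...) object$coefficients

#' @export
predict.reversion_model <- function(object, baseline, ...) {
  cf <- object$coefficients
  drop(cbind(1, baseline, baseline^2, baseline^3) %*% cf)
}

#' @export
print.reversion_model <- function(x, ...) {
  cat(sprintf("Reversion-to-the-mean correction (cubic, %d pseudo trials)\n",
              x$n))
  cat("  coefficients:", paste(sprintf("%s=%.4g", names(x$coefficients),
                                       x$coefficients), collapse = ", "), "\n")
  cat(sprintf("  predicted drift at grand-mean baseline: %.4g\n",
              predict(x, x$grand_mean_baseline)))
  invisible(x)
}

#' @export
plot.reversion_model <- function(x, ...) {
  bgrid <- seq(x$baseline_range[1], x$baseline_range[2], length.out = 200)
  plot(x$bins$mean_baseline, x$bins$mean_response,
       xlab = "pseudo baseline", ylab = "pseudo response",
       main = "Spontaneous reversion to the mean", pch = 19, ...)
  segments(x$bins$mean_baseline,
           x$bins$mean_response - x$bins$sem_response,
           x$bins$mean_baseline,
           x$bins$mean_response + x$bins$sem_response)
  lines(bgrid, predict(x, bgrid), col = "red3", lwd = 2)
  abline(h = 0, lty = 3)
  invisible(x)
}

#' Apply the reversion correction to evoked responses
#'
#' Subtracts the cubic prediction of the spontaneous drift (given each
#' trial's observed baseline) from the observed evoked response, adding a
#' `<response>_corrected` column.  The uncorrected column is retained so
#' that corrected and uncorrected analyses can be compared.  Applying the
#' correction twice to the same column is an error.
#'
#' @param trials a trial table.
#' @param model a [reversion_model()] fitted on the same signal kind and
#'   windows.
#' @param response,baseline column names to correct from.
#' @return the trial table with the corrected column added.
#' @export
apply_correction <- function(trials, model, response = "response_pupil",
                             baseline = "baseline_pupil") {
  out_col <- paste0(response, "_corrected")
  if (out_col %in% names(trials)) {
    stop("column '", out_col, "' already exists: the correction must not ",
         "be applied twice")
  }
  b <- trials[[baseline]]
  outside <- is.finite(b) &
    (b < model$baseline_range[1] | b > model$baseline_range[2])
  if (any(outside)) {
    warning(sum(outside), " trial(s) have baselines outside the fitted ",
            "range; correction extrapolates")
  }
  trials[[out_col]] <- trials[[response]] - predict(model, b)
  trials
}
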