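#' Session-wise current leak fraction
#'
#' L = 1 - A_m / A_i, where A_m is the mean across the minimum measured
#' amplitude for each unique (pulse width, rate) group -- restricted to
#' widths of at least `min_width_ms`, because narrower pulses are
#' attenuated by the pulse-width filter rather than by leakage -- and A_i
#' is the session's minimum intended amplitude.
#'
#' @param measured data frame with `width_ms`, `rate_hz`, `intended_ma`,
#'   `measured_ma` per pulse or train (see [generate_measured_current()]).
#' @param intended_min_ma minimum intended amplitude A_i; defaults to the
#'   minimum of `intended_ma`.
#' @param min_width_ms smallest width eligible for the leak estimate
#'   (default 0.4 ms, i.e. the 0.1 and 0.2 ms widths are excluded).
#' @return leak fraction L (dimensionless).  Small negative values can
#'   arise from measurement noise and are flagged with a warning; values
#'   below -0.05 are an error.
#' @export
leak_fraction <- function(measured, intended_min_ma = NULL,
                          min_width_ms = 0.4) {
  el <- measured[measured$width_ms >= min_width_ms, , drop = FALSE]
  if (!nrow(el)) stop("no eligible pulse widths (>= ", min_width_ms, " ms)")
  if (is.null(intended_min_ma)) intended_min_ma <- min(measured$intended_ma)
  grp <- interaction(el$width_ms, el$rate_hz, drop = TRUE)
  A_m <- mean(tapply(el$measured_ma, grp, min))
  L <- 1 - A_m / intended_min_ma
  if (L < -0.05) stop("leak fraction ", signif(L, 3), " below -0.05: ",
                      "measured exceeds intended beyond noise tolerance")
  if (L < 0) warning("slightly negative leak fraction (", signif(L, 3),
                     "): treated as measurement noise")
  L
}

#' Fit the sigmoidal pulse-width filter
#'
#' Least-squares fit of A_m(W) = s / (1 + exp(-a (W - b))) to the mean
#' measured amplitude per pulse width: s is the wide-pulse plateau, b the
#' width at half plateau, and a the steepness of the attenuation affecting
#' narrow pulses.
#'
#' @param measured data frame as in [leak_fraction()]; amplitudes are
#'   averaged per unique width before fitting.
#' @return a `width_filter_fit` with `print`, `coef` and `predict`
#'   methods.  A flat measured profile is detected as degenerate: the
#'   plateau is set to the mean with a warning.
#' @export
width_filter_fit <- function(measured) {
  W <- sort(unique(measured$width_ms))
  if (length(W) < 3) stop("need at least 3 distinct pulse widths")
  A <- as.numeric(tapply(measured$measured_ma, measured$width_ms, mean))
  if (sd(A) < 1e-3 * max(abs(A))) {
    warning("measured amplitudes are flat across widths; degenerate fit ",
            "(plateau = mean, no attenuation)")
    par <- c(s = mean(A), a = Inf, b = min(W) / 2)
    return(structure(list(par = par, widths = W, measured = A,
                          degenerate = TRUE),
                     class = "width_filter_fit"))
  }
  obj <- function(p) sum((A - p[1] / (1 + exp(-p[2] * (W - p[3]))))^2)
  best <- NULL
  for (a0 in c(5, 10, 20, 40)) {
    for (b0 in quantile(W, c(0.1, 0.25, 0.5), names = FALSE)) {
      res <- tryCatch(
        optim(c(max(A), a0, b0), obj, method = "L-BFGS-B",
              lower = c(0, 0.1, 0), upper = c(10 * max(A), 1000, max(W))),
        error = function(e) NULL)
      if (!is.null(res) && is.finite(res$value) &&
          (is.null(best) || res$value < best$value)) best <- res
    }
  }
  if (is.null(best)) {
    stop("sigmoid fit did not converge; measured amplitudes were: ",
         paste(signif(A, 4), collapse = ", "))
  }
  par <- setNames(best$par, c("s", "a", "b"))
  structure(list(par = par, widths = W, measured = A, ssr = best$value,
                 degenerate = FALSE),
            class = "width_filter_fit")
}

#' @export
coef.width_filter_fit <- function(object, ...) object$par

#' @export
predict.width_filter_fit <- function(object, width_ms = object$widths, ...) {
  p <- object$par
  if (object$degenerate) return(rep(p["s"], length(width_ms)))
  unname(p["s"] / (1 + exp(-p["a"] * (width_ms - p["b"]))))
}

#' @export
print.width_filter_fit <- function(x, ...) {
  cat("Pulse-width filter (sigmoid fit)\n")
  if (x$degenerate) {
    cat(sprintf("  degenerate (flat): plateau = %.4g mA\n", x$par["s"]))
  } else {
    cat(sprintf("  plateau s = %.4g mA, steepness a = %.4g /ms, half-plateau width b = %.4g ms\n",
                x$par["s"], x$par["a"], x$par["b"]))
  }
  invisible(x)
}

#' Joint leak and filter characterization
#'
#' Convenience wrapper running [leak_fraction()] and [width_filter_fit()]
#' on one measured-current table.
#'
#' @inheritParams leak_fraction
#' @return list with `leak` and `filter`.
#' @export
characterize_electronics <- function(measured, intended_min_ma = NULL,
                                     min_width_ms = 0.4) {
  list(leak = leak_fraction(measured, intended_min_ma, min_width_ms),
       filter = width_filter_fit(measured))
}
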