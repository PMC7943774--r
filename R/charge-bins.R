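#' Assign trials to log-spaced charge/pulse bins
#'
#' Partitions the tested charge range into `n_bins` equal log10-width bins
#' (default 5) and labels each trial.  Bins are half-open on the right
#' except the last, so every tested (amplitude, width) combination maps to
#' exactly one bin.  Bin 1 is labelled `no-effect`, the intermediate bins
#' `optimal` and the top bin `off-target`, following the zones defined by
#' the intact- vs cut-nerve comparison.
#'
#' @param trials trial table (or data frame with `charge_upc`).
#' @param n_bins number of bins (>= 2).
#' @return a `charge_bins` object: `edges` (uC), `labels`, per-trial `bin`,
#'   and the unique combination-to-bin `mapping` table.
#' @export
assign_charge_bins <- function(trials, n_bins = 5) {
  if (n_bins < 2) stop("n_bins must be at least 2")
  df <- as.data.frame(trials)
  charge <- df$charge_upc
  if (is.null(charge)) charge <- df$amplitude_ma * df$width_ms
  if (any(charge <= 0)) stop("charges must be positive")
  lo <- min(charge); hi <- max(charge)
  if (lo == hi) {
    warning("all trials share one charge; single occupied bin")
    edges <- 10^seq(log10(lo) - 0.5, log10(hi) + 0.5,
                    length.out = n_bins + 1)
  } else {
    edges <- 10^seq(log10(lo), log10(hi), length.out = n_bins + 1)
  }
  bin <- findInterval(log10(charge), log10(edges),
                      rightmost.closed = TRUE, all.inside = TRUE)
  labels <- c("no-effect", rep("optimal", n_bins - 2), "off-target")
  mapping <- unique(data.frame(amplitude_ma = df$amplitude_ma,
                               width_ms = df$width_ms,
                               charge_upc = charge, bin = bin))
  mapping <- mapping[order(mapping$charge_upc), ]
  rownames(mapping) <- NULL
  structure(list(edges = edges, labels = labels, bin = bin,
                 n_bins = n_bins, mapping = mapping),
            class = "charge_bins")
}

#' @export
print.charge_bins <- function(x, ...) {
  cat(sprintf("Charge/pulse bins (%d, log-spaced over %.3g-%.3g uC)\n",
              x$n_bins, x$edges[1], x$edges[length(x$edges)]))
  for (b in seq_len(x$n_bins)) {
    cat(sprintf("  bin %d [%s]: %.3g-%.3g uC, %d trials\n", b,
                x$labels[b], x$edges[b], x$edges[b + 1], sum(x$bin == b)))
  }
  invisible(x)
}

#' Binwise significance tests with FDR control
#'
#' Tests the evoked response in each charge bin x train rate cell, either
#' against zero (two-sided one-sample t test; pupil, eyelid, walking) or
#' against the lowest charge bin (two-sided paired t test, pairing trials
#' of the same rate by within-cell position; used for calcium, whose
#' region of interest was itself selected by responsiveness, so a test
#' against zero would be circular).  Raw p-values are adjusted with the
#' Benjamini-Hochberg procedure across all testable cells.
#'
#' @param trials trial table.
#' @param bins an [assign_charge_bins()] result for the same trials.
#' @param response response column to test.
#' @param mode `"vs_zero"` or `"vs_lowest_bin"`.
#' @param q FDR level for the significance stars (default 0.05).
#' @param exclude_artifacts drop flagged trials first.
#' @return a `charge_bin_tests` data frame: per cell the mean, s.e.m., n,
#'   t statistic, raw and adjusted p, and stars (`***` < 0.001,
#'   `**` < 0.01, `*` < 0.05 on adjusted p).
#' @export
binwise_tests <- function(trials, bins, response = "response_pupil",
                          mode = c("vs_zero", "vs_lowest_bin"), q = 0.05,
                          exclude_artifacts = TRUE) {
  mode <- match.arg(mode)
  df <- as.data.frame(trials)
  df$bin <- bins$bin
  if (exclude_artifacts && "artifact" %in% names(df)) {
    df <- df[!df$artifact, , drop = FALSE]
  }
  df <- df[is.finite(df[[response]]), , drop = FALSE]
  rates <- sort(unique(df$rate_hz))
  rows <- list()
  for (r in rates) {
    for (b in sort(unique(df$bin))) {
      v <- df[[response]][df$bin == b & df$rate_hz == r]
      row <- data.frame(bin = b, label = bins$labels[b], rate_hz = r,
                        n = length(v), mean = mean(v),
                        sem = sd(v) / sqrt(length(v)),
                        stat = NA_real_, p = NA_real_)
      if (mode == "vs_zero") {
        if (length(v) >= 2 && sd(v) > 0) {
          tt <- t.test(v)
          row$stat <- unname(tt$statistic)
          row$p <- tt$p.value
        }
      } else if (b > min(df$bin)) {
        ref <- df[[response]][df$bin == min(df$bin) & df$rate_hz == r]
        m <- min(length(v), length(ref))
        if (m >= 2) {
          tt <- t.test(v[seq_len(m)], ref[seq_len(m)], paired = TRUE)
          if (is.finite(tt$statistic)) {
            row$stat <- unname(tt$statistic)
            row$p <- tt$p.value
          }
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  adj <- bh_fdr(out$p, q)
  out$p_adj <- adj$p_adjusted
  out$significant <- adj$reject
  out$stars <- ifelse(is.na(out$p_adj), "",
                      ifelse(out$p_adj < 0.001, "***",
                             ifelse(out$p_adj < 0.01, "**",
                                    ifelse(out$p_adj < 0.05, "*", ""))))
  attr(out, "mode") <- mode
  attr(out, "q") <- q
  class(out) <- c("charge_bin_tests", "data.frame")
  out
}

#' @export
print.charge_bin_tests <- function(x, ...) {
  cat(sprintf("Binwise tests (%s, BH-FDR at q = %g)\n", attr(x, "mode"),
              attr(x, "q")))
  print.data.frame(cbind(format(as.data.frame(x)[c("bin", "label", "rate_hz",
                                                   "n")]),
                         mean = sprintf("%.3f", x$mean),
                         p_adj = ifelse(is.na(x$p_adj), "-",
                                        sprintf("%.4f", x$p_adj)),
                         sig = x$stars),
                   row.names = FALSE)
  invisible(x)
}
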