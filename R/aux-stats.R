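#' Sequential polynomial regression with orthogonalized regressors
#'
#' Tests whether incrementally adding higher polynomial orders of X
#' explains significantly more variance in Y.  The design columns
#' [1, X, X^2, ...] are orthogonalized by QR decomposition (so each added
#' column contributes variance independently of the lower orders), models
#' of increasing order are fitted, and each increment is tested with
#' \deqn{F = \frac{SS_{k-1} - SS_k}{SS_{max} / df_{max}}}
#' where the denominator comes from the maximal-order model.  The selected
#' order is the last in the sequence of consecutively significant
#' increments (p < 0.05).  A per-order BIC,
#' n ln(SS/n) + k ln(n), is reported alongside with the conventional
#' Delta-BIC >= 10 decision rule; additive likelihood constants cancel in
#' the differences.
#'
#' @param Y dependent variable.
#' @param X independent variable (finite, non-constant).
#' @param max_order highest polynomial order (default 2, i.e. up to a
#'   quadratic, the inverted-U detector).
#' @return a `seq_poly` object: orthogonal-basis coefficients, per-step F,
#'   df, p, per-order BIC, and the orders selected by F tests and by BIC.
#' @export
sequential_poly_regression <- function(Y, X, max_order = 2) {
  ok <- is.finite(Y) & is.finite(X)
  Y <- Y[ok]; X <- X[ok]
  n <- length(Y)
  if (n <= max_order + 1) stop("need n > max_order + 1 observations")
  if (sd(X) == 0) stop("constant X: polynomial design is rank-deficient")
  V <- outer(X, 0:max_order, `^`)
  qrd <- qr(V)
  if (qrd$rank < ncol(V)) stop("polynomial design is rank-deficient")
  Q <- qr.Q(qrd)
  g <- drop(crossprod(Q, Y))            # coefficients on orthonormal basis
  ss_res <- sum(Y^2) - cumsum(g^2)      # residual SS for order 0..max
  df_full <- n - (max_order + 1)
  ms_full <- ss_res[max_order + 1] / df_full
  Fstat <- (ss_res[seq_len(max_order)] - ss_res[-1]) / ms_full
  pval <- pf(Fstat, 1, df_full, lower.tail = FALSE)
  sig <- pval < 0.05
  selected <- if (any(!sig)) which(!sig)[1] - 1L else max_order
  bic <- n * log(ss_res / n) + (seq_len(max_order + 1)) * log(n)
  sel_bic <- 0L
  for (k in seq_len(max_order)) {
    if (bic[sel_bic + 1L] - bic[k + 1L] >= 10) sel_bic <- k
  }
  structure(list(coefficients = g, ss_res = ss_res,
                 F = Fstat, df = c(1, df_full), p = pval,
                 bic = setNames(bic, paste0("order", 0:max_order)),
                 selected_order = selected, selected_order_bic = sel_bic,
                 n = n, max_order = max_order, Q = Q),
            class = "seq_poly")
}

#' @export
print.seq_poly <- function(x, ...) {
  cat(sprintf("Sequential polynomial regression (n = %d, up to order %d)\n",
              x$n, x$max_order))
  for (k in seq_len(x$max_order)) {
    cat(sprintf("  order %d vs %d: F(1,%d) = %.3f, p = %.4g%s\n", k, k - 1,
                x$df[2], x$F[k], x$p[k],
                if (x$p[k] < 0.05) " *" else ""))
  }
  cat(sprintf("  selected order: %d (F tests), %d (Delta-BIC >= 10)\n",
              x$selected_order, x$selected_order_bic))
  cat("  BIC:", paste(sprintf("%s = %.1f", names(x$bic), x$bic),
                      collapse = ", "), "\n")
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up BH adjustment (via [stats::p.adjust()]) with a rejection mask at
#' level `q`.  Missing p-values are excluded from the family and stay `NA`.
#'
#' @param p vector of p-values in [0, 1] (NA allowed).
#' @param q FDR level (default 0.05).
#' @return list with `p_adjusted` and logical `reject`.
#' @export
bh_fdr <- function(p, q = 0.05) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  adj <- rep(NA_real_, length(p))
  adj[ok] <- p.adjust(p[ok], method = "BH")
  reject <- adj <= q
  reject[!ok] <- NA
  list(p_adjusted = adj, reject = reject)
}

#' Cluster-based permutation test of a pixel response map
#'
#' One-sample test of per-pixel evoked responses against zero with
#' cluster-level multiple-comparison correction: per-pixel t statistics
#' are thresholded (two-sided p < `pixel_alpha`), suprathreshold pixels
#' are grouped into 4-connected clusters scored by their summed t, and the
#' null distribution of the maximal cluster score is built from random
#' per-trial sign flips.  Cluster p-values are (1 + #null >= observed) /
#' (1 + n_perm); the significant mask keeps pixels of clusters with
#' p < `cluster_alpha`.
#'
#' @param responses trials x pixels matrix of per-trial evoked responses
#'   (e.g. from [pixel_trial_responses()]).
#' @param dim image dimensions `(rows, cols)` with `prod(dim) ==
#'   ncol(responses)`.
#' @param n_perm number of sign-flip permutations (default 10000).
#' @param cluster_alpha cluster-level significance threshold (default
#'   0.01).
#' @param pixel_alpha cluster-forming (pixel-level) two-sided threshold
#'   (default 0.05).
#' @param seed integer seed for the permutations.
#' @return a `cluster_map`: `t_map` and cluster `labels` matrices, the
#'   cluster table with p-values, the significant-pixel mask and its count.
#' @export
cluster_permutation_map <- function(responses, dim, n_perm = 10000,
                                    cluster_alpha = 0.01,
                                    pixel_alpha = 0.05, seed = 1) {
  n <- nrow(responses)
  if (n < 8) stop("need at least 8 trials")
  npix <- ncol(responses)
  stopifnot(prod(dim) == npix)
  old <- local_rng(seed)
  on.exit(restore_rng(old), add = TRUE)

  sums <- colSums(responses)
  sumsq <- colSums(responses^2)
  tfun <- function(s) {
    m <- s / n
    v <- (sumsq - s^2 / n) / (n - 1)
    tv <- m / sqrt(v / n)
    tv[!is.finite(tv)] <- 0    # zero-variance pixels carry no evidence
    tv
  }
  t_obs <- tfun(sums)
  thr <- qt(1 - pixel_alpha / 2, df = n - 1)

  lab <- label_clusters_cpp(t_obs, as.integer(dim[1]), as.integer(dim[2]),
                            thr)
  labels <- matrix(lab$labels, dim[1], dim[2])
  n_clust <- length(lab$mass)

  flips <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  perm_sums <- flips %*% responses           # n_perm x npix
  null_max <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    null_max[i] <- max_cluster_mass_cpp(tfun(perm_sums[i, ]),
                                        as.integer(dim[1]),
                                        as.integer(dim[2]), thr)
  }

  cluster_p <- if (n_clust) {
    vapply(abs(lab$mass), function(m) {
      (1 + sum(null_max >= m)) / (1 + n_perm)
    }, numeric(1))
  } else numeric(0)
  sig_clusters <- which(cluster_p < cluster_alpha)
  sig_mask <- matrix(labels %in% sig_clusters, dim[1], dim[2])
  tab <- data.frame(cluster = seq_len(n_clust),
                    size = lab$size, mass = lab$mass, p = cluster_p)
  structure(list(t_map = matrix(t_obs, dim[1], dim[2]), labels = labels,
                 clusters = tab, sig_mask = sig_mask,
                 n_significant_pixels = sum(sig_mask),
                 n_perm = n_perm, cluster_alpha = cluster_alpha,
                 pixel_alpha = pixel_alpha, threshold_t = thr),
            class = "cluster_map")
}

#' @export
print.cluster_map <- function(x, ...) {
  cat(sprintf("Cluster permutation map: %d x %d pixels, %d permutations\n",
              nrow(x$t_map), ncol(x$t_map), x$n_perm))
  sig <- x$clusters[x$clusters$p < x$cluster_alpha, , drop = FALSE]
  cat(sprintf("  %d cluster(s), %d significant at p < %g; %d significant pixels\n",
              nrow(x$clusters), nrow(sig), x$cluster_alpha,
              x$n_significant_pixels))
  invisible(x)
}

#' Phase-locked spectral power of eye movements
#'
#' Sliding-window (1 s Hanning, 0.25 s hop) spectrogram of onset-locked
#' eye-position epochs, averaged over trials, expressed per frequency as
#' percent signal change relative to the pre-stimulation baseline window.
#' The scalar summary is the mean percent change at the frequency bin
#' nearest the pulse-train rate over the 10 s train -- the signature of
#' stimulation current reaching the eye in grounded preparations.
#'
#' @param epochs an [epoch_signal()] matrix of an eye-position channel (or
#'   a plain trials x time matrix with a `time` attribute).
#' @param train_rate_hz stimulation pulse rate, Hz; must be below the
#'   Nyquist frequency of the conditioned signal.
#' @param sample_rate_hz sampling rate of the epochs (taken from the
#'   attribute if present).
#' @param window_s Hanning window length, seconds.
#' @param hop_s hop between window centres, seconds.
#' @param baseline_window baseline for the percent change, seconds
#'   relative to onset (default -5.5 to -0.5).
#' @param train_window averaging window for the scalar (default the 10 s
#'   train).
#' @return a `spectral_result`: `freq`, `time`, `pct_change` matrix
#'   (freq x time) and the `scalar` phase-locked power.
#' @export
phase_locked_power <- function(epochs, train_rate_hz,
                               sample_rate_hz = attr(epochs, "rate"),
                               window_s = 1, hop_s = 0.25,
                               baseline_window = c(-5.5, -0.5),
                               train_window = c(0, 10)) {
  if (is.null(sample_rate_hz)) stop("sample rate not supplied")
  if (train_rate_hz >= sample_rate_hz / 2) {
    stop("train rate is at or above the Nyquist frequency")
  }
  tm <- attr(epochs, "time")
  nwin <- round(window_s * sample_rate_hz)
  hop <- max(1L, round(hop_s * sample_rate_hz))
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nwin) / (nwin + 1))  # Hanning
  starts <- seq(1L, ncol(epochs) - nwin + 1L, by = hop)
  centres <- tm[starts] + window_s / 2
  freq <- (seq_len(nwin %/% 2 + 1) - 1) * sample_rate_hz / nwin
  pow <- matrix(0, length(freq), length(starts))
  n_tr <- 0L
  for (i in seq_len(nrow(epochs))) {
    x <- epochs[i, ]
    if (anyNA(x)) next
    n_tr <- n_tr + 1L
    for (j in seq_along(starts)) {
      seg <- x[starts[j]:(starts[j] + nwin - 1L)] * win
      sp <- abs(stats::fft(seg))^2
      pow[, j] <- pow[, j] + sp[seq_along(freq)]
    }
  }
  if (n_tr == 0L) stop("no complete epochs")
  pow <- pow / n_tr
  bsel <- centres >= baseline_window[1] & centres < baseline_window[2]
  if (!any(bsel)) stop("baseline window not covered by the epochs")
  base <- rowMeans(pow[, bsel, drop = FALSE])
  pct <- 100 * sweep(sweep(pow, 1, base, "-"), 1, base, "/")
  fbin <- which.min(abs(freq - train_rate_hz))
  tsel <- centres >= train_window[1] & centres < train_window[2]
  scalar <- mean(pct[fbin, tsel])
  structure(list(freq = freq, time = centres, pct_change = pct,
                 scalar = scalar, train_rate_hz = train_rate_hz,
                 freq_bin = freq[fbin], n_trials = n_tr),
            class = "spectral_result")
}

#' @export
print.spectral_result <- function(x, ...) {
  cat(sprintf("Phase-locked power at %g Hz (bin %g Hz): %.1f%% change vs baseline (%d trials)\n",
              x$train_rate_hz, x$freq_bin, x$scalar, x$n_trials))
  invisible(x)
}
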