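#' Cross-validated nerve-engagement prediction
#'
#' Builds the per-trial engagement vector N by K-fold cross-validation
#' (default 20-fold): in each fold the log-logistic surface is fitted to
#' the training trials' pupil responses and evaluated at the held-out
#' trials' stimulation parameters, so every trial's N comes from a model
#' that never saw that trial.  Folds are stratified by charge bin so every
#' training set spans the tested dose range.  N reduces the
#' three-dimensional parameter space to one dose axis on the response
#' scale, letting the downstream mediation analysis use ordinary linear
#' regressions.
#'
#' @param trials trial table.
#' @param response response column the surface is fitted to.
#' @param folds number of folds; `folds = nrow(trials)` gives
#'   leave-one-out.
#' @param model surface model used per fold (default `"full"`).
#' @param seed integer seed for the fold partition.
#' @param exclude_artifacts drop flagged trials first.
#' @return an `engagement_cv` object: `engagement` (N per used trial),
#'   `fold` assignment, the row index into `trials`, and per-fold fit
#'   provenance.
#' @export
predict_engagement_cv <- function(trials, response = "response_pupil",
                                  folds = 20, model = "full", seed = 1,
                                  exclude_artifacts = TRUE) {
  df <- as.data.frame(trials)
  if (exclude_artifacts && "artifact" %in% names(df)) {
    keep <- !df$artifact & is.finite(df[[response]])
  } else {
    keep <- is.finite(df[[response]])
  }
  idx <- which(keep)
  df <- df[keep, , drop = FALSE]
  n <- nrow(df)
  if (folds < 2 || folds > n) stop("folds must be in [2, n]")
  old <- local_rng(seed)
  on.exit(restore_rng(old), add = TRUE)
  # stratified balanced partition: shuffle within strata, then deal fold
  # labels cyclically across the stratum-ordered list (random phase), so
  # fold sizes differ by at most one and each stratum spreads over folds
  strata <- assign_charge_bins(df)$bin
  ord <- unlist(lapply(sample(unique(strata)), function(s) {
    sample(which(strata == s))
  }))
  fold <- integer(n)
  fold[ord] <- (sample.int(folds, 1) + seq_len(n)) %% folds + 1L
  N <- rep(NA_real_, n)
  provenance <- vector("list", folds)
  for (k in sort(unique(fold))) {
    test <- fold == k
    fit <- tryCatch(
      loglogistic_fit(df[!test, , drop = FALSE], response, model,
                      exclude_artifacts = FALSE, start_grid = "median"),
      error = function(e) NULL)
    if (is.null(fit)) {
      # merge a failing fold into its neighbour and refit
      merged <- fold == k | fold == (k %% folds) + 1
      fit <- loglogistic_fit(df[!merged, , drop = FALSE], response, model,
                             exclude_artifacts = FALSE,
                             start_grid = "median")
    }
    N[test] <- predict(fit, df[test, , drop = FALSE])
    provenance[[k]] <- list(fold = k, n_train = sum(!test),
                            par = coef(fit))
  }
  structure(list(engagement = N, fold = fold, index = idx,
                 response = response, model = model, folds = folds,
                 provenance = provenance),
            class = "engagement_cv")
}

#' @export
print.engagement_cv <- function(x, ...) {
  cat(sprintf("Cross-validated nerve engagement: %d trials, %d folds (%s surface)\n",
              length(x$engagement), x$folds, x$model))
  cat(sprintf("  N range: %.3g-%.3g\n", min(x$engagement),
              max(x$engagement)))
  invisible(x)
}

#' Mediation path analysis
#'
#' Fits the three ordinary least-squares path models of a standard
#' mediation analysis of the effect of nerve engagement N on the pupil
#' response P via the calcium (cholinergic) response C:
#' \deqn{P = i_0 + cN \quad (total)\qquad C = i_1 + aN \qquad
#'   P = i_2 + c'N + bC \quad (direct + mediator)}
#' The indirect (mediated) effect is a x b, and for OLS with these
#' regressor sets the identity c = c' + a b holds exactly; the proportion
#' mediated is a b / c, reported only when |c| exceeds twice its standard
#' error.
#'
#' @param P pupil responses (vector).
#' @param C calcium responses (vector).
#' @param N engagement vector (numeric or an [predict_engagement_cv()]
#'   object; when the latter, P and C are subset to its trial index).
#' @return a `mediation_fit` with coefficients, intercepts, derived
#'   effects and methods `print`, `summary`, `coef`.
#' @export
mediation_fit <- function(P, C, N) {
  if (inherits(N, "engagement_cv")) {
    idx <- N$index
    N <- N$engagement
    if (length(P) != length(N)) P <- P[idx]
    if (length(C) != length(N)) C <- C[idx]
  }
  ok <- complete.cases(P, C, N)
  P <- P[ok]; C <- C[ok]; N <- N[ok]
  n <- length(P)
  if (n < 4) stop("need at least 4 complete trials")
  if (sd(N) == 0) stop("engagement vector is constant")
  if (abs(cor(N, C)) > 0.999) stop("N and C are collinear (|r| > 0.999)")
  m_total <- lm(P ~ N)
  m_a <- lm(C ~ N)
  m_med <- lm(P ~ N + C)
  cf_t <- coef(m_total); cf_a <- coef(m_a); cf_m <- coef(m_med)
  c_tot <- unname(cf_t["N"])
  a <- unname(cf_a["N"])
  b <- unname(cf_m["C"])
  c_dir <- unname(cf_m["N"])
  se_c <- summary(m_total)$coefficients["N", "Std. Error"]
  prop <- if (abs(c_tot) >= 2 * se_c) a * b / c_tot else NA_real_
  structure(list(
    c = c_tot, a = a, b = b, c_prime = c_dir,
    indirect = a * b,
    proportion_mediated = prop,
    intercepts = c(i0 = unname(cf_t[1]), i1 = unname(cf_a[1]),
                   i2 = unname(cf_m[1])),
    se = c(c = se_c,
           a = summary(m_a)$coefficients["N", "Std. Error"],
           b = summary(m_med)$coefficients["C", "Std. Error"],
           c_prime = summary(m_med)$coefficients["N", "Std. Error"]),
    n = n,
    models = list(total = m_total, mediator = m_a, outcome = m_med)),
    class = "mediation_fit")
}

#' @export
coef.mediation_fit <- function(object, ...) {
  c(c = object$c, a = object$a, b = object$b, c_prime = object$c_prime,
    indirect = object$indirect)
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat(sprintf("Mediation path analysis (n = %d trials)\n", x$n))
  cat(sprintf("  total effect      c  = %.4g (SE %.3g)\n", x$c, x$se["c"]))
  cat(sprintf("  engagement->Ca    a  = %.4g (SE %.3g)\n", x$a, x$se["a"]))
  cat(sprintf("  Ca->pupil         b  = %.4g (SE %.3g)\n", x$b, x$se["b"]))
  cat(sprintf("  direct effect     c' = %.4g (SE %.3g)\n", x$c_prime,
              x$se["c_prime"]))
  cat(sprintf("  indirect (a x b)     = %.4g\n", x$indirect))
  if (is.na(x$proportion_mediated)) {
    cat("  proportion mediated not reported (|c| < 2 SE)\n")
  } else {
    cat(sprintf("  proportion mediated  = %.1f%%\n",
                100 * x$proportion_mediated))
  }
  invisible(x)
}

#' @export
summary.mediation_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Bootstrap the mediation effects
#'
#' Resamples trials with replacement and refits the three path models,
#' returning draws of the total, indirect and direct effects and the
#' fraction of draws below zero for each (the one-sided sign statistic).
#'
#' @inheritParams mediation_fit
#' @param n_boot bootstrap replicates (default 5000).
#' @param seed integer seed.
#' @return a `mediation_boot` object with `draws` (n_boot x 3) and
#'   `sign_fraction`.
#' @export
bootstrap_mediation <- function(P, C, N, n_boot = 5000, seed = 1) {
  if (inherits(N, "engagement_cv")) {
    idx <- N$index
    N <- N$engagement
    if (length(P) != length(N)) P <- P[idx]
    if (length(C) != length(N)) C <- C[idx]
  }
  ok <- complete.cases(P, C, N)
  P <- P[ok]; C <- C[ok]; N <- N[ok]
  mediation_fit(P, C, N)   # errors early if the full-sample fit fails
  n <- length(P)
  old <- local_rng(seed)
  on.exit(restore_rng(old), add = TRUE)
  draws <- matrix(NA_real_, n_boot, 3,
                  dimnames = list(NULL, c("total", "indirect", "direct")))
  degenerate <- 0L
  one <- cbind(1)
  for (bi in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    Nb <- N[idx]; Cb <- C[idx]; Pb <- P[idx]
    if (sd(Nb) == 0 || sd(Cb) == 0 || abs(cor(Nb, Cb)) > 0.999) {
      degenerate <- degenerate + 1L
      next
    }
    ct <- lm.fit(cbind(1, Nb), Pb)$coefficients[2]
    aa <- lm.fit(cbind(1, Nb), Cb)$coefficients[2]
    cm <- lm.fit(cbind(1, Nb, Cb), Pb)$coefficients
    draws[bi, ] <- c(ct, aa * cm[3], cm[2])
  }
  if (degenerate > 0.05 * n_boot) {
    stop("more than 5% of bootstrap resamples were degenerate")
  }
  draws <- draws[stats::complete.cases(draws), , drop = FALSE]
  structure(list(draws = draws,
                 sign_fraction = colMeans(draws < 0),
                 n_boot = n_boot, n_degenerate = degenerate),
            class = "mediation_boot")
}

#' @export
print.mediation_boot <- function(x, ...) {
  q <- apply(x$draws, 2, quantile, probs = c(0.025, 0.5, 0.975))
  cat(sprintf("Bootstrapped mediation effects (%d replicates)\n",
              nrow(x$draws)))
  for (nm in colnames(x$draws)) {
    cat(sprintf("  %-9s median %.4g [%.4g, %.4g], Pr(<0) = %.4f\n", nm,
                q[2, nm], q[1, nm], q[3, nm], x$sign_fraction[nm]))
  }
  invisible(x)
}

#' Partial correlation of pupil and calcium after removing engagement
#'
#' Residualizes P and C each on N (linear OLS), correlates the residuals,
#' and runs the sequential polynomial regression on the residual
#' relationship to ask whether it is linear or curved.  A positive partial
#' correlation means pupil and calcium covary beyond what the stimulation
#' parameters predict.
#'
#' @inheritParams mediation_fit
#' @return list with `r`, `p` (Pearson test on residuals) and `poly`
#'   (a [sequential_poly_regression()] result).
#' @export
partial_residual_correlation <- function(P, C, N) {
  if (inherits(N, "engagement_cv")) {
    idx <- N$index
    N <- N$engagement
    if (length(P) != length(N)) P <- P[idx]
    if (length(C) != length(N)) C <- C[idx]
  }
  ok <- complete.cases(P, C, N)
  P <- P[ok]; C <- C[ok]; N <- N[ok]
  rP <- lm.fit(cbind(1, N), P)$residuals
  rC <- lm.fit(cbind(1, N), C)$residuals
  ct <- cor.test(rP, rC)
  poly <- sequential_poly_regression(rP, rC)
  list(r = unname(ct$estimate), p = ct$p.value, poly = poly,
       residuals = data.frame(pupil = rP, calcium = rC))
}
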