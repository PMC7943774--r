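#' Fit a multivariate log-logistic dose-response surface
#'
#' Fits, by nonlinear least squares on trial-level responses, either the
#' full separable surface over pulse amplitude A (mA), width W (ms) and
#' rate R (Hz)
#' \deqn{P = \frac{s}{1+(A/a_1)^{-b_1}} \times \frac{1}{1+(W/a_2)^{-b_2}}
#'   \times \frac{1}{1+(R/a_3)^{-b_3}}}
#' or the reduced surface over charge/pulse C = A x W (uC) and rate
#' \deqn{P = \frac{s}{1+(C/a_1)^{-b_1}} \times \frac{1}{1+(R/a_2)^{-b_2}}.}
#' Each midpoint \eqn{a_i} is the factor value at which that factor's
#' sigmoid reaches half of its saturating contribution; in the reduced
#' model \eqn{a_1} is the half-maximal charge.
#'
#' Optimization is bounded multi-start L-BFGS-B: scale starts at the
#' maximal cell mean, midpoints at the 25th/50th/75th percentiles of the
#' observed factor values, shapes at 1 and 2; bounds keep a within
#' [min/10, max*10] of the tested values and b within [0.1, 20].  Because
#' predictions depend on the factors only through the unique tested
#' combinations, the trial-level sum of squares is evaluated exactly on
#' count-weighted cell means (plus the constant within-cell sum of
#' squares), which makes the fit cheap at any number of repetitions.
#'
#' @param trials trial table (or any data frame) with columns
#'   `amplitude_ma`, `width_ms`, `rate_hz` and the response column.
#' @param response name of the response column.
#' @param model `"full"` (7 parameters) or `"reduced"` (5 parameters).
#' @param s_sign `"positive"` constrains the scale s to be nonnegative
#'   (pupil, calcium); `"free"` allows a signed scale (eyelid, walking).
#' @param exclude_artifacts drop rows flagged `artifact` before fitting.
#' @param start_grid `"quartiles"` (the full multi-start grid),
#'   `"median"` (a lighter grid starting midpoints at the median factor
#'   value only; used for the many per-fold fits of the cross-validated
#'   engagement predictor) or `"none"` (use only `start_par`).
#' @param start_par optional named start vector (e.g. a previous fit's
#'   parameters, for warm-started bootstrap refits).
#' @return a `loglogistic_fit` with methods `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals`, `plot` and `simulate`.  Fields
#'   include `ve` (percent of trialwise variance explained) and the
#'   cell-level summary used for plotting.
#' @examples
#' tr <- generate_protocol(seed = 2)
#' tr <- as.data.frame(tr)
#' tr$response <- eval_surface(vns_truth()$surface$pupil,
#'                             tr$amplitude_ma, tr$width_ms, tr$rate_hz)
#' fit <- loglogistic_fit(tr, response = "response", model = "reduced")
#' coef(fit)["a1"]   # half-maximal charge, uC
#' @export
loglogistic_fit <- function(trials, response = "response_pupil",
                            model = c("full", "reduced"),
                            s_sign = c("positive", "free"),
                            exclude_artifacts = TRUE,
                            start_grid = c("quartiles", "median", "none"),
                            start_par = NULL) {
  model <- match.arg(model)
  s_sign <- match.arg(s_sign)
  start_grid <- match.arg(start_grid)
  df <- as.data.frame(trials)
  if (!response %in% names(df)) stop("no response column '", response, "'")
  if (exclude_artifacts && "artifact" %in% names(df)) {
    df <- df[!df$artifact, , drop = FALSE]
  }
  if (!"charge_upc" %in% names(df)) {
    df$charge_upc <- df$amplitude_ma * df$width_ms
  }
  P <- df[[response]]
  keep <- is.finite(P)
  df <- df[keep, , drop = FALSE]
  P <- P[keep]
  if (!length(P)) stop("no finite responses to fit")
  factors <- if (model == "full") {
    list(A = df$amplitude_ma, W = df$width_ms, R = df$rate_hz)
  } else {
    list(C = df$charge_upc, R = df$rate_hz)
  }
  fit <- ll_fit_engine(P, factors, model, s_sign, start_par = start_par,
                       start_grid = start_grid)
  fit$response <- response
  fit$call <- match.call()
  fit
}

ll_eval <- function(par, factors, model) {
  lgl <- function(x, a, b) 1 / (1 + (x / a)^(-b))
  if (model == "full") {
    par["s"] * lgl(factors$A, par["a1"], par["b1"]) *
      lgl(factors$W, par["a2"], par["b2"]) *
      lgl(factors$R, par["a3"], par["b3"])
  } else {
    par["s"] * lgl(factors$C, par["a1"], par["b1"]) *
      lgl(factors$R, par["a2"], par["b2"])
  }
}

ll_par_names <- function(model) {
  if (model == "full") c("s", "a1", "b1", "a2", "b2", "a3", "b3")
  else c("s", "a1", "b1", "a2", "b2")
}

ll_fit_engine <- function(P, factors, model, s_sign,
                          start_par = NULL, start_grid = "quartiles") {
  key <- do.call(interaction, c(factors, list(drop = TRUE)))
  cell_n <- as.numeric(tapply(P, key, length))
  cell_m <- as.numeric(tapply(P, key, mean))
  ssw <- sum(P^2) - sum(cell_n * cell_m^2)
  ufac <- lapply(factors, function(x) as.numeric(tapply(x, key, `[`, 1)))
  nm <- ll_par_names(model)
  anames <- grep("^a", nm, value = TRUE)
  bnames <- grep("^b", nm, value = TRUE)
  fnames <- names(factors)

  obj <- function(p) {
    names(p) <- nm
    pred <- ll_eval(p, ufac, model)
    ssw + sum(cell_n * (cell_m - pred)^2)
  }
  sstot <- sum((P - mean(P))^2)

  if (all(abs(P) < 1e-12)) {
    warning("all responses are zero; returning a null (s = 0) fit")
    par <- setNames(numeric(length(nm)), nm)
    par[anames] <- vapply(ufac, median, numeric(1))
    par[bnames] <- 1
    fit <- list(par = par, value = 0, sstot = 0, ve = 0)
    return(ll_finish(fit, P, factors, ufac, cell_n, cell_m, model, s_sign, 0L))
  }

  lower <- setNames(numeric(length(nm)), nm)
  upper <- setNames(numeric(length(nm)), nm)
  lower["s"] <- if (s_sign == "positive") 0 else -Inf
  upper["s"] <- Inf
  for (i in seq_along(anames)) {
    rng <- range(ufac[[fnames[i]]])
    lower[anames[i]] <- rng[1] / 10
    upper[anames[i]] <- rng[2] * 10
  }
  lower[bnames] <- 0.1
  upper[bnames] <- 20

  starts <- list()
  if (!is.null(start_par)) starts <- list(pmin(pmax(start_par, lower), upper))
  if (start_grid != "none") {
    s0 <- cell_m[which.max(abs(cell_m))]
    if (s_sign == "positive") s0 <- max(s0, 1e-6)
    probs <- if (start_grid == "quartiles") c(0.25, 0.5, 0.75) else 0.5
    aq <- lapply(ufac, quantile, probs = probs, names = FALSE)
    agrid <- expand.grid(lapply(aq, unique), KEEP.OUT.ATTRS = FALSE)
    bgrid <- expand.grid(rep(list(c(1, 2)), length(bnames)),
                         KEEP.OUT.ATTRS = FALSE)
    for (ia in seq_len(nrow(agrid))) {
      for (ib in seq_len(nrow(bgrid))) {
        p <- setNames(numeric(length(nm)), nm)
        p["s"] <- s0
        p[anames] <- as.numeric(agrid[ia, ])
        p[bnames] <- as.numeric(bgrid[ib, ])
        starts[[length(starts) + 1L]] <- p
      }
    }
  }
  if (!length(starts)) stop("no optimization starts supplied")

  best <- NULL
  n_ok <- 0L
  for (p0 in starts) {
    res <- tryCatch(
      optim(p0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) next
    n_ok <- n_ok + 1L
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    stop("log-logistic fit did not converge from any of ", length(starts),
         " starts")
  }
  par <- setNames(best$par, nm)
  fit <- list(par = par, value = best$value, sstot = sstot,
              ve = 100 * (1 - best$value / sstot))
  ll_finish(fit, P, factors, ufac, cell_n, cell_m, model, s_sign, n_ok)
}

ll_finish <- function(fit, P, factors, ufac, cell_n, cell_m, model,
                      s_sign, n_ok) {
  cells <- as.data.frame(ufac)
  cells$n <- cell_n
  cells$mean <- cell_m
  cells$fitted <- as.numeric(ll_eval(fit$par, ufac, model))
  structure(c(fit, list(model = model, s_sign = s_sign, n = length(P),
                        cells = cells, n_starts_ok = n_ok,
                        data = list(factors = factors, response_values = P))),
            class = "loglogistic_fit")
}

#' @export
coef.loglogistic_fit <- function(object, ...) object$par

#' @export
fitted.loglogistic_fit <- function(object, ...) {
  as.numeric(ll_eval(object$par, object$data$factors, object$model))
}

#' @export
residuals.loglogistic_fit <- function(object, ...) {
  object$data$response_values - fitted(object)
}

#' Predict from a fitted log-logistic surface
#'
#' @param object a [loglogistic_fit()].
#' @param newdata data frame with `amplitude_ma`, `width_ms`, `rate_hz`
#'   (full model) or `charge_upc` (or amplitude and width), `rate_hz`
#'   (reduced model).  Defaults to the training trials.
#' @param ... unused.
#' @export
predict.loglogistic_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  nd <- as.data.frame(newdata)
  factors <- if (object$model == "full") {
    list(A = nd$amplitude_ma, W = nd$width_ms, R = nd$rate_hz)
  } else {
    C <- nd$charge_upc
    if (is.null(C)) C <- nd$amplitude_ma * nd$width_ms
    list(C = C, R = nd$rate_hz)
  }
  if (any(vapply(factors, is.null, logical(1)))) {
    stop("newdata is missing required stimulation-parameter columns")
  }
  as.numeric(ll_eval(object$par, factors, object$model))
}

#' @export
print.loglogistic_fit <- function(x, ...) {
  cat(sprintf("Log-logistic dose-response surface (%s model, %d trials)\n",
              x$model, x$n))
  cat("  ", paste(sprintf("%s = %.4g", names(x$par), x$par),
                  collapse = ", "), "\n", sep = "")
  cat(sprintf("  variance explained: %.2f%%\n", x$ve))
  if (x$model == "reduced") {
    cat(sprintf("  half-maximal charge: %.4g uC\n", x$par["a1"]))
  }
  invisible(x)
}

#' @export
summary.loglogistic_fit <- function(object, ...) {
  out <- list(par = object$par, ve = object$ve, n = object$n,
              model = object$model, cells = object$cells,
              boot_sd = object$boot_sd)
  class(out) <- "summary.loglogistic_fit"
  out
}

#' @export
print.summary.loglogistic_fit <- function(x, ...) {
  cat(sprintf("Log-logistic surface summary (%s model)\n", x$model))
  tab <- data.frame(estimate = x$par)
  if (!is.null(x$boot_sd)) tab$boot_sd <- x$boot_sd[names(x$par)]
  print(tab)
  cat(sprintf("n = %d trials, variance explained = %.2f%%\n", x$n, x$ve))
  invisible(x)
}

#' @export
plot.loglogistic_fit <- function(x, ...) {
  cells <- x$cells
  charge <- if (x$model == "reduced") cells$C else cells$A * cells$W
  rates <- sort(unique(cells$R))
  cols <- grDevices::hcl.colors(max(length(rates), 2), "Dark 3")
  plot(range(charge), range(c(cells$mean, cells$fitted)), type = "n",
       log = "x", xlab = "charge/pulse (uC)", ylab = "evoked response",
       main = sprintf("Dose-response (%s model, VE %.1f%%)", x$model, x$ve))
  for (i in seq_along(rates)) {
    sel <- cells$R == rates[i]
    ord <- order(charge[sel])
    points(charge[sel], cells$mean[sel], col = cols[i], pch = 19)
    lines(charge[sel][ord], cells$fitted[sel][ord], col = cols[i])
  }
  legend("topleft", legend = sprintf("%g Hz", rates), col = cols[seq_along(rates)],
         pch = 19, bty = "n")
  invisible(x)
}

#' @export
simulate.loglogistic_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- local_rng(seed)
    on.exit(restore_rng(old), add = TRUE)
  }
  mu <- fitted(object)
  sigma <- sqrt(max(object$value, 0) / max(object$n - length(object$par), 1))
  out <- replicate(nsim, mu + rnorm(length(mu), 0, sigma), simplify = FALSE)
  as.data.frame(setNames(out, paste0("sim_", seq_len(nsim))))
}

#' Compare variance explained by the full and reduced surfaces
#'
#' Fits both models to the same trials and reports the trialwise variance
#' explained by each and their difference.  Near-zero difference supports
#' collapsing amplitude and width into charge/pulse.
#'
#' @inheritParams loglogistic_fit
#' @return list with both fits and the paired variance-explained report.
#' @export
compare_full_vs_reduced <- function(trials, response = "response_pupil",
                                    s_sign = "positive",
                                    exclude_artifacts = TRUE) {
  full <- loglogistic_fit(trials, response, "full", s_sign,
                          exclude_artifacts)
  reduced <- loglogistic_fit(trials, response, "reduced", s_sign,
                             exclude_artifacts)
  structure(list(full = full, reduced = reduced,
                 ve_full = full$ve, ve_reduced = reduced$ve,
                 difference = full$ve - reduced$ve),
            class = "ve_comparison")
}

#' @export
print.ve_comparison <- function(x, ...) {
  cat(sprintf("Variance explained: full %.2f%% vs reduced %.2f%% (difference %.2f%%)\n",
              x$ve_full, x$ve_reduced, x$difference))
  invisible(x)
}

#' Half-maximal charge with bootstrap uncertainty
#'
#' The half-maximal charge is the fitted midpoint a1 of the reduced
#' (charge x rate) surface.  Uncertainty is estimated by resampling trials
#' with replacement and refitting (warm-started at the full-sample
#' parameters).
#'
#' @param fit a reduced-model [loglogistic_fit()].
#' @param n_boot bootstrap replicates (default 5000).
#' @param seed integer seed.
#' @return a `half_max_charge` list: `estimate` (uC), `sd` (bootstrap SD)
#'   and `draws`.
#' @export
half_max_charge <- function(fit, n_boot = 5000, seed = 1) {
  if (!inherits(fit, "loglogistic_fit") || fit$model != "reduced") {
    stop("half_max_charge() needs a reduced-model loglogistic_fit")
  }
  old <- local_rng(seed)
  on.exit(restore_rng(old), add = TRUE)
  P <- fit$data$response_values
  factors <- fit$data$factors
  n <- length(P)
  draws <- rep(NA_real_, n_boot)
  fail <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    res <- tryCatch(
      ll_fit_engine(P[idx], lapply(factors, `[`, idx), "reduced",
                    fit$s_sign, start_par = fit$par, start_grid = "none"),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(res)) fail <- fail + 1L else draws[b] <- res$par["a1"]
  }
  if (fail > 0.2 * n_boot) {
    stop("more than 20% of bootstrap refits failed (", fail, "/", n_boot, ")")
  }
  draws <- draws[is.finite(draws)]
  structure(list(estimate = unname(fit$par["a1"]), sd = sd(draws),
                 draws = draws, n_boot = n_boot, n_failed = fail),
            class = "half_max_charge")
}

#' @export
print.half_max_charge <- function(x, ...) {
  cat(sprintf("Half-maximal charge: %.3g +/- %.2g uC (bootstrapped SD, %d draws)\n",
              x$estimate, x$sd, length(x$draws)))
  invisible(x)
}

#' Two-sided bootstrap comparison of half-maximal charges
#'
#' Pairs the two bootstrap draw sets by index and computes
#' p = 2 min(Pr(diff <= 0), Pr(diff >= 0)), floored at 2 / n.
#'
#' @param x,y [half_max_charge()] results or numeric draw vectors.
#' @return list with the p-value and the paired difference summary.
#' @export
compare_half_max <- function(x, y) {
  dx <- if (inherits(x, "half_max_charge")) x$draws else as.numeric(x)
  dy <- if (inherits(y, "half_max_charge")) y$draws else as.numeric(y)
  if (!length(dx) || !length(dy)) stop("empty draw set")
  n <- min(length(dx), length(dy))
  d <- dx[seq_len(n)] - dy[seq_len(n)]
  p <- 2 * min(mean(d <= 0), mean(d >= 0))
  p <- max(p, 2 / n)
  p <- min(p, 1)
  list(p = p, mean_difference = mean(d), n = n)
}
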