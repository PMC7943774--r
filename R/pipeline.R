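#' Run the full analysis pipeline on session bundles
#'
#' Chains every stage on one or more sessions: read (or accept in-memory
#' sessions), condition all channels, build per-train trial tables with
#' artifact flags, pool sessions per experiment kind to fit and apply the
#' reversion-to-the-mean correction, fit the full and reduced dose-response
#' surfaces, assign charge bins and run the binwise FDR tests, and -- when
#' calcium responses are present -- build the cross-validated engagement
#' vector and run the bootstrap mediation analysis (on non-walking trials
#' by default).  Deterministic given `config$seed`.
#'
#' @param bundles character vector of bundle directories, or a list of
#'   [vns_session()] objects.
#' @param config a [vns_config()].
#' @param out_dir optional output directory for [write_results()].
#' @param mediation_include_walking include walking trials in the
#'   mediation analysis (default FALSE, mirroring the main analysis; the
#'   TRUE variant reproduces the supplementary check).
#' @param n_boot bootstrap replicates for mediation and half-max charge
#'   (defaults to `config$n_boot`).
#' @return a `vns_report` list: pooled trial table, reversion models,
#'   surface fits, variance-explained comparison, half-max charge, charge
#'   bins and tests, and (if applicable) the mediation results.
#' @export
run_pipeline <- function(bundles, config = vns_config(), out_dir = NULL,
                         mediation_include_walking = FALSE,
                         n_boot = config$n_boot) {
  sessions <- lapply(seq_along(bundles), function(i) {
    b <- bundles[[i]]
    s <- if (inherits(b, "vns_session")) b else read_session_bundle(b)
    if (identical(s$meta$session_id, "session")) {
      s$meta$session_id <- sprintf("session_%02d", i)
    }
    s
  })

  stage <- function(name, sid, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed for session '%s': %s",
                   name, sid, conditionMessage(e)), call. = FALSE)
    })
  }

  trials <- list()
  pseudo <- list()
  for (s in sessions) {
    sid <- s$meta$session_id
    cond <- stage("conditioning", sid, condition_session(s, config))
    tt <- stage("epoching", sid, build_trial_table(cond, s, config))
    wins <- window_for(config, s$meta$luminance_class)
    ps <- stage("pseudo-trials", sid,
                extract_pseudo_trials(cond$pupil, s$events, wins$response,
                                      wins$baseline, config$pseudo_pre_span_s))
    tt$session_id <- sid
    tt$experiment_kind <- s$meta$experiment_kind
    trials[[sid]] <- tt
    ps$experiment_kind <- s$meta$experiment_kind
    pseudo[[sid]] <- ps
  }
  all_trials <- do.call(rbind, trials)
  all_pseudo <- do.call(rbind, pseudo)
  class(all_trials) <- c("vns_trials", "data.frame")

  # reversion correction, pooled per experiment kind
  reversion <- list()
  for (kind in unique(all_trials$experiment_kind)) {
    sel <- all_pseudo$experiment_kind == kind
    model <- tryCatch(reversion_model(all_pseudo[sel, , drop = FALSE]),
                      error = function(e) NULL)
    reversion[[kind]] <- model
    rows <- all_trials$experiment_kind == kind
    if (!is.null(model)) {
      corrected <- apply_correction(all_trials[rows, , drop = FALSE], model)
      all_trials[rows, "response_pupil_corrected"] <-
        corrected$response_pupil_corrected
    } else {
      all_trials[rows, "response_pupil_corrected"] <-
        all_trials[rows, "response_pupil"]
    }
  }

  # dose-response fitting on corrected responses
  comparison <- stage("dose-response", "pooled",
                      compare_full_vs_reduced(all_trials,
                                              "response_pupil_corrected"))
  halfmax <- stage("half-max bootstrap", "pooled",
                   half_max_charge(comparison$reduced, n_boot = n_boot,
                                   seed = config$seed))
  bins <- assign_charge_bins(all_trials, config$n_charge_bins)
  tests <- stage("binwise tests", "pooled",
                 binwise_tests(all_trials, bins, "response_pupil_corrected",
                               "vs_zero", config$fdr_q))

  report <- list(trials = all_trials, reversion = reversion,
                 fit_full = comparison$full, fit_reduced = comparison$reduced,
                 ve_comparison = comparison, half_max = halfmax,
                 charge_bins = bins, bin_tests = tests,
                 config = config, seed = config$seed)

  # mediation branch: needs calcium responses
  has_ca <- any(is.finite(all_trials$response_calcium))
  if (has_ca) {
    med_trials <- all_trials[is.finite(all_trials$response_calcium), ,
                             drop = FALSE]
    if (!mediation_include_walking && !all(is.na(med_trials$walked))) {
      med_trials <- med_trials[!med_trials$walked %in% TRUE, , drop = FALSE]
    }
    med_rows <- match(rownames(med_trials), rownames(all_trials))
    engagement <- stage("engagement", "pooled",
                        predict_engagement_cv(med_trials,
                                              "response_pupil_corrected",
                                              folds = min(config$cv_folds,
                                                          nrow(med_trials)),
                                              seed = config$seed))
    P <- med_trials$response_pupil_corrected[engagement$index]
    C <- med_trials$response_calcium[engagement$index]
    report$engagement <- engagement
    report$mediation_rows <- med_rows[engagement$index]
    report$mediation <- stage("mediation", "pooled",
                              mediation_fit(P, C, engagement$engagement))
    report$mediation_boot <- stage("mediation bootstrap", "pooled",
                                   bootstrap_mediation(P, C,
                                                       engagement$engagement,
                                                       n_boot = n_boot,
                                                       seed = config$seed))
    report$partial_correlation <- partial_residual_correlation(
      P, C, engagement$engagement)
  }

  class(report) <- "vns_report"
  if (!is.null(out_dir)) {
    write_results(all_trials,
                  list(fit_full = report$fit_full,
                       fit_reduced = report$fit_reduced),
                  out_dir)
    write_config(config, file.path(out_dir, "config.json"))
  }
  report
}

#' @export
print.vns_report <- function(x, ...) {
  cat("=== VNS pipeline report ===\n")
  print(x$trials)
  cat("\n")
  print(x$ve_comparison)
  print(x$half_max)
  cat("\n")
  print(x$bin_tests)
  if (!is.null(x$mediation)) {
    cat("\n")
    print(x$mediation)
    print(x$mediation_boot)
  }
  invisible(x)
}
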