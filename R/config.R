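#' Analysis configuration
#'
#' All tunable parameters of the pipeline in one list.  Defaults are the
#' values used throughout the study design this package implements: 50 Hz
#' working sample rate, third-order Butterworth low-pass at 3 Hz (applied
#' forward and backward, so zero net phase), blink detection at |z| > 3 on
#' the derivative with a 150 ms interpolation pad, evoked windows per
#' luminance class (standard: response 2.5--7.5 s after onset vs 5 s
#' baseline; imaging: 10--30 s vs 20 s baseline, reflecting the slower
#' dilation at low luminance), a 0.05 cm/s walking threshold, five
#' log-spaced charge bins, 20 cross-validation folds and 5000 bootstrap
#' replicates.
#'
#' @param ... named overrides of any default listed below.
#' @return a classed list of configuration values.
#' @examples
#' cfg <- vns_config(blink_z_threshold = 4)
#' cfg$blink_z_threshold
#' @export
vns_config <- function(...) {
  cfg <- list(
    sample_rate_hz = 50,
    lowpass_order = 3,
    lowpass_cutoff_hz = 3,
    blink_z_threshold = 3,
    interp_pad_s = 0.15,
    windows = list(
      standard = list(baseline = c(-5, 0), response = c(2.5, 7.5)),
      imaging  = list(baseline = c(-20, 0), response = c(10, 30))
    ),
    epoch_window = c(-20, 60),
    walk_window = c(0, 10),
    walk_threshold_cms = 0.05,
    artifact_max_gap_frac = 0.25,
    motion_limit_um = 2,
    pseudo_pre_span_s = 30,
    n_charge_bins = 5,
    cv_folds = 20,
    n_boot = 5000,
    fdr_q = 0.05,
    min_leak_width_ms = 0.4,
    seed = 1
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  w <- cfg$windows
  for (cl in names(w)) {
    for (win in w[[cl]]) {
      if (length(win) != 2L || win[1] >= win[2]) {
        stop("windows must be (start, end) with start < end", call. = FALSE)
      }
    }
  }
  structure(cfg, class = "vns_config")
}

#' @export
print.vns_config <- function(x, ...) {
  cat("VNS analysis configuration\n")
  for (nm in names(x)) {
    val <- x[[nm]]
    if (is.list(val)) {
      cat(sprintf("  %s:\n", nm))
      for (cl in names(val)) {
        parts <- vapply(names(val[[cl]]), function(k) {
          sprintf("%s [%g, %g)", k, val[[cl]][[k]][1], val[[cl]][[k]][2])
        }, character(1))
        cat(sprintf("    %s: %s\n", cl, paste(parts, collapse = ", ")))
      }
    } else {
      cat(sprintf("  %s: %s\n", nm, paste(format(val), collapse = ", ")))
    }
  }
  invisible(x)
}

#' Read a configuration document (JSON or YAML)
#'
#' Values present in the file override [vns_config()] defaults; everything
#' else keeps its default.
#'
#' @param path file ending in `.json`, `.yaml` or `.yml`.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("the 'yaml' package is required to read YAML configuration")
      }
      yaml::read_yaml(path)
    },
    stop("unsupported configuration format: ", ext)
  )
  do.call(vns_config, vals)
}

#' Write a configuration document as JSON
#' @param config a [vns_config()] object.
#' @param path output path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

window_for <- function(config, luminance_class = c("standard", "imaging")) {
  luminance_class <- match.arg(luminance_class)
  config$windows[[luminance_class]]
}
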