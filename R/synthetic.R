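#' Ground-truth parameters for synthetic sessions
#'
#' Returns the generative parameters used by [generate_session()].  The
#' defaults encode the study conditions the analysis targets:
#' \itemize{
#'   \item dose-response surfaces per modality are separable log-logistic
#'     functions of charge/pulse and train rate, with the pupil half-max
#'     charge at 0.15 uC, the calcium half-max at 0.062 uC and the walking
#'     half-max at 0.17 uC;
#'   \item the spontaneous pupil baseline is an Ornstein-Uhlenbeck (OU)
#'     process (time constant 40 s, stationary SD 6 in percent-of-max
#'     units) -- mean-reverting by construction, which is exactly the
#'     confound the pseudo-trial correction removes;
#'   \item evoked transients are difference-of-exponential kernels, slower
#'     under the low-luminance imaging class;
#'   \item trial-to-trial response noise is multiplicative log-normal
#'     (sdlog 0.4) plus the additive scalar noise the OU baseline induces
#'     (SD about 3.4 in the same units), which puts the variance explained
#'     by the surface near 25 percent;
#'   \item in imaging sessions pupil and calcium amplitudes follow the
#'     linear path model C = a N + e, P = c' N + b C + e with a = 1,
#'     b = 0.5, c' = 0.5, i.e. half of the total engagement effect on the
#'     pupil is routed through the calcium mediator;
#'   \item measured stimulation current shows a leak fraction and a
#'     sigmoidal pulse-width filter attenuating the narrowest pulses.
#' }
#'
#' @param ... named overrides of any top-level field.
#' @return a classed list of generator parameters.
#' @export
vns_truth <- function(...) {
  tr <- list(
    surface = list(
      pupil   = list(kind = "reduced", s = 10, a1 = 0.15, b1 = 2, a2 = 9, b2 = 2),
      calcium = list(kind = "reduced", s = 10, a1 = 0.062, b1 = 2, a2 = 9, b2 = 2),
      walk    = list(kind = "reduced", s = 0.45, a1 = 0.17, b1 = 2, a2 = 9, b2 = 2)
    ),
    baseline = list(tau_s = 40, sd = 6, mean = 50),
    kernel = list(
      standard = list(rise_s = 1.5, decay_s = 6, latency_s = 0.5),
      imaging  = list(rise_s = 4, decay_s = 15, latency_s = 0.5),
      calcium  = list(rise_s = 0.8, decay_s = 4, latency_s = 0.3)
    ),
    trial_noise = list(sdlog = 0.4, additive_sd = 3.4),
    coupling = list(a = 1, b = 0.5, c_direct = 0.5,
                    sd_calcium = 2, sd_pupil = 2),
    walk = list(speed_scale_cms = 0.35, decay_s = 3,
                spont_rate_per_min = 0.2, spont_dur_s = 5),
    blink = list(rate_per_min = 2, dur_mean_s = 0.3, dur_sdlog = 0.5),
    eyelid = list(gain = 0.6, sd = 3),
    eye = list(tau_s = 1, sd = 1, grounded_amp = 0.5),
    calcium_baseline = list(mean = 50, sd = 2, tau_s = 20,
                            bleach_slope_per_s = -0.003),
    channel_noise = list(pupil = 0.3, eyelid = 0.3, eye = 0.3,
                         velocity = 0.01, fluorescence = 1.0),
    electronics = list(leak = 0.1, filter_a = 20, filter_b = 0.12,
                       noise_sd_ma = 0.001),
    baseline_mod = NULL
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(tr))
  if (length(unknown)) {
    stop("unknown truth field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(dots)) {
    tr[[nm]] <- if (is.list(tr[[nm]]) && is.list(dots[[nm]])) {
      utils::modifyList(tr[[nm]], dots[[nm]])
    } else dots[[nm]]
  }
  structure(tr, class = "vns_truth")
}

#' Evaluate a ground-truth dose-response surface
#'
#' Separable log-logistic surface, either over (amplitude, width, rate)
#' (`kind = "full"`, parameters s, a1..a3, b1..b3) or over (charge/pulse,
#' rate) (`kind = "reduced"`, parameters s, a1, b1, a2, b2 with
#' charge = amplitude x width).
#'
#' @param surface one element of `vns_truth()$surface`.
#' @param amplitude_ma,width_ms,rate_hz stimulation parameters (vectors).
#' @return expected response per trial.
#' @export
eval_surface <- function(surface, amplitude_ma, width_ms, rate_hz) {
  lgl <- function(x, a, b) 1 / (1 + (x / a)^(-b))
  if (identical(surface$kind, "full")) {
    surface$s * lgl(amplitude_ma, surface$a1, surface$b1) *
      lgl(width_ms, surface$a2, surface$b2) *
      lgl(rate_hz, surface$a3, surface$b3)
  } else {
    surface$s * lgl(amplitude_ma * width_ms, surface$a1, surface$b1) *
      lgl(rate_hz, surface$a2, surface$b2)
  }
}

#' Exact discretization of an Ornstein-Uhlenbeck process
#'
#' Mean-reverting Gaussian process with autocorrelation
#' exp(-dt / tau); sampled exactly (no Euler error), starting from a
#' stationary draw.
#'
#' @param n number of samples.
#' @param dt sample spacing, seconds.
#' @param tau_s mean-reversion time constant, seconds.
#' @param sd stationary standard deviation.
#' @param mean stationary mean level.
#' @return numeric vector of length `n`.
#' @export
ou_process <- function(n, dt, tau_s, sd = 1, mean = 0) {
  if (n == 0L) return(numeric(0))
  phi <- exp(-dt / tau_s)
  e <- rnorm(n, 0, sd * sqrt(1 - phi^2))
  e[1] <- rnorm(1, 0, sd)
  mean + as.numeric(stats::filter(e, phi, method = "recursive"))
}

# difference-of-exponentials kernel, unit peak, zero before t = 0
evoked_kernel <- function(t, rise_s, decay_s) {
  k <- ifelse(t < 0, 0, exp(-t / decay_s) - exp(-t / rise_s))
  tpk <- log(decay_s / rise_s) / (1 / rise_s - 1 / decay_s)
  k / (exp(-tpk / decay_s) - exp(-tpk / rise_s))
}

# add amp[i] * kernel(t - onset[i] - latency) onto a trace (in place-ish)
add_evoked <- function(values, time, onsets, amps, kern) {
  span <- kern$latency_s + 8 * kern$decay_s
  dt <- time[2] - time[1]
  for (i in seq_along(onsets)) {
    if (amps[i] == 0) next
    i0 <- max(1L, ceiling((onsets[i] - time[1]) / dt) + 1L)
    i1 <- min(length(values), floor((onsets[i] + span - time[1]) / dt) + 1L)
    if (i0 > i1) next
    idx <- i0:i1
    values[idx] <- values[idx] +
      amps[i] * evoked_kernel(time[idx] - onsets[i] - kern$latency_s,
                              kern$rise_s, kern$decay_s)
  }
  values
}

#' Sample trial-level evoked response amplitudes
#'
#' Draws per-trial evoked amplitudes from the generator's response model:
#' the surface value at each trial's (amplitude, width, rate) times
#' multiplicative log-normal trial noise (mean 1), plus additive Gaussian
#' scalar noise.  The same model underlies the evoked amplitudes placed in
#' full synthetic sessions, where the additive component arises from the OU
#' baseline instead of being added explicitly.
#'
#' @param events a [stim_trains()] table.
#' @param surface a surface from [vns_truth()].
#' @param sdlog log-normal trial-noise SD (log scale).
#' @param additive_sd additive scalar noise SD.
#' @param seed optional integer seed.
#' @return numeric vector of evoked amplitudes, one per event.
#' @export
sample_evoked_amplitudes <- function(events, surface, sdlog = 0.4,
                                     additive_sd = 3.4, seed = NULL) {
  if (!is.null(seed)) {
    old <- local_rng(seed)
    on.exit(restore_rng(old), add = TRUE)
  }
  mu <- eval_surface(surface, events$amplitude_ma, events$width_ms,
                     events$rate_hz)
  n <- nrow(events)
  mu * rlnorm(n, -sdlog^2 / 2, sdlog) + rnorm(n, 0, additive_sd)
}

poisson_events <- function(rate_per_min, duration_s) {
  n <- rpois(1, rate_per_min * duration_s / 60)
  sort(runif(n, 0, duration_s))
}

#' Generate one synthetic session
#'
#' Simulates the raw multichannel recording of one VNS session with the
#' statistical structure the analysis assumes: an OU pupil baseline, evoked
#' transients whose amplitude follows the ground-truth log-logistic surface
#' with multiplicative trial noise, an eyelid channel sharing the evoked
#' drive, probabilistic walking bouts during and shortly after trains,
#' blinks inserted as missing samples, eye-position channels (with a
#' train-rate sinusoid when `grounded`), and -- for `axon_imaging`
#' sessions -- a fluorescence channel whose evoked amplitudes follow the
#' linear mediation chain C = aN + e, P = c'N + bC + e plus a linear
#' bleaching rundown.
#'
#' Ground-truth per-trial annotations (engagement N, evoked amplitudes,
#' walk draws) are attached as `attr(session, "truth")` and written to the
#' bundle sidecar `truth.json` by [write_session_bundle()].
#'
#' @param protocol a [stim_trains()] table.
#' @param truth a [vns_truth()].
#' @param seed integer seed; one seeded generator drives all channels.
#' @param duration_s session length; default: 90 s past the last train.
#' @param meta session metadata (see [vns_session()]); `experiment_kind =
#'   "axon_imaging"` adds the fluorescence channel and switches evoked
#'   kernels and native rates to the imaging class.
#' @param native_rates optional named overrides of the per-channel raw
#'   sampling rates (defaults: eye channels 143 Hz standard / 15 Hz
#'   imaging, velocity 50 Hz, fluorescence 15 Hz).
#' @return a [vns_session()].
#' @export
generate_session <- function(protocol, truth = vns_truth(), seed = 1,
                             duration_s = NULL, meta = list(),
                             native_rates = list()) {
  meta <- validate_meta(meta)
  if (is.null(duration_s)) {
    duration_s <- if (nrow(protocol)) max(protocol$onset_s) + 90 else 600
  }
  if (nrow(protocol) && max(protocol$onset_s) + 40 > duration_s) {
    stop("protocol overruns the session duration")
  }
  old <- local_rng(seed)
  on.exit(restore_rng(old), add = TRUE)

  imaging <- identical(meta$experiment_kind, "axon_imaging") ||
    identical(meta$luminance_class, "imaging")
  if (imaging) meta$luminance_class <- "imaging"
  rates <- utils::modifyList(list(
    pupil = if (imaging) 15 else 143,
    eyelid = if (imaging) 15 else 143,
    eye = if (imaging) 15 else 143,
    velocity = 50,
    fluorescence = 15
  ), native_rates)

  n_ev <- nrow(protocol)
  onsets <- protocol$onset_s
  kern <- truth$kernel[[if (imaging) "imaging" else "standard"]]

  # --- per-trial ground-truth amplitudes ------------------------------
  N <- eval_surface(truth$surface$pupil, protocol$amplitude_ma,
                    protocol$width_ms, protocol$rate_hz)
  lognoise <- rlnorm(n_ev, -truth$trial_noise$sdlog^2 / 2,
                     truth$trial_noise$sdlog)
  if (imaging) {
    cp <- truth$coupling
    amp_calcium <- cp$a * N + rnorm(n_ev, 0, cp$sd_calcium)
    amp_pupil <- (cp$c_direct * N + cp$b * amp_calcium) * lognoise
  } else {
    amp_calcium <- rep(NA_real_, n_ev)
    amp_pupil <- N * lognoise
  }

  # --- pupil ----------------------------------------------------------
  tp <- seq(0, duration_s, by = 1 / rates$pupil)
  base <- ou_process(length(tp), 1 / rates$pupil, truth$baseline$tau_s,
                     truth$baseline$sd, truth$baseline$mean)
  amp_p <- amp_pupil
  if (!is.null(truth$baseline_mod) && n_ev) {
    # optional inverted-U modulation of evoked amplitude by baseline state
    bidx <- pmax(1L, floor(onsets * rates$pupil) + 1L)
    dev <- base[bidx] - truth$baseline$mean
    g <- 1 + truth$baseline_mod$lin * dev + truth$baseline_mod$quad * dev^2
    amp_p <- amp_p * pmax(0, g)
  }
  pupil <- add_evoked(base, tp, onsets, amp_p, kern)
  pupil <- pupil + rnorm(length(tp), 0, truth$channel_noise$pupil)

  # --- eyelid ---------------------------------------------------------
  lid_base <- ou_process(length(tp), 1 / rates$pupil, truth$baseline$tau_s,
                         truth$eyelid$sd, truth$baseline$mean)
  eyelid <- add_evoked(lid_base, tp, onsets, truth$eyelid$gain * amp_p, kern)
  eyelid <- eyelid + rnorm(length(tp), 0, truth$channel_noise$eyelid)

  # --- blinks: shared missing spans on pupil + eyelid -----------------
  blink_on <- poisson_events(truth$blink$rate_per_min, duration_s)
  blink_dur <- rlnorm(length(blink_on),
                      log(truth$blink$dur_mean_s) - truth$blink$dur_sdlog^2 / 2,
                      truth$blink$dur_sdlog)
  for (i in seq_along(blink_on)) {
    idx <- which(tp >= blink_on[i] & tp < blink_on[i] + blink_dur[i])
    pupil[idx] <- NA
    eyelid[idx] <- NA
  }

  # --- eye position ---------------------------------------------------
  eye_x <- ou_process(length(tp), 1 / rates$eye, truth$eye$tau_s,
                      truth$eye$sd, 0) +
    rnorm(length(tp), 0, truth$channel_noise$eye)
  eye_y <- ou_process(length(tp), 1 / rates$eye, truth$eye$tau_s,
                      truth$eye$sd, 0) +
    rnorm(length(tp), 0, truth$channel_noise$eye)
  if (meta$grounded && n_ev) {
    for (i in seq_len(n_ev)) {
      idx <- which(tp >= onsets[i] & tp < onsets[i] + protocol$duration_s[i])
      osc <- truth$eye$grounded_amp *
        sin(2 * pi * protocol$rate_hz[i] * tp[idx])
      eye_x[idx] <- eye_x[idx] + osc
      eye_y[idx] <- eye_y[idx] + osc
    }
  }

  # --- walking --------------------------------------------------------
  tv <- seq(0, duration_s, by = 1 / rates$velocity)
  vel <- rnorm(length(tv), 0, truth$channel_noise$velocity)
  p_walk <- pmin(1, pmax(0, eval_surface(truth$surface$walk,
                                         protocol$amplitude_ma,
                                         protocol$width_ms,
                                         protocol$rate_hz)))
  walked <- if (n_ev) rbinom(n_ev, 1, p_walk) == 1 else logical(0)
  add_bout <- function(vel, start, dur, speed) {
    during <- which(tv >= start & tv < start + dur)
    after <- which(tv >= start + dur &
                     tv < start + dur + 4 * truth$walk$decay_s)
    vel[during] <- vel[during] + speed
    vel[after] <- vel[after] +
      speed * exp(-(tv[after] - start - dur) / truth$walk$decay_s)
    vel
  }
  for (i in which(walked)) {
    vel <- add_bout(vel, onsets[i], protocol$duration_s[i],
                    truth$walk$speed_scale_cms)
  }
  for (s0 in poisson_events(truth$walk$spont_rate_per_min, duration_s)) {
    vel <- add_bout(vel, s0, truth$walk$spont_dur_s,
                    truth$walk$speed_scale_cms)
  }

  channels <- list(
    pupil = list(time = tp, values = pupil),
    eyelid = list(time = tp, values = eyelid),
    eye_x = list(time = tp, values = eye_x),
    eye_y = list(time = tp, values = eye_y),
    velocity = list(time = tv, values = vel)
  )

  # --- calcium fluorescence ------------------------------------------
  if (imaging && identical(meta$experiment_kind, "axon_imaging")) {
    tf <- seq(0, duration_s, by = 1 / rates$fluorescence)
    cb <- truth$calcium_baseline
    fl <- ou_process(length(tf), 1 / rates$fluorescence, cb$tau_s, cb$sd,
                     cb$mean) + cb$bleach_slope_per_s * tf
    fl <- add_evoked(fl, tf, onsets, amp_calcium, truth$kernel$calcium)
    fl <- fl + rnorm(length(tf), 0, truth$channel_noise$fluorescence)
    channels$fluorescence <- list(time = tf, values = fl)
  }

  sess <- vns_session(channels, protocol, meta)
  attr(sess, "truth") <- list(
    seed = seed,
    surface = truth$surface,
    coupling = if (imaging) truth$coupling else NULL,
    trials = data.frame(
      trial = seq_len(n_ev),
      engagement = N,
      amp_pupil = amp_pupil,
      amp_calcium = amp_calcium,
      p_walk = p_walk,
      walked = walked
    )
  )
  sess
}

#' Generate a synthetic pixel image stack
#'
#' Produces a small fluorescence image time stack in which a contiguous
#' "axon plexus" mask carries the evoked calcium dynamics while background
#' pixels are pure noise, plus the ground-truth mask for validating the
#' cluster-based pixel test.
#'
#' @param protocol a [stim_trains()] table.
#' @param truth a [vns_truth()].
#' @param shape image dimensions (rows, cols), at most 128 x 128.
#' @param seed integer seed.
#' @param frame_rate stack frame rate, Hz.
#' @param mask optional logical matrix of effect pixels; default is a
#'   central disc of about 900 pixels (scaled to the image size).
#' @param amp_scale multiplier on the evoked amplitudes (0 gives a null
#'   stack).
#' @param noise_sd per-pixel, per-frame Gaussian noise SD.
#' @return list with `stack` (frames x pixels matrix), `dim`, `times`,
#'   `mask` (logical matrix) and the protocol.
#' @export
generate_image_stack <- function(protocol, truth = vns_truth(),
                                 shape = c(64, 64), seed = 1,
                                 frame_rate = 5, mask = NULL,
                                 amp_scale = 1, noise_sd = 1) {
  stopifnot(all(shape <= 128))
  old <- local_rng(seed)
  on.exit(restore_rng(old), add = TRUE)
  duration_s <- if (nrow(protocol)) max(protocol$onset_s) + 40 else 120
  times <- seq(0, duration_s, by = 1 / frame_rate)
  npix <- prod(shape)
  if (is.null(mask)) {
    r <- sqrt(900 / pi) * min(shape) / 64
    cx <- (shape[1] + 1) / 2
    cy <- (shape[2] + 1) / 2
    mask <- outer(seq_len(shape[1]), seq_len(shape[2]),
                  function(i, j) (i - cx)^2 + (j - cy)^2 <= r^2)
  }
  stopifnot(identical(dim(mask), as.integer(shape)))
  amps <- amp_scale * eval_surface(truth$surface$calcium,
                                   protocol$amplitude_ma,
                                   protocol$width_ms, protocol$rate_hz)
  drive <- add_evoked(numeric(length(times)), times, protocol$onset_s,
                      amps, truth$kernel$calcium)
  stack <- matrix(rnorm(length(times) * npix, 0, noise_sd),
                  nrow = length(times))
  midx <- which(as.vector(mask))
  # per-pixel gain jitter keeps the plexus from being perfectly uniform
  gains <- rlnorm(length(midx), -0.02, 0.2)
  stack[, midx] <- stack[, midx] + outer(drive, gains)
  list(stack = stack, dim = as.integer(shape), times = times, mask = mask,
       protocol = protocol)
}

#' Per-trial, per-pixel evoked responses from an image stack
#'
#' For each train and pixel: mean over the response window minus mean over
#' the baseline window (windows in seconds relative to train onset,
#' half-open).
#'
#' @param stack_obj result of [generate_image_stack()] (or a compatible
#'   list).
#' @param response_window,baseline_window windows relative to onset.
#' @return trials x pixels matrix.
#' @export
pixel_trial_responses <- function(stack_obj, response_window = c(2.5, 7.5),
                                  baseline_window = c(-5, 0)) {
  times <- stack_obj$times
  onsets <- stack_obj$protocol$onset_s
  out <- matrix(NA_real_, length(onsets), ncol(stack_obj$stack))
  for (i in seq_along(onsets)) {
    rsel <- times >= onsets[i] + response_window[1] &
      times < onsets[i] + response_window[2]
    bsel <- times >= onsets[i] + baseline_window[1] &
      times < onsets[i] + baseline_window[2]
    out[i, ] <- colMeans(stack_obj$stack[rsel, , drop = FALSE]) -
      colMeans(stack_obj$stack[bsel, , drop = FALSE])
  }
  out
}

#' Simulate measured stimulation current
#'
#' Per train, the measured return-current amplitude equals the intended
#' amplitude times (1 - leak fraction) times a sigmoidal pulse-width filter
#' `1 / (1 + exp(-a (W - b)))` that attenuates the narrowest pulses, plus
#' measurement noise.
#'
#' @param trains a [stim_trains()] table.
#' @param truth a [vns_truth()]; uses `truth$electronics`.
#' @param seed optional integer seed.
#' @return data frame with intended and measured amplitudes per train.
#' @export
generate_measured_current <- function(trains, truth = vns_truth(),
                                      seed = NULL) {
  if (!is.null(seed)) {
    old <- local_rng(seed)
    on.exit(restore_rng(old), add = TRUE)
  }
  el <- truth$electronics
  stopifnot(el$leak >= 0, el$leak < 1)
  filt <- 1 / (1 + exp(-el$filter_a * (trains$width_ms - el$filter_b)))
  measured <- trains$amplitude_ma * (1 - el$leak) * filt +
    rnorm(nrow(trains), 0, el$noise_sd_ma)
  data.frame(train = seq_len(nrow(trains)),
             width_ms = trains$width_ms,
             rate_hz = trains$rate_hz,
             intended_ma = trains$amplitude_ma,
             measured_ma = measured)
}
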