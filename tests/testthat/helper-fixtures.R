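# shared fixtures: noise-free truth variants and small protocols

# truth with every stochastic component silenced; deterministic sessions
quiet_truth <- function(...) {
  base <- list(
    baseline = list(sd = 0),
    trial_noise = list(sdlog = 0, additive_sd = 0),
    blink = list(rate_per_min = 0),
    walk = list(spont_rate_per_min = 0),
    surface = list(walk = list(s = 0)),
    channel_noise = list(pupil = 0, eyelid = 0, eye = 0, velocity = 0,
                         fluorescence = 0),
    eyelid = list(sd = 0),
    calcium_baseline = list(sd = 0),
    electronics = list(noise_sd_ma = 0)
  )
  do.call(vns_truth, utils::modifyList(base, list(...)))
}

# null truth: no evoked responses anywhere, spontaneous dynamics intact
null_truth <- function(...) {
  vns_truth(
    surface = list(pupil = list(s = 0), calcium = list(s = 0),
                   walk = list(s = 0)),
    blink = list(rate_per_min = 0),
    walk = list(spont_rate_per_min = 0),
    ...
  )
}

# short protocol for fast session-level tests
short_protocol <- function(n_seed = 1, amplitudes = c(0.1, 0.5, 0.9),
                           widths = c(0.1, 0.4), rates = c(5, 20),
                           iti = c(50, 60), first = 45) {
  generate_protocol(amplitudes, widths, rates, seed = n_seed,
                    iti_range = iti, first_onset_s = first)
}

# uniform-grid raw channel wrapper
uniform_channel <- function(values, rate = 50, t0 = 0) {
  list(time = t0 + (seq_along(values) - 1) / rate, values = values)
}

# mean of the standard evoked kernel over a window: the "windowing factor"
# linking generator amplitudes to measured evoked scalars.  Computed by
# direct numerical integration of the kernel definition, independent of
# the epoching code.
kernel_window_factor <- function(kern, window, baseline = NULL, dt = 1e-3) {
  tt <- seq(window[1], window[2] - dt, by = dt)
  shape <- function(t) {
    tau_r <- kern$rise_s; tau_d <- kern$decay_s
    tpk <- log(tau_d / tau_r) / (1 / tau_r - 1 / tau_d)
    peak <- exp(-tpk / tau_d) - exp(-tpk / tau_r)
    ifelse(t < kern$latency_s, 0,
           (exp(-(t - kern$latency_s) / tau_d) -
              exp(-(t - kern$latency_s) / tau_r)) / peak)
  }
  f <- mean(shape(tt))
  if (!is.null(baseline)) {
    tb <- seq(baseline[1], baseline[2] - dt, by = dt)
    f <- f - mean(shape(tb))
  }
  f
}
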