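# Shared fixture builders (all fixtures are generated in code).

# Fully deterministic, artifact-free generator configuration: no noise,
# no ocular mixing, no blinks, no single-trial variability. Under this
# configuration the generated EEG is exactly the sum of the component
# kernels.
noise_free_config <- function(n_runs = 1, seed = 1, ...) {
  modify_config(
    generator_config(n_runs = n_runs, seed = seed,
                     eeg_noise_sd_uV = 0, sensor_noise_sd_uV = 0,
                     ocular_gain = default_ocular_gain() * 0,
                     trial_amp_sd = 0, trial_lat_sd_s = 0,
                     pupil_trial_amp_sd = 0, pupil_trial_lat_sd_s = 0,
                     pupil_noise_sd_mm = 0, blink_rate_hz = 0,
                     rr_jitter_s = 0),
    ...)
}

# Small epoch set at the decoding rate with an optional class-dependent
# Gaussian bump (peak at `at` seconds); channels default to FCz only.
toy_epochs <- function(n_per = 25, channels = "FCz", effect = 0,
                       at = 0.35, noise = 1, seed = 1) {
  set.seed(seed)
  labs <- rep(condition_levels(), each = n_per)
  tax <- seq(-0.5, by = 1 / 32, length.out = 48)
  nch <- length(channels)
  dat <- array(stats::rnorm(length(labs) * nch * 48, sd = noise),
               c(length(labs), nch, 48))
  if (effect != 0) {
    bump <- exp(-(tax - at)^2 / (2 * 0.05^2))
    for (i in seq_along(labs)) {
      cl <- match(labs[i], condition_levels())
      if (cl < 4)
        for (ch in seq_len(nch))
          dat[i, ch, ] <- dat[i, ch, ] + effect * cl * bump
    }
  }
  epoch_set(dat, labs, tax, 32, channel_names = channels)
}

# Brute-force evaluation of the Bayesian belief measure from first
# principles (independent of bayes_fuse's implementation).
brute_force_belief <- function(predictions, confusions, priors,
                               smoothing = 0) {
  M <- nrow(confusions[[1]])
  O <- numeric(M)
  for (i in seq_len(M)) {
    o <- priors[i]
    for (k in seq_along(confusions)) {
      cnt <- confusions[[k]] + smoothing
      j <- predictions[k]
      o <- o * cnt[i, j] / sum(cnt[, j])
    }
    O[i] <- o
  }
  O
}
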