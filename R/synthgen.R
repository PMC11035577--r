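# Synthetic-data generator for the VR flight paradigm: event schedules,
# continuous EEG with error-related potentials and ocular artifacts,
# gaze/pupil streams with foreshortening distortion and blinks, and
# RR-interval series with respiratory sinus arrhythmia and post-error
# heart-rate deceleration.

#' Default error-related potential components
#'
#' Per-condition component tables (P1, ERN, Pe, N400) with peak latency,
#' peak amplitude at the component's topographic centre, Gaussian kernel
#' width (SD, seconds) and centre channel. Latencies and amplitudes encode
#' the reported grand-average waveform at FCz: P1 at 188 ms
#' (1.33/1.03/0.748 uV for target/passive/active), ERN at 234/250/266 ms
#' (-0.401/-0.274/-0.331 uV), Pe at 313/344/391 ms (4.16/1.30/1.08 uV)
#' and N400 at 469/484/500 ms. N400 amplitudes are not reported and
#' default to a moderate negativity. Correct trials carry no event-locked
#' components.
#'
#' @return named list (`target`, `passive`, `active`) of data.frames with
#'   columns `name`, `latency_s`, `amplitude_uV`, `width_s`, `center`.
#' @export
default_erp_components <- function() {
  mk <- function(lat, amp) data.frame(
    name = c("P1", "ERN", "Pe", "N400"),
    latency_s = lat, amplitude_uV = amp,
    width_s = c(0.018, 0.016, 0.028, 0.045),
    center = c("FCz", "FCz", "Cz", "Cz"),
    stringsAsFactors = FALSE)
  list(target  = mk(c(0.188, 0.234, 0.313, 0.469), c(1.33, -0.401, 4.16, -1.5)),
       passive = mk(c(0.188, 0.250, 0.344, 0.484), c(1.03, -0.274, 1.30, -1.2)),
       active  = mk(c(0.188, 0.266, 0.391, 0.500), c(0.748, -0.331, 1.08, -1.2)))
}

#' Default pupil dilation components
#'
#' Error-evoked pupil dilation kernels peaking at 0.625 s (target),
#' 0.656 s (passive) and 0.734 s (active) after error onset; amplitudes
#' and widths are generator defaults chosen to produce dilations of a few
#' hundredths of a millimetre, the magnitude typical of task-evoked
#' orienting responses.
#'
#' @return named list of `latency_s`, `amplitude_mm`, `width_s` per
#'   condition.
#' @export
default_pupil_components <- function() {
  list(target  = list(latency_s = 0.625, amplitude_mm = 0.080, width_s = 0.21),
       passive = list(latency_s = 0.656, amplitude_mm = 0.060, width_s = 0.21),
       active  = list(latency_s = 0.734, amplitude_mm = 0.050, width_s = 0.23))
}

#' Default ocular mixing gains
#'
#' Linear mixing of the three ocular sources (horizontal gaze angle,
#' vertical gaze angle, blink pulse) into the EEG channels: frontally
#' weighted for vertical/blink sources and laterally antisymmetric for the
#' horizontal source, emulating the corneo-retinal dipole projection.
#'
#' @param labels channel labels.
#' @return channels-by-3 matrix (columns `gaze_h`, `gaze_v`, `blink`),
#'   units uV/deg for gaze and uV per unit pulse for blinks.
#' @export
default_ocular_gain <- function(labels = eeg_montage()) {
  pos <- electrode_positions(labels)
  fpz <- sph_point(72, 90)
  arc_fpz <- acos(pmin(1, as.matrix(pos[, c("x", "y", "z")]) %*% fpz))
  w_front <- exp(-arc_fpz^2 / (2 * 0.55^2))
  g_h <- 1.2 * pos$x * pmax(pos$y, 0) * 2     # lateral-frontal antisymmetric
  g_v <- 1.5 * w_front
  g_b <- 120 * w_front
  out <- cbind(gaze_h = g_h, gaze_v = as.vector(g_v),
               blink = as.vector(g_b))
  rownames(out) <- labels
  out
}

#' Generator configuration
#'
#' Assembles all tunable parameters of the synthetic paradigm. Defaults
#' encode the study conditions: 512 Hz EEG on the 63-name montage, 120 Hz
#' gaze/pupil, nine flight-simulation runs, ERP and pupil components per
#' [default_erp_components()] and [default_pupil_components()], cubic
#' pupil-foreshortening coefficients per eye, and an RR series with
#' respiratory sinus arrhythmia plus a post-error lengthening kernel.
#'
#' @param fs_eeg,fs_gaze sampling rates (Hz).
#' @param n_runs flight-simulation runs per session.
#' @param eeg_noise_sd_uV per-channel SD of the 1/f background (uV).
#' @param one_over_f_exponent spectral exponent of the background.
#' @param n_noise_sources number of spatially mixed background sources.
#' @param sensor_noise_sd_uV white sensor noise SD (uV).
#' @param erp_components per-condition ERP component tables.
#' @param topo_sd_rad angular SD of the Gaussian scalp topographies.
#' @param ocular_gain channels-by-3 mixing matrix (see
#'   [default_ocular_gain()]).
#' @param trial_amp_sd,trial_lat_sd_s single-trial variability of the ERP
#'   components: log-normal amplitude scale SD (log units) and Gaussian
#'   latency jitter SD (s), both zero-mean so grand averages stay centred
#'   on the component defaults.
#' @param pupil_components per-condition dilation kernels.
#' @param pupil_trial_amp_sd,pupil_trial_lat_sd_s single-trial
#'   variability of the dilation response (log-amplitude SD, latency
#'   jitter SD in s).
#' @param pupil_baseline_mm resting pupil diameter (mm).
#' @param pupil_noise_sd_mm SD (mm) of spontaneous slow pupil
#'   fluctuations (arousal-related activity unrelated to the events;
#'   in real recordings these are comparable to or larger than the
#'   evoked dilations).
#' @param pfe_coeffs list(left, right) of cubic coefficients
#'   (mm, mm/deg, mm/deg^2, mm/deg^3) mapping horizontal gaze angle to the
#'   apparent pupil-size bias.
#' @param blink_rate_hz blink rate (Hz).
#' @param blink_dur_s range (min, max) of blink durations (s).
#' @param rr_base_s baseline RR interval (s).
#' @param rsa_amp_s respiratory sinus arrhythmia amplitude (s).
#' @param rsa_freq_hz respiration frequency (Hz).
#' @param rr_jitter_s white RR jitter SD (s).
#' @param hr_decel list(`magnitude_bpm`, `latency_s`, `width_s`) of the
#'   post-error heart-rate deceleration kernel (per error condition scale
#'   factors in `condition_scale`).
#' @param seed integer; fully determines generator output.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(fs_eeg = 512, fs_gaze = 120, n_runs = 9,
                             eeg_noise_sd_uV = 10,
                             one_over_f_exponent = 1,
                             n_noise_sources = 20,
                             sensor_noise_sd_uV = 1,
                             erp_components = default_erp_components(),
                             trial_amp_sd = 0.3,
                             trial_lat_sd_s = 0.010,
                             topo_sd_rad = 0.8,
                             ocular_gain = default_ocular_gain(),
                             pupil_components = default_pupil_components(),
                             pupil_trial_amp_sd = 0.5,
                             pupil_trial_lat_sd_s = 0.050,
                             pupil_baseline_mm = 3.5,
                             pupil_noise_sd_mm = 0.12,
                             pfe_coeffs = list(
                               left  = c(0, -3.0e-3, -1.2e-4,  2.0e-6),
                               right = c(0, -2.5e-3, -1.0e-4, -2.0e-6)),
                             blink_rate_hz = 0.2,
                             blink_dur_s = c(0.15, 0.30),
                             rr_base_s = 0.8,
                             rsa_amp_s = 0.03,
                             rsa_freq_hz = 0.25,
                             rr_jitter_s = 0.005,
                             hr_decel = list(magnitude_bpm = 2,
                                             latency_s = 1.1, width_s = 0.45,
                                             condition_scale = c(
                                               target = 0.8, passive = 1.2,
                                               active = 1.0)),
                             seed = 1L) {
  stopifnot(fs_eeg > 0, fs_gaze > 0, n_runs >= 1, eeg_noise_sd_uV >= 0,
            rr_base_s > 0, rsa_freq_hz > 0, blink_rate_hz >= 0)
  structure(as.list(environment()), class = "generator_config")
}

#' Simulate paradigm event schedules
#'
#' One flight-simulation run schedules 70 targets roughly 4 s apart; 30%
#' of them (randomised) trigger one of three error events, seven per error
#' condition (21 error trials per run), leaving 49 correct targets. Target
#' jumps occur 1.6 s before the glider would pass the target;
#' passive/active rotations are drawn uniformly 1.1-1.8 s before the pass.
#'
#' @param n_runs number of runs (>= 1).
#' @param seed integer RNG seed; the same seed reproduces the schedule.
#' @param spacing_s mean target spacing (s).
#' @param spacing_jitter_s half-range of the uniform spacing jitter (s).
#' @param run_gap_s gap between runs on the session clock (s).
#' @return data.frame of class `paradigm_events` with columns `run_index`,
#'   `onset_s`, `condition`, `prev_target_pass_s`, `pass_s`, `direction`.
#'   `onset_s` is the error onset for error targets and the target pass
#'   time for correct targets; all times are seconds on one session clock
#'   with t = 0 at recording start.
#' @export
simulate_paradigm <- function(n_runs, seed = 1L, spacing_s = 4,
                              spacing_jitter_s = 0.2, run_gap_s = 10) {
  if (!is.numeric(n_runs) || length(n_runs) != 1 || n_runs < 1)
    stop("n_runs must be a positive integer")
  n_runs <- as.integer(n_runs)
  set.seed(as.integer(seed))
  out <- vector("list", n_runs)
  t0 <- 5  # lead-in before the first target of the session
  for (r in seq_len(n_runs)) {
    spacing <- stats::runif(70, spacing_s - spacing_jitter_s,
                            spacing_s + spacing_jitter_s)
    pass <- t0 + cumsum(spacing)
    cond <- rep("correct", 70)
    err_pos <- sample(70, 21)
    cond[err_pos] <- sample(rep(c("target", "passive", "active"), each = 7))
    onset <- pass
    onset[cond == "target"] <- pass[cond == "target"] - 1.6
    pa <- cond %in% c("passive", "active")
    onset[pa] <- pass[pa] - stats::runif(sum(pa), 1.1, 1.8)
    direction <- ifelse(cond == "correct", "none",
                        sample(c("left", "right"), 70, replace = TRUE))
    prev_pass <- c(t0, pass[-70])
    out[[r]] <- data.frame(run_index = r, onset_s = onset, condition = cond,
                           prev_target_pass_s = prev_pass, pass_s = pass,
                           direction = direction, stringsAsFactors = FALSE)
    t0 <- pass[70] + run_gap_s
  }
  ev <- do.call(rbind, out)
  ev$condition <- factor(ev$condition, levels = condition_levels())
  ev <- ev[order(ev$onset_s), ]
  rownames(ev) <- NULL
  ev$event_id <- seq_len(nrow(ev))
  class(ev) <- c("paradigm_events", "data.frame")
  ev
}

session_duration <- function(events, pad_s = 5) max(events$pass_s) + pad_s

# Column index blocks of at most `size` for chunked matrix updates.
col_chunks <- function(n, size = 262144L) {
  split(seq_len(n), ceiling(seq_len(n) / size))
}

# 1/f^a noise of length n at rate fs, unit SD, via spectral shaping.
# The FFT length is padded to a highly composite size (mixed-radix FFTs
# of awkward lengths are prohibitively slow) and the result truncated.
one_over_f_noise <- function(n, fs, exponent) {
  if (exponent == 0) return(stats::rnorm(n))
  m <- stats::nextn(n, c(2, 3, 5))
  w <- stats::rnorm(m)
  W <- stats::fft(w)
  f <- seq(0, fs, length.out = m + 1)[seq_len(m)]
  f[f > fs / 2] <- fs - f[f > fs / 2]  # fold to physical frequency
  g <- c(0, (f[-1] / 1)^(-exponent / 2))  # no DC; 1 Hz reference
  x <- Re(stats::fft(W * g, inverse = TRUE)) / m
  x <- x[seq_len(n)]
  x / stats::sd(x)
}

# Per-condition channel gain maps: Gaussian in great-circle distance from
# the component's centre electrode, 1 at the centre.
component_topographies <- function(comp_tab, labels, topo_sd) {
  pos <- electrode_positions(labels)
  xyz <- as.matrix(pos[, c("x", "y", "z")])
  sapply(seq_len(nrow(comp_tab)), function(i) {
    ctr <- xyz[match(comp_tab$center[i], labels), ]
    arc <- acos(pmax(-1, pmin(1, xyz %*% ctr)))
    exp(-arc^2 / (2 * topo_sd^2))
  })
}

# Channels-by-samples kernel matrix for one condition on time base
# kt (seconds relative to event onset).
condition_kernel <- function(comp_tab, labels, topo_sd, kt) {
  topo <- component_topographies(comp_tab, labels, topo_sd)
  K <- matrix(0, length(labels), length(kt))
  for (i in seq_len(nrow(comp_tab))) {
    k <- comp_tab$amplitude_uV[i] *
      exp(-(kt - comp_tab$latency_s[i])^2 / (2 * comp_tab$width_s[i]^2))
    K <- K + outer(topo[, i], k)
  }
  rownames(K) <- labels
  K
}

# Smooth AR(1) noise with unit SD (tau in samples).
ar1_noise <- function(n, tau) {
  phi <- exp(-1 / tau)
  x <- stats::filter(stats::rnorm(n), phi, method = "recursive")
  as.numeric(x) / stats::sd(x)
}

# Gaze model shared by flight and calibration runs: setpoints with
# sigmoidal saccadic transitions plus fixational AR(1) noise.
gaze_track <- function(t, change_t, setpoints, noise_sd = 0.6, fs = 120,
                       trans_s = 0.12) {
  g <- rep(setpoints[1], length(t))
  for (i in seq_along(change_t)) {
    delta <- setpoints[i + 1] - setpoints[i]
    if (delta == 0) next
    ct <- change_t[i]
    # sigmoid is indistinguishable from its asymptotes beyond +-4 trans_s
    lo <- findInterval(ct - 4 * trans_s, t)
    hi <- findInterval(ct + 4 * trans_s, t)
    if (hi < length(t)) g[(hi + 1):length(t)] <- g[(hi + 1):length(t)] + delta
    idx <- max(1, lo):hi
    g[idx] <- g[idx] + delta / (1 + exp(-(t[idx] - ct) / (trans_s / 6)))
  }
  if (noise_sd > 0) g <- g + noise_sd * ar1_noise(length(t), 0.3 * fs)
  g
}

# Draw blink intervals over [0, dur]; returns data.frame(onset, offset).
draw_blinks <- function(dur, rate_hz, dur_range) {
  if (rate_hz <= 0) return(data.frame(onset = numeric(), offset = numeric()))
  n <- stats::rpois(1, rate_hz * dur)
  if (n == 0) return(data.frame(onset = numeric(), offset = numeric()))
  onset <- sort(stats::runif(n, 1, dur - 1))
  len <- stats::runif(n, dur_range[1], dur_range[2])
  data.frame(onset = onset, offset = onset + len)
}

eval_cubic <- function(coeffs, g) {
  coeffs[1] + coeffs[2] * g + coeffs[3] * g^2 + coeffs[4] * g^3
}

#' Synthesize gaze and pupil streams for a session
#'
#' Pupil diameter per eye is a resting baseline plus condition-specific
#' error-evoked dilation kernels, a cubic function of the horizontal gaze
#' angle (the pupil foreshortening distortion), and slow noise. Gaze
#' follows the target layout with saccadic setpoint changes at each target
#' pass. Blinks are inserted as flagged dropout intervals (samples marked
#' invalid, pupil values NA) at `blink_rate_hz`.
#'
#' @param events a `paradigm_events` table.
#' @param cfg a [generator_config()].
#' @return a [gaze_pupil_stream()].
#' @export
synth_pupil <- function(events, cfg) {
  stopifnot(nrow(events) > 0)
  set.seed(as.integer(cfg$seed) + 101L)
  dur <- session_duration(events)
  fs <- cfg$fs_gaze
  t <- seq(0, dur, by = 1 / fs)
  # gaze: setpoint change at each target pass
  nset <- nrow(events) + 1
  sp_h <- sample(c(-20, 0, 20), nset, replace = TRUE, prob = c(.25, .5, .25))
  sp_v <- sample(c(-6, 0, 6), nset, replace = TRUE, prob = c(.2, .6, .2))
  gh <- gaze_track(t, events$pass_s, sp_h, fs = fs)
  gv <- gaze_track(t, events$pass_s, sp_v, fs = fs)
  # error-evoked dilation (shared by both eyes)
  dil <- rep(0, length(t))
  err <- events[events$condition != "correct", ]
  for (i in seq_len(nrow(err))) {
    pc <- cfg$pupil_components[[as.character(err$condition[i])]]
    amp <- pc$amplitude_mm *
      exp(stats::rnorm(1, 0, cfg$pupil_trial_amp_sd))
    ctr <- err$onset_s[i] + pc$latency_s +
      stats::rnorm(1, 0, cfg$pupil_trial_lat_sd_s)
    idx <- which(t > ctr - 4 * pc$width_s & t < ctr + 4 * pc$width_s)
    dil[idx] <- dil[idx] +
      amp * exp(-(t[idx] - ctr)^2 / (2 * pc$width_s^2))
  }
  mknoise <- function() if (cfg$pupil_noise_sd_mm > 0)
    cfg$pupil_noise_sd_mm * ar1_noise(length(t), 1.0 * fs) else 0
  pl <- cfg$pupil_baseline_mm + dil + eval_cubic(cfg$pfe_coeffs$left, gh) +
    mknoise()
  pr <- cfg$pupil_baseline_mm + dil + eval_cubic(cfg$pfe_coeffs$right, gh) +
    mknoise()
  # blinks: both eyes drop out together
  bl <- draw_blinks(dur, cfg$blink_rate_hz, cfg$blink_dur_s)
  valid <- rep(TRUE, length(t))
  for (i in seq_len(nrow(bl)))
    valid[t >= bl$onset[i] & t <= bl$offset[i]] <- FALSE
  valid[c(1, length(t))] <- TRUE
  pl[!valid] <- NA_real_
  pr[!valid] <- NA_real_
  out <- gaze_pupil_stream(t, gh, gv, pl, pr, valid, valid, fs)
  attr(out, "blink_onsets") <- bl$onset
  out
}

# Unit-peak blink pulse kernel (Hann window, 200 ms).
blink_pulse_kernel <- function(fs, dur_s = 0.2) {
  n <- max(3L, round(dur_s * fs))
  0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = n))
}

# Continuous blink pulse signal from blink onsets.
blink_signal <- function(onsets, n, fs) {
  k <- blink_pulse_kernel(fs)
  s <- rep(0, n)
  for (on in onsets) {
    i0 <- round(on * fs) + 1L
    idx <- i0:min(n, i0 + length(k) - 1L)
    s[idx] <- s[idx] + k[seq_along(idx)]
  }
  s
}

# Ocular reference matrix (3 x samples) at the EEG rate from a gaze/pupil
# stream: horizontal gaze, vertical gaze, blink pulse signal.
ocular_references <- function(stream, n, fs) {
  gh <- resample_linear(stream$gaze_h_deg, attr(stream, "fs"), fs)$x
  gv <- resample_linear(stream$gaze_v_deg, attr(stream, "fs"), fs)$x
  pad <- function(x) { length(x) <- n; x[is.na(x)] <- x[max(which(!is.na(x)))]; x }
  gh <- pad(gh[seq_len(min(n, length(gh)))])
  gv <- pad(gv[seq_len(min(n, length(gv)))])
  bl <- blink_signal(attr(stream, "blink_onsets"), n, fs)
  rbind(gaze_h = gh, gaze_v = gv, blink = bl)
}

#' Synthesize continuous EEG for a session
#'
#' The EEG is a strict sum of three terms: condition-specific ERP
#' component kernels added at each error-event onset (Gaussian bumps with
#' Gaussian scalp topographies), spatially mixed 1/f background noise plus
#' white sensor noise, and ocular sources (horizontal/vertical gaze angle
#' and blink pulses) mixed linearly through `cfg$ocular_gain`. Zeroing any
#' term removes exactly its contribution.
#'
#' @param events a `paradigm_events` table.
#' @param cfg a [generator_config()].
#' @param stream optional [gaze_pupil_stream()] providing the ocular
#'   sources; when `NULL` and `ocular_gain` is non-zero, a stream is
#'   synthesized internally with the same seed.
#' @return a [continuous_eeg()].
#' @export
synth_eeg <- function(events, cfg, stream = NULL) {
  stopifnot(nrow(events) > 0)
  labels <- eeg_montage()
  fs <- cfg$fs_eeg
  dur <- session_duration(events)
  n <- round(dur * fs)
  if (any(events$onset_s > dur))
    stop("event beyond stream duration")
  set.seed(as.integer(cfg$seed) + 202L)
  nch <- length(labels)
  # background: mixed 1/f sources + sensor noise
  if (cfg$eeg_noise_sd_uV > 0) {
    K <- cfg$n_noise_sources
    A <- matrix(stats::rnorm(nch * K), nch, K)
    A <- A / sqrt(rowSums(A^2))
    S <- matrix(0, K, n)
    for (k in seq_len(K))
      S[k, ] <- one_over_f_noise(n, fs, cfg$one_over_f_exponent)
    eeg <- (cfg$eeg_noise_sd_uV * A) %*% S
    rm(S)
    if (cfg$sensor_noise_sd_uV > 0)
      for (blk in col_chunks(n))  # chunked to bound temporaries
        eeg[, blk] <- eeg[, blk] +
          matrix(stats::rnorm(nch * length(blk),
                              sd = cfg$sensor_noise_sd_uV), nch)
  } else {
    eeg <- matrix(0, nch, n)
  }
  rownames(eeg) <- labels
  # event-locked components
  kt <- seq(-0.1, 1.0, by = 1 / fs)
  kernels <- lapply(cfg$erp_components, condition_kernel,
                    labels = labels, topo_sd = cfg$topo_sd_rad, kt = kt)
  err <- events[events$condition != "correct", ]
  for (i in seq_len(nrow(err))) {
    K <- kernels[[as.character(err$condition[i])]]
    amp <- exp(stats::rnorm(1, 0, cfg$trial_amp_sd))
    jit <- round(stats::rnorm(1, 0, cfg$trial_lat_sd_s) * fs)
    i0 <- round((err$onset_s[i] + kt[1]) * fs) + 1L + jit
    idx <- seq(i0, i0 + ncol(K) - 1L)
    ok <- idx >= 1 & idx <= n
    eeg[, idx[ok]] <- eeg[, idx[ok]] + amp * K[, ok]
  }
  # ocular contamination (chunked to bound temporaries)
  if (any(cfg$ocular_gain != 0)) {
    if (is.null(stream)) stream <- synth_pupil(events, cfg)
    R <- ocular_references(stream, n, fs)
    for (blk in col_chunks(n))
      eeg[, blk] <- eeg[, blk] +
        cfg$ocular_gain %*% R[, blk, drop = FALSE]
  }
  continuous_eeg(eeg, fs, labels)
}

#' Synthesize an RR-interval series
#'
#' `RR(t) = rr_base_s + rsa_amp_s * sin(2 pi rsa_freq_hz t) + post-error
#' lengthening kernel + jitter`, integrated into strictly increasing
#' R-peak times. The lengthening kernel is the RR-domain equivalent of a
#' heart-rate deceleration of `hr_decel$magnitude_bpm` beats/min peaking
#' `hr_decel$latency_s` after each error onset.
#'
#' @param events a `paradigm_events` table.
#' @param cfg a [generator_config()].
#' @return an [rr_series()].
#' @export
synth_rr <- function(events, cfg) {
  stopifnot(nrow(events) > 0)
  if (cfg$rr_base_s <= 0) stop("rr_base_s must be positive")
  set.seed(as.integer(cfg$seed) + 303L)
  dur <- session_duration(events)
  err <- events[events$condition != "correct", ]
  hd <- cfg$hr_decel
  # delta-RR amplitude equivalent to the bpm deceleration at baseline HR
  amp_rr <- function(cond)
    hd$magnitude_bpm * unname(hd$condition_scale[cond]) *
      cfg$rr_base_s^2 / 60
  decel <- function(tt) {
    d <- 0
    near <- which(abs(err$onset_s + hd$latency_s - tt) < 4 * hd$width_s)
    for (i in near)
      d <- d + amp_rr(as.character(err$condition[i])) *
        exp(-(tt - err$onset_s[i] - hd$latency_s)^2 / (2 * hd$width_s^2))
    d
  }
  tks <- numeric(ceiling(dur / (cfg$rr_base_s * 0.5)))
  rrs <- numeric(length(tks))
  tk <- 0; k <- 0
  while (tk < dur) {
    # modulation evaluated at the R peak that ends the interval (one
    # fixed-point refinement of the implicit peak time)
    te <- tk + cfg$rr_base_s
    rr <- cfg$rr_base_s +
      cfg$rsa_amp_s * sin(2 * pi * cfg$rsa_freq_hz * te) +
      decel(te) +
      if (cfg$rr_jitter_s > 0) stats::rnorm(1, sd = cfg$rr_jitter_s) else 0
    rr <- max(rr, 0.3)
    tk <- tk + rr
    k <- k + 1
    tks[k] <- tk; rrs[k] <- rr
  }
  rr_series(tks[seq_len(k)], rrs[seq_len(k)])
}

#' Synthesize an eye-calibration recording
#'
#' A ~5 minute recording with three labelled segments: horizontal
#' saccades sweeping seven distinct angles, vertical saccades, and a
#' blink block. EEG contains background noise plus the same linear ocular
#' mixing as the flight runs; the pupil carries the same cubic
#' foreshortening distortion. Used to fit the ocular subtraction model and
#' the pupil-foreshortening regression.
#'
#' @param cfg a [generator_config()].
#' @param seg_dur_s duration of each of the three segments (s).
#' @param with_eeg also synthesize the contaminated EEG (disable for
#'   pupil-only analyses, where only the gaze/pupil stream is needed).
#' @return a [multimodal_recording()] with a `segments` table
#'   (`kind` in `horizontal`, `vertical`, `blink`).
#' @export
synth_eye_calibration <- function(cfg, seg_dur_s = 100, with_eeg = TRUE) {
  set.seed(as.integer(cfg$seed) + 404L)
  fs <- cfg$fs_gaze
  dur <- 3 * seg_dur_s
  t <- seq(0, dur, by = 1 / fs)
  segments <- data.frame(
    kind = c("horizontal", "vertical", "blink"),
    start_s = c(0, seg_dur_s, 2 * seg_dur_s),
    end_s = c(seg_dur_s, 2 * seg_dur_s, dur))
  # horizontal block: step through seven distinct angles every 2 s,
  # return to centre at block end
  ch_h <- seq(2, seg_dur_s - 2, by = 2)
  angles_h <- rep(c(-25, -15, -5, 5, 15, 25, 0), length.out = length(ch_h))
  gh <- gaze_track(t, c(ch_h, seg_dur_s), c(0, angles_h, 0), fs = fs)
  # vertical block
  ch_v <- seg_dur_s + seq(2, seg_dur_s - 2, by = 2)
  angles_v <- rep(c(-15, 15, -8, 8, 0), length.out = length(ch_v))
  gv <- gaze_track(t, c(ch_v, 2 * seg_dur_s), c(0, angles_v, 0), fs = fs)
  # blink block
  bl <- draw_blinks(seg_dur_s, max(cfg$blink_rate_hz, 0.4), cfg$blink_dur_s)
  bl$onset <- bl$onset + 2 * seg_dur_s
  bl$offset <- bl$offset + 2 * seg_dur_s
  valid <- rep(TRUE, length(t))
  for (i in seq_len(nrow(bl)))
    valid[t >= bl$onset[i] & t <= bl$offset[i]] <- FALSE
  valid[c(1, length(t))] <- TRUE
  mknoise <- function() if (cfg$pupil_noise_sd_mm > 0)
    cfg$pupil_noise_sd_mm * ar1_noise(length(t), 1.0 * fs) else 0
  pl <- cfg$pupil_baseline_mm + eval_cubic(cfg$pfe_coeffs$left, gh) + mknoise()
  pr <- cfg$pupil_baseline_mm + eval_cubic(cfg$pfe_coeffs$right, gh) + mknoise()
  pl[!valid] <- NA_real_; pr[!valid] <- NA_real_
  stream <- gaze_pupil_stream(t, gh, gv, pl, pr, valid, valid, fs)
  attr(stream, "blink_onsets") <- bl$onset
  # EEG: noise + ocular mixing (skipped for pupil-only analyses)
  if (!with_eeg)
    return(multimodal_recording(NULL, stream, segments = segments))
  n <- round(dur * cfg$fs_eeg)
  labels <- eeg_montage()
  nch <- length(labels)
  if (cfg$eeg_noise_sd_uV > 0) {
    K <- cfg$n_noise_sources
    A <- matrix(stats::rnorm(nch * K), nch, K)
    A <- A / sqrt(rowSums(A^2))
    S <- matrix(0, K, n)
    for (k in seq_len(K))
      S[k, ] <- one_over_f_noise(n, cfg$fs_eeg, cfg$one_over_f_exponent)
    eeg <- (cfg$eeg_noise_sd_uV * A) %*% S
  } else {
    eeg <- matrix(0, nch, n)
  }
  rownames(eeg) <- labels
  R <- ocular_references(stream, n, cfg$fs_eeg)
  eeg <- eeg + cfg$ocular_gain %*% R
  multimodal_recording(continuous_eeg(eeg, cfg$fs_eeg, labels), stream,
                       segments = segments)
}

#' Simulate a full multimodal session for one participant
#'
#' Generates the event schedule and all three modalities on one session
#' clock, plus the two eye-calibration recordings (one per block).
#'
#' @param cfg a [generator_config()].
#' @return a [multimodal_recording()] with an extra element
#'   `calibrations` (list of two eye-run recordings).
#' @export
simulate_recording <- function(cfg) {
  events <- simulate_paradigm(cfg$n_runs, seed = cfg$seed)
  stream <- synth_pupil(events, cfg)
  eeg <- synth_eeg(events, cfg, stream)
  rr <- synth_rr(events, cfg)
  calib <- list(
    synth_eye_calibration(modify_config(cfg, seed = cfg$seed + 11L)),
    synth_eye_calibration(modify_config(cfg, seed = cfg$seed + 12L)))
  rec <- multimodal_recording(eeg, stream, rr, events)
  rec$calibrations <- calib
  rec
}

#' Modify a generator configuration
#'
#' @param cfg a [generator_config()].
#' @param ... fields to replace.
#' @return updated configuration.
#' @export
modify_config <- function(cfg, ...) {
  repl <- list(...)
  cfg[names(repl)] <- repl
  cfg
}

#' Per-participant configurations for a synthetic cohort
#'
#' Applies moderate inter-subject variability around the default study
#' conditions: log-normal scaling of ERP and pupil response amplitudes
#' (SD 0.15 on the log scale) and a participant-level latency shift
#' (SD 5 ms for ERPs, 20 ms for the pupil). Latency shifts have zero mean,
#' so cohort grand averages stay centred on the default component
#' latencies.
#'
#' @param n_participants cohort size.
#' @param cfg base [generator_config()].
#' @param seed cohort-level seed; participant seeds are derived from it.
#' @return list of per-participant configurations.
#' @export
cohort_configs <- function(n_participants, cfg = generator_config(),
                           seed = 1L) {
  set.seed(as.integer(seed) + 505L)
  lapply(seq_len(n_participants), function(p) {
    amp <- exp(stats::rnorm(1, 0, 0.15))
    dlat <- stats::rnorm(1, 0, 0.005)
    dlat_p <- stats::rnorm(1, 0, 0.020)
    erp <- lapply(cfg$erp_components, function(tab) {
      tab$amplitude_uV <- tab$amplitude_uV * amp
      tab$latency_s <- tab$latency_s + dlat
      tab
    })
    pup <- lapply(cfg$pupil_components, function(pc) {
      pc$amplitude_mm <- pc$amplitude_mm * amp
      pc$latency_s <- pc$latency_s + dlat_p
      pc
    })
    modify_config(cfg, erp_components = erp, pupil_components = pup,
                  seed = as.integer(seed) + 1000L * p)
  })
}
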