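# EEG preprocessing: broadband filtering, ocular artifact subtraction,
# narrow-band filtering and resampling, epoching, artifact rejection,
# bad-channel interpolation, grand-average ERPs.

#' Broadband filtering of raw EEG
#'
#' Zero-phase Butterworth band-pass 0.4-30 Hz (order 4 per section,
#' applied forward-backward) plus 50 Hz and 100 Hz notch filters for
#' power-line noise.
#'
#' @param eeg a [continuous_eeg()] with `fs > 200` (Nyquist headroom for
#'   the 100 Hz notch).
#' @param lo,hi band edges (Hz).
#' @param notch notch frequencies (Hz).
#' @return filtered [continuous_eeg()].
#' @export
filter_raw <- function(eeg, lo = 0.4, hi = 30, notch = c(50, 100)) {
  stopifnot(inherits(eeg, "continuous_eeg"))
  if (length(notch) && eeg$fs <= 2 * max(notch))
    stop("sampling rate too low for the requested notch filters")
  filters <- bandpass_filters(eeg$fs, lo, hi)
  for (f0 in notch) {
    co <- notch_coefs(f0, eeg$fs)
    filters <- c(filters, list(make_zp_filter(co$b, co$a)))
  }
  continuous_eeg(zp_chain(filters, eeg$data), eeg$fs, eeg$channel_names)
}

#' Fit an ocular artifact model on an eye-calibration recording
#'
#' Least-squares regression of each EEG channel onto three ocular
#' reference signals (horizontal gaze angle, vertical gaze angle, blink
#' indicator convolved with a canonical 200 ms pulse), fitted on the
#' labelled artifact segments of the eye run only. The resulting weights
#' are subtracted from subsequent recordings by [remove_ocular()].
#'
#' @param calib a [multimodal_recording()] with a `segments` table
#'   containing `horizontal`, `vertical` and `blink` segments.
#' @return object of class `ocular_model` with fields `weights`
#'   (channels x 3) and `fs`.
#' @export
fit_ocular_model <- function(calib) {
  if (is.null(calib$segments))
    stop("calibration recording carries no segment labels")
  eeg <- calib$eeg
  n <- ncol(eeg$data)
  R <- ocular_references(calib$stream, n, eeg$fs)
  t <- (seq_len(n) - 1) / eeg$fs
  sel <- rep(FALSE, n)
  for (i in seq_len(nrow(calib$segments)))
    sel <- sel | (t >= calib$segments$start_s[i] &
                    t < calib$segments$end_s[i])
  Rs <- R[, sel, drop = FALSE]
  Ys <- eeg$data[, sel, drop = FALSE]
  # W minimising ||Y - W R||^2  =>  W = Y R' (R R')^-1
  W <- t(solve(tcrossprod(Rs), Rs %*% t(Ys)))
  rownames(W) <- eeg$channel_names
  colnames(W) <- rownames(R)
  structure(list(weights = W, fs = eeg$fs), class = "ocular_model")
}

#' Average ocular models
#'
#' @param models list of `ocular_model` objects on the same montage.
#' @return `ocular_model` with element-wise averaged weights.
#' @export
average_ocular_models <- function(models) {
  W <- Reduce(`+`, lapply(models, `[[`, "weights")) / length(models)
  structure(list(weights = W, fs = models[[1]]$fs), class = "ocular_model")
}

#' Subtract ocular artifacts from continuous EEG
#'
#' Rebuilds the three ocular reference signals from the session's gaze
#' stream and blink onsets, resampled to the EEG rate, and subtracts
#' `weights %*% references`. Samples where all references are zero are
#' untouched.
#'
#' @param eeg a [continuous_eeg()].
#' @param model an `ocular_model` from [fit_ocular_model()].
#' @param stream the session [gaze_pupil_stream()] (with blink onsets).
#' @return corrected [continuous_eeg()].
#' @export
remove_ocular <- function(eeg, model, stream) {
  stopifnot(inherits(model, "ocular_model"))
  if (!identical(rownames(model$weights), eeg$channel_names))
    stop("ocular model fitted on a different montage")
  R <- ocular_references(stream, ncol(eeg$data), eeg$fs)
  continuous_eeg(eeg$data - model$weights %*% R, eeg$fs, eeg$channel_names)
}

#' Narrow-band filtering, resampling and frontal channel removal
#'
#' Zero-phase 1-10 Hz Butterworth band-pass (order 4 per section),
#' anti-aliased resampling to 64 Hz (linear interpolation is exact to
#' rounding here because the signal is already band-limited to 10 Hz),
#' and removal of the frontopolar and anterior-frontal channels, leaving
#' 58 channels.
#'
#' @param eeg a [continuous_eeg()].
#' @param lo,hi band edges (Hz).
#' @param fs_out output rate (Hz).
#' @param drop channels to remove after filtering.
#' @return a [continuous_eeg()] at `fs_out`.
#' @export
narrowband_resample_select <- function(eeg, lo = 1, hi = 10, fs_out = 64,
                                       drop = frontal_drop_channels()) {
  stopifnot(inherits(eeg, "continuous_eeg"))
  x <- bw_bandpass(eeg$data, eeg$fs, lo, hi)
  rs <- resample_linear(x, eeg$fs, fs_out)
  x <- rs$x
  missing <- setdiff(drop, eeg$channel_names)
  if (length(missing)) {
    warning("channels not present, drop step skipped for: ",
            paste(missing, collapse = ", "))
    drop <- intersect(drop, eeg$channel_names)
  }
  keep <- setdiff(eeg$channel_names, drop)
  continuous_eeg(x[keep, , drop = FALSE], fs_out, keep)
}

#' Segment continuous data into labelled trials
#'
#' Error trials span \[-0.5, 1\] s around the error onset; correct trials
#' are 1.5 s windows starting 1.5 s after the previous target pass.
#' Trials exceeding the recording are skipped and logged.
#'
#' @param eeg a [continuous_eeg()] (any rate).
#' @param events a `paradigm_events` table.
#' @return an [epoch_set()] (trials x channels x 1.5 s).
#' @export
epoch_trials <- function(eeg, events) {
  fs <- eeg$fs
  nsamp <- round(1.5 * fs)
  t_axis <- seq(-0.5, by = 1 / fs, length.out = nsamp)
  starts <- ifelse(events$condition == "correct",
                   events$prev_target_pass_s + 1.5,
                   events$onset_s - 0.5)
  i0 <- round(starts * fs) + 1L
  ok <- i0 >= 1 & (i0 + nsamp - 1L) <= ncol(eeg$data)
  skipped <- which(!ok)
  dat <- array(0, c(sum(ok), nrow(eeg$data), nsamp),
               dimnames = list(NULL, eeg$channel_names, NULL))
  kept_events <- which(ok)
  for (j in seq_along(kept_events)) {
    i <- kept_events[j]
    dat[j, , ] <- eeg$data[, i0[i]:(i0[i] + nsamp - 1L)]
  }
  log <- data.frame(trial = skipped,
                    reason = rep("outside recording", length(skipped)))
  epoch_set(dat, events$condition[ok], t_axis, fs,
            event_id = events$event_id[ok],
            channel_names = eeg$channel_names, rejection_log = log)
}

# Excess kurtosis of a vector.
.kurtosis <- function(x) {
  x <- x - mean(x)
  n <- length(x)
  (sum(x^4) / n) / (sum(x^2) / n)^2 - 3
}

#' Artifact-based trial rejection
#'
#' A trial is marked rejected when (i) any sample exceeds the amplitude
#' threshold, (ii) any channel's excess kurtosis, z-scored across trials
#' per channel, exceeds `z_thresh`, or (iii) its joint-probability
#' statistic (mean negative log-likelihood of its sample amplitudes under
#' per-channel kernel-density estimates pooled over all trials), z-scored
#' across trials, exceeds `z_thresh`. Rejected trials stay in the set with
#' `kept = FALSE`; `rejection_log` records the first matching reason.
#'
#' @param epochs an [epoch_set()] with at least `min_trials` trials.
#' @param amp_uV amplitude threshold (microvolts).
#' @param z_thresh z-score threshold for kurtosis and joint probability.
#' @param min_trials minimum trial count for stable z-scoring.
#' @return the epoch set with updated `kept` and `rejection_log`.
#' @export
reject_artifacts <- function(epochs, amp_uV = 35, z_thresh = 5,
                             min_trials = 10) {
  ntr <- dim(epochs$data)[1]
  if (ntr < min_trials)
    stop("need at least ", min_trials, " trials for stable z-scoring")
  nch <- dim(epochs$data)[2]
  amp_bad <- apply(abs(epochs$data), 1, max) > amp_uV
  # kurtosis per channel per trial, z-scored across trials per channel
  ku <- matrix(0, ntr, nch)
  for (ch in seq_len(nch))
    ku[, ch] <- apply(epochs$data[, ch, , drop = FALSE], 1, .kurtosis)
  kz <- scale(ku)
  kz[is.nan(kz)] <- 0
  kurt_bad <- apply(kz, 1, max) > z_thresh
  # joint probability: per-channel KDE over pooled samples
  jp <- matrix(0, ntr, nch)
  for (ch in seq_len(nch)) {
    pooled <- as.vector(epochs$data[, ch, ])
    de <- stats::density(pooled, n = 512)
    f <- stats::approxfun(de$x, pmax(de$y, 1e-12), rule = 2)
    jp[, ch] <- apply(epochs$data[, ch, , drop = FALSE], 1,
                      function(x) -mean(log(f(x))))
  }
  jstat <- rowMeans(jp)
  jz <- as.vector(scale(jstat))
  jz[is.nan(jz)] <- 0
  jp_bad <- jz > z_thresh
  reason <- ifelse(amp_bad, "amplitude",
                   ifelse(kurt_bad, "kurtosis",
                          ifelse(jp_bad, "joint_probability", NA)))
  bad <- which(!is.na(reason))
  epochs$kept <- epochs$kept & is.na(reason)
  epochs$rejection_log <- rbind(
    epochs$rejection_log,
    data.frame(trial = bad, reason = reason[bad]))
  epochs
}

#' Variance-based bad-channel detection and spherical interpolation
#'
#' Channel variances are pooled over kept trials; channels above
#' `Q3 + 1.5 IQR` are replaced by spherical-spline interpolation from the
#' remaining channels in every trial. Aborts when more than
#' `max_frac` of channels are flagged.
#'
#' @param epochs an [epoch_set()] with channel names from the montage.
#' @param max_frac maximum tolerated fraction of bad channels.
#' @return the epoch set with interpolated channels; flagged labels in
#'   attribute `interpolated`.
#' @export
interpolate_bad_channels <- function(epochs, max_frac = 0.25) {
  labels <- epochs$channel_names
  stopifnot(!is.null(labels))
  keep <- which(epochs$kept)
  v <- apply(epochs$data[keep, , , drop = FALSE], 2,
             function(x) stats::var(as.vector(x)))
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
  thr <- q[2] + 1.5 * (q[2] - q[1])
  bad <- which(v > thr)
  if (length(bad) > max_frac * length(labels))
    stop("more than ", round(100 * max_frac),
         "% of channels flagged bad; data unusable")
  if (length(bad)) {
    pos <- electrode_positions(labels)
    for (tr in seq_len(dim(epochs$data)[1])) {
      d <- epochs$data[tr, , ]
      rownames(d) <- labels
      epochs$data[tr, , ] <- spherical_interpolate(d, bad, pos)
    }
  }
  attr(epochs, "interpolated") <- labels[bad]
  epochs
}

#' Grand-average event-related potentials
#'
#' Re-references every trial to the common average, averages kept trials
#' per condition within participant, then averages across participants
#' and computes the SEM.
#'
#' @param epoch_sets list of per-participant [epoch_set()]s sharing the
#'   same time axis and channels.
#' @param conditions conditions to include.
#' @param reref re-reference each trial to the common average (EEG
#'   display convention); skipped automatically for single-channel
#'   modalities.
#' @return list per condition with `mean` and `sem`
#'   (channels x samples), plus `t_axis` and `channel_names`.
#' @export
grand_average_erp <- function(epoch_sets,
                              conditions = condition_levels(),
                              reref = TRUE) {
  t_axis <- epoch_sets[[1]]$t_axis
  for (es in epoch_sets)
    if (!isTRUE(all.equal(es$t_axis, t_axis)))
      stop("epoch sets have mismatched time axes")
  labels <- epoch_sets[[1]]$channel_names
  out <- list()
  for (cond in conditions) {
    per_part <- lapply(epoch_sets, function(es) {
      idx <- which(es$kept & es$labels == cond)
      if (!length(idx)) return(NULL)
      d <- es$data[idx, , , drop = FALSE]
      # common-average re-reference per trial (meaningless for a single
      # channel, where it would null the signal)
      if (reref && dim(d)[2] > 1)
        for (i in seq_along(idx)) {
          sl <- d[i, , , drop = FALSE][1, , ]
          d[i, , ] <- sweep(sl, 2, colMeans(sl))
        }
      apply(d, c(2, 3), mean)
    })
    per_part <- Filter(Negate(is.null), per_part)
    arr <- simplify2array(per_part)  # channels x samples x participants
    np <- dim(arr)[3]
    m <- apply(arr, c(1, 2), mean)
    s <- apply(arr, c(1, 2), stats::sd) / sqrt(np)
    if (np == 1) s[, ] <- 0
    rownames(m) <- rownames(s) <- labels
    out[[cond]] <- list(mean = m, sem = s)
  }
  out$t_axis <- t_axis
  out$channel_names <- labels
  out
}

#' Peak latency within a window
#'
#' @param trace numeric vector (one channel).
#' @param t_axis sample times (s).
#' @param window two-element window (s).
#' @param mode `"min"` (negative peak) or `"max"`.
#' @return list with `latency_s` and `value`.
#' @export
peak_latency <- function(trace, t_axis, window, mode = c("min", "max")) {
  mode <- match.arg(mode)
  idx <- which(t_axis >= window[1] - 1e-9 & t_axis <= window[2] + 1e-9)
  i <- if (mode == "min") idx[which.min(trace[idx])] else
    idx[which.max(trace[idx])]
  list(latency_s = t_axis[i], value = trace[i])
}
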