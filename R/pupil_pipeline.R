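# Pupillometric preprocessing: blink interpolation, resampling and
# band-pass filtering, pupil-foreshortening correction, epoching with
# variance-based rejection and baseline correction.

#' Linear interpolation of blinks in the pupil streams
#'
#' Invalid (blink) runs are replaced, per eye, by linear interpolation
#' between the flanking valid samples; leading/trailing invalid samples
#' are filled with the nearest valid value. Validity flags are preserved
#' for audit.
#'
#' @param stream a [gaze_pupil_stream()].
#' @return the stream with interpolated pupil columns.
#' @export
interpolate_blinks <- function(stream) {
  fill <- function(x, valid) {
    if (!any(valid)) stop("an eye is entirely invalid")
    if (all(valid)) return(x)
    stats::approx(stream$t_s[valid], x[valid], xout = stream$t_s,
                  rule = 2)$y
  }
  stream$pupil_left_mm <- fill(stream$pupil_left_mm, stream$valid_left)
  stream$pupil_right_mm <- fill(stream$pupil_right_mm, stream$valid_right)
  stream
}

#' Resample and band-pass filter the pupil streams
#'
#' Resamples all stream columns to a uniform grid at `fs_out` (default
#' 128 Hz) and applies a zero-phase 0.1-10 Hz Butterworth band-pass
#' (order 4 per section) to the pupil columns. Gaze columns are resampled
#' but not filtered (they feed the foreshortening correction, which needs
#' the raw angle). Validity is carried over by nearest-neighbour rule.
#'
#' @param stream a blink-interpolated [gaze_pupil_stream()].
#' @param fs_out output rate (Hz).
#' @param lo,hi band edges (Hz).
#' @return a [gaze_pupil_stream()] at `fs_out`.
#' @export
resample_filter_pupil <- function(stream, fs_out = 128, lo = 0.1, hi = 10) {
  t <- stream$t_s
  tout <- seq(t[1], t[length(t)], by = 1 / fs_out)
  rs <- function(x) stats::approx(t, x, xout = tout, rule = 2)$y
  rsv <- function(v) stats::approx(t, as.numeric(v), xout = tout,
                                   method = "constant", rule = 2)$y > 0.5
  pl <- bw_bandpass(rs(stream$pupil_left_mm), fs_out, lo, hi)
  pr <- bw_bandpass(rs(stream$pupil_right_mm), fs_out, lo, hi)
  out <- gaze_pupil_stream(tout, rs(stream$gaze_h_deg), rs(stream$gaze_v_deg),
                           pl, pr, rsv(stream$valid_left),
                           rsv(stream$valid_right), fs_out)
  attr(out, "blink_onsets") <- attr(stream, "blink_onsets")
  attr(out, "bandpass") <- c(lo, hi)
  out
}

#' Fit the pupil-foreshortening regression
#'
#' Per-eye least-squares cubic of pupil size on the horizontal gaze angle
#' over the horizontal-saccade segments of an eye-calibration recording.
#'
#' @param calib_stream the calibration [gaze_pupil_stream()] (blink
#'   interpolation is applied internally if needed).
#' @param saccade_segments data.frame with `start_s`, `end_s` rows
#'   delimiting the horizontal-saccade segments.
#' @return object of class `pfe_model` with `coeffs_left`, `coeffs_right`
#'   (intercept, deg, deg^2, deg^3), the calibration mean angle
#'   `center_deg` and the calibration angle range.
#' @export
fit_pfe <- function(calib_stream, saccade_segments) {
  sel <- rep(FALSE, nrow(calib_stream))
  for (i in seq_len(nrow(saccade_segments)))
    sel <- sel | (calib_stream$t_s >= saccade_segments$start_s[i] &
                    calib_stream$t_s < saccade_segments$end_s[i])
  g <- calib_stream$gaze_h_deg[sel]
  if (length(unique(round(g))) < 4)
    stop("need at least 4 distinct horizontal angles to fit a cubic")
  fit_eye <- function(p, valid) {
    ok <- valid[sel] & !is.na(p[sel])
    X <- cbind(1, g[ok], g[ok]^2, g[ok]^3)
    qrx <- qr(X)
    if (qrx$rank < 4) stop("rank-deficient design in foreshortening fit")
    qr.coef(qrx, p[sel][ok])
  }
  structure(list(
    coeffs_left = fit_eye(calib_stream$pupil_left_mm,
                          calib_stream$valid_left),
    coeffs_right = fit_eye(calib_stream$pupil_right_mm,
                           calib_stream$valid_right),
    center_deg = mean(g),
    range_deg = range(g)), class = "pfe_model")
}

#' Subtract the pupil-foreshortening dependency
#'
#' Per eye, subtracts the gaze-dependent part of the fitted cubic
#' evaluated at the instantaneous horizontal gaze angle. Only the
#' dependency is removed: the cubic is centred at the calibration mean
#' angle, so the absolute pupil level is preserved. When the stream has
#' already been band-pass filtered (by [resample_filter_pupil()]), the
#' dependency is passed through the same band before subtraction —
#' the foreshortening bias present in filtered data is the filtered
#' bias, and subtracting the raw cubic instead would leave slow
#' saccade-locked residuals from the high-pass edge. Warns when angles
#' fall far outside the calibration range.
#'
#' @param stream a [gaze_pupil_stream()].
#' @param model a `pfe_model` from [fit_pfe()].
#' @param extrapolation_warn_deg slack beyond the calibration range
#'   before warning.
#' @return corrected stream.
#' @export
correct_pfe <- function(stream, model, extrapolation_warn_deg = 5) {
  g <- stream$gaze_h_deg
  if (any(g < model$range_deg[1] - extrapolation_warn_deg |
            g > model$range_deg[2] + extrapolation_warn_deg))
    warning("gaze angles far outside the calibration range; ",
            "foreshortening correction extrapolates")
  bp <- attr(stream, "bandpass")
  fs <- attr(stream, "fs")
  dep <- function(coeffs) {
    d <- eval_cubic(coeffs, g) - eval_cubic(coeffs, model$center_deg)
    if (!is.null(bp)) d <- bw_bandpass(d, fs, bp[1], bp[2])
    d
  }
  stream$pupil_left_mm <- stream$pupil_left_mm - dep(model$coeffs_left)
  stream$pupil_right_mm <- stream$pupil_right_mm - dep(model$coeffs_right)
  stream
}

#' Epoch the pupil signal with variance rejection and baselines
#'
#' Averages the two eyes, cuts 1.5 s trials (error trials \[-0.5, 1\] s
#' around the error onset, correct trials 1.5 s after the previous target
#' pass as for the EEG), rejects trials with variance above
#' `Q3 + 1.5 IQR` -- computed separately for the error and correct pools
#' -- and baseline-corrects: error trials by the mean of \[-0.5, 0\] s,
#' correct trials by the mean of the entire trial.
#'
#' @param stream a corrected, resampled [gaze_pupil_stream()].
#' @param events a `paradigm_events` table.
#' @return an [epoch_set()] with one channel (`pupil`), millimetres
#'   relative to baseline.
#' @export
epoch_pupil <- function(stream, events) {
  fs <- attr(stream, "fs")
  avg <- (stream$pupil_left_mm + stream$pupil_right_mm) / 2
  eeg_like <- continuous_eeg(matrix(avg, 1, dimnames = list("pupil", NULL)),
                             fs, "pupil")
  # epoch_trials uses sample index = round(t * fs); shift times so that
  # index 1 corresponds to stream$t_s[1]
  ev <- events
  ev$onset_s <- ev$onset_s - stream$t_s[1]
  ev$prev_target_pass_s <- ev$prev_target_pass_s - stream$t_s[1]
  epochs <- epoch_trials(eeg_like, ev)
  # variance rejection in separate pools
  v <- apply(epochs$data[, 1, , drop = FALSE], 1,
             function(x) stats::var(as.vector(x)))
  flag_pool <- function(idx) {
    if (length(idx) < 4) return(integer())
    q <- stats::quantile(v[idx], c(0.25, 0.75), names = FALSE)
    idx[v[idx] > q[2] + 1.5 * (q[2] - q[1])]
  }
  bad <- c(flag_pool(which(epochs$labels != "correct")),
           flag_pool(which(epochs$labels == "correct")))
  if (length(bad)) {
    epochs$kept[bad] <- FALSE
    epochs$rejection_log <- rbind(
      epochs$rejection_log,
      data.frame(trial = bad, reason = "variance"))
  }
  # baselines
  base_idx <- which(epochs$t_axis < 0)
  for (i in seq_len(dim(epochs$data)[1])) {
    b <- if (epochs$labels[i] == "correct") mean(epochs$data[i, 1, ])
    else mean(epochs$data[i, 1, base_idx])
    epochs$data[i, 1, ] <- epochs$data[i, 1, ] - b
  }
  epochs
}
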