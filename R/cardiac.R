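# Cardiac processing: RR series to heart-rate change epochs.

#' Convert an RR series to a uniform heart-rate stream
#'
#' Heart rate at each R peak is `60 / rr_s` (beats per minute); values
#' are linearly interpolated onto a uniform grid.
#'
#' @param rr an [rr_series()] with at least two peaks.
#' @param fs_out output rate (Hz); heart rate is slow, 4 Hz suffices.
#' @return list with `hr_bpm`, `t_s` and `fs`.
#' @export
rr_to_hr <- function(rr, fs_out = 4) {
  if (nrow(rr) < 2) stop("need at least two R peaks")
  tout <- seq(0, max(rr$r_peak_t_s), by = 1 / fs_out)
  hr <- stats::approx(rr$r_peak_t_s, 60 / rr$rr_s, xout = tout, rule = 2)$y
  list(hr_bpm = hr, t_s = tout, fs = fs_out)
}

#' Epoch heart-rate changes around events
#'
#' Cuts \[-0.5, 3\] s epochs around each event onset (correct trials
#' around the nominal pass time) and subtracts the per-trial mean of the
#' \[-0.5, 0\] s baseline window. Epochs off either end of the stream are
#' skipped and logged.
#'
#' @param hr a heart-rate stream from [rr_to_hr()].
#' @param events a `paradigm_events` table.
#' @param window epoch window (s) relative to onset.
#' @return an [epoch_set()] with one channel (`hr`), bpm relative to
#'   baseline.
#' @export
epoch_hr <- function(hr, events, window = c(-0.5, 3)) {
  fs <- hr$fs
  nsamp <- round((window[2] - window[1]) * fs) + 1L
  t_axis <- seq(window[1], by = 1 / fs, length.out = nsamp)
  i0 <- round((events$onset_s + window[1]) * fs) + 1L
  ok <- i0 >= 1 & (i0 + nsamp - 1L) <= length(hr$hr_bpm)
  dat <- array(0, c(sum(ok), 1, nsamp), dimnames = list(NULL, "hr", NULL))
  kept_events <- which(ok)
  base_idx <- which(t_axis < 0)
  for (j in seq_along(kept_events)) {
    x <- hr$hr_bpm[i0[kept_events[j]]:(i0[kept_events[j]] + nsamp - 1L)]
    dat[j, 1, ] <- x - mean(x[base_idx])
  }
  log <- data.frame(trial = which(!ok),
                    reason = rep("outside recording", sum(!ok)))
  epoch_set(dat, events$condition[ok], t_axis, fs,
            event_id = events$event_id[ok], channel_names = "hr",
            rejection_log = log)
}

#' Peak heart-rate deceleration per condition
#'
#' Minimum of the per-condition trial-average heart-rate change within
#' the deceleration window.
#'
#' @param epochs an [epoch_set()] from [epoch_hr()].
#' @param window search window (s), default \[0.7, 1.7\].
#' @return named numeric vector of minima (bpm) per condition present.
#' @export
peak_deceleration <- function(epochs, window = c(0.7, 1.7)) {
  stopifnot(min(epochs$t_axis) <= window[1],
            max(epochs$t_axis) >= window[2])
  idx <- which(epochs$t_axis >= window[1] - 1e-9 & epochs$t_axis <= window[2] + 1e-9)
  conds <- levels(epochs$labels)[table(epochs$labels[epochs$kept]) > 0]
  out <- vapply(conds, function(cond) {
    tr <- which(epochs$kept & epochs$labels == cond)
    avg <- apply(epochs$data[tr, 1, , drop = FALSE], 3, mean)
    min(avg[idx])
  }, numeric(1))
  names(out) <- conds
  out
}

#' Threshold-based R-peak detection (utility)
#'
#' Simple detector for raw ECG: samples above `thresh_sd` robust SDs of
#' the signal, reduced to local maxima separated by at least
#' `refractory_s`.
#'
#' @param ecg numeric vector (arbitrary units).
#' @param fs sampling rate (Hz).
#' @param thresh_sd detection threshold in robust SD units.
#' @param refractory_s minimum peak separation (s).
#' @return an [rr_series()].
#' @export
detect_r_peaks <- function(ecg, fs, thresh_sd = 3, refractory_s = 0.3) {
  thr <- stats::median(ecg) + thresh_sd * stats::mad(ecg)
  above <- which(ecg > thr)
  if (!length(above)) stop("no peaks above threshold")
  peaks <- integer()
  i <- 1
  while (i <= length(above)) {
    run_end <- i
    while (run_end < length(above) &&
             above[run_end + 1] - above[run_end] < refractory_s * fs)
      run_end <- run_end + 1
    seg <- above[i:run_end]
    peaks <- c(peaks, seg[which.max(ecg[seg])])
    i <- run_end + 1
  }
  tt <- (peaks - 1) / fs
  rr_series(tt[-1], diff(tt))
}
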