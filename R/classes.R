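# S3 containers shared by the pipelines.

#' Continuous EEG container
#'
#' @param data channels-by-samples numeric matrix, microvolts.
#' @param fs sampling rate in Hz.
#' @param channel_names labels for the rows of `data`.
#' @return object of class `continuous_eeg`.
#' @export
continuous_eeg <- function(data, fs, channel_names = rownames(data)) {
  stopifnot(is.matrix(data), fs > 0, length(channel_names) == nrow(data),
            !anyDuplicated(channel_names))
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = channel_names),
            class = "continuous_eeg")
}

#' @export
print.continuous_eeg <- function(x, ...) {
  cat(sprintf("<continuous_eeg> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Epoch container (trials x channels x samples)
#'
#' @param data 3-d array `[trial, channel, sample]` (microvolts for EEG) or,
#'   for single-channel modalities, a trials-by-samples matrix which is
#'   promoted to a 3-d array with one channel.
#' @param labels factor (or character) of per-trial condition labels with
#'   levels `target`, `passive`, `active`, `correct`.
#' @param t_axis sample times in seconds relative to the event onset.
#' @param fs sampling rate in Hz.
#' @param event_id integer identity of the originating event row, used to
#'   align trials across modalities after independent rejections.
#' @param channel_names optional channel labels.
#' @param kept logical per-trial mask (artifact rejection sets entries
#'   FALSE but keeps the data for audit).
#' @param rejection_log data.frame (`trial`, `reason`).
#' @return object of class `epoch_set`.
#' @export
epoch_set <- function(data, labels, t_axis, fs, event_id = seq_len(dim(data)[1]),
                      channel_names = NULL, kept = NULL, rejection_log = NULL) {
  if (length(dim(data)) == 2) data <- array(data, c(nrow(data), 1, ncol(data)))
  stopifnot(length(dim(data)) == 3)
  labels <- factor(as.character(labels), levels = condition_levels())
  stopifnot(dim(data)[1] == length(labels), dim(data)[3] == length(t_axis))
  if (is.null(kept)) kept <- rep(TRUE, dim(data)[1])
  if (is.null(rejection_log))
    rejection_log <- data.frame(trial = integer(), reason = character())
  if (!is.null(channel_names)) dimnames(data)[[2]] <- channel_names
  structure(list(data = data, labels = labels, t_axis = t_axis, fs = fs,
                 event_id = event_id,
                 channel_names = dimnames(data)[[2]],
                 kept = kept, rejection_log = rejection_log),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set> %d trials (%d kept) x %d channels x %d samples @ %g Hz\n",
    dim(x$data)[1], sum(x$kept), dim(x$data)[2], dim(x$data)[3], x$fs))
  print(table(x$labels[x$kept]))
  invisible(x)
}

#' Condition labels of the paradigm
#' @return character vector `c("target", "passive", "active", "correct")`.
#' @export
condition_levels <- function() c("target", "passive", "active", "correct")

#' Drop rejected trials from an epoch set
#'
#' @param epochs an `epoch_set`.
#' @return the epoch set restricted to kept trials.
#' @export
drop_rejected <- function(epochs) {
  keep <- which(epochs$kept)
  epoch_set(epochs$data[keep, , , drop = FALSE], epochs$labels[keep],
            epochs$t_axis, epochs$fs, event_id = epochs$event_id[keep],
            channel_names = epochs$channel_names,
            rejection_log = epochs$rejection_log)
}

#' Subset an epoch set by trial index
#' @param epochs an `epoch_set`.
#' @param idx trial indices to keep.
#' @return restricted epoch set.
#' @export
subset_trials <- function(epochs, idx) {
  epoch_set(epochs$data[idx, , , drop = FALSE], epochs$labels[idx],
            epochs$t_axis, epochs$fs, event_id = epochs$event_id[idx],
            channel_names = epochs$channel_names,
            kept = epochs$kept[idx])
}

#' Gaze/pupil stream container
#'
#' @param t_s sample times (s), strictly increasing.
#' @param gaze_h_deg,gaze_v_deg gaze angles (deg).
#' @param pupil_left_mm,pupil_right_mm pupil diameters (mm).
#' @param valid_left,valid_right per-sample validity (FALSE during blinks).
#' @param fs nominal sampling rate in Hz.
#' @return data.frame of class `gaze_pupil_stream` with attribute `fs`.
#' @export
gaze_pupil_stream <- function(t_s, gaze_h_deg, gaze_v_deg, pupil_left_mm,
                              pupil_right_mm, valid_left, valid_right, fs) {
  stopifnot(all(diff(t_s) > 0))
  out <- data.frame(t_s = t_s, gaze_h_deg = gaze_h_deg,
                    gaze_v_deg = gaze_v_deg,
                    pupil_left_mm = pupil_left_mm,
                    pupil_right_mm = pupil_right_mm,
                    valid_left = valid_left, valid_right = valid_right)
  attr(out, "fs") <- fs
  class(out) <- c("gaze_pupil_stream", "data.frame")
  out
}

#' RR-interval series container
#'
#' @param r_peak_t_s R-peak times (s), strictly increasing.
#' @param rr_s intervals (s): `rr_s[k] = r_peak_t_s[k] - r_peak_t_s[k-1]`
#'   (the first entry is the interval preceding the first listed peak).
#' @return data.frame of class `rr_series`.
#' @export
rr_series <- function(r_peak_t_s, rr_s) {
  stopifnot(all(diff(r_peak_t_s) > 0), all(rr_s > 0),
            length(r_peak_t_s) == length(rr_s))
  out <- data.frame(r_peak_t_s = r_peak_t_s, rr_s = rr_s)
  class(out) <- c("rr_series", "data.frame")
  out
}

#' Multimodal recording container
#'
#' Synchronised streams of one session: all streams share t = 0 at
#' recording start.
#'
#' @param eeg a [continuous_eeg()].
#' @param stream a [gaze_pupil_stream()].
#' @param rr an [rr_series()].
#' @param events a paradigm event table (see [simulate_paradigm()]).
#' @param segments optional labelled segment table (eye-calibration runs):
#'   columns `kind`, `start_s`, `end_s`.
#' @return object of class `multimodal_recording`.
#' @export
multimodal_recording <- function(eeg, stream, rr = NULL, events = NULL,
                                 segments = NULL) {
  structure(list(eeg = eeg, stream = stream, rr = rr, events = events,
                 segments = segments),
            class = "multimodal_recording")
}
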