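# Plain-text serialisation: tab-separated event/stream/RR tables and an
# array container (TSV + JSON sidecar) for epoch sets.

#' Write / read a paradigm event table
#'
#' Tab-separated with columns `onset_s`, `run_index`, `condition`,
#' `direction`, `prev_target_pass_s`, `pass_s`, `event_id`.
#'
#' @param events a `paradigm_events` table.
#' @param path file path.
#' @return (read) the event table.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  ev <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  ev$condition <- factor(ev$condition, levels = condition_levels())
  class(ev) <- c("paradigm_events", "data.frame")
  ev
}

#' Write / read a gaze/pupil stream
#'
#' @param stream a [gaze_pupil_stream()].
#' @param path file path.
#' @return (read) the stream.
#' @export
write_stream_tsv <- function(stream, path) {
  utils::write.table(as.data.frame(stream), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stream_tsv
#' @param fs sampling rate of the stored stream (Hz).
#' @export
read_stream_tsv <- function(path, fs) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  gaze_pupil_stream(d$t_s, d$gaze_h_deg, d$gaze_v_deg, d$pupil_left_mm,
                    d$pupil_right_mm, as.logical(d$valid_left),
                    as.logical(d$valid_right), fs)
}

#' Write / read an RR series
#'
#' Two-column tab-separated table (`r_peak_t_s`, `rr_s`).
#'
#' @param rr an [rr_series()].
#' @param path file path.
#' @return (read) the series.
#' @export
write_rr_tsv <- function(rr, path) {
  utils::write.table(as.data.frame(rr), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_rr_tsv
#' @export
read_rr_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  rr_series(d$r_peak_t_s, d$rr_s)
}

#' Write / read an epoch set (TSV matrix + JSON sidecar)
#'
#' The data array is flattened to a trials-by-(channels * samples) TSV;
#' labels, time axis, channel names, kept mask and rejection log go to a
#' JSON sidecar `<path>.json`.
#'
#' @param epochs an [epoch_set()].
#' @param path base file path (data written to `path`, metadata to
#'   `paste0(path, ".json")`).
#' @return (read) the epoch set.
#' @export
write_epochs <- function(epochs, path) {
  d <- dim(epochs$data)
  flat <- matrix(epochs$data, d[1], d[2] * d[3])
  utils::write.table(flat, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(dim = d, labels = as.character(epochs$labels),
               t_axis = epochs$t_axis, fs = epochs$fs,
               event_id = epochs$event_id,
               channel_names = epochs$channel_names,
               kept = epochs$kept,
               rejection_log = epochs$rejection_log)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  flat <- as.matrix(utils::read.table(path, sep = "\t"))
  epoch_set(array(flat, meta$dim), meta$labels, meta$t_axis, meta$fs,
            event_id = meta$event_id, channel_names = meta$channel_names,
            kept = meta$kept,
            rejection_log = as.data.frame(meta$rejection_log))
}
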