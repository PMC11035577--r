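# Config-driven orchestration: simulate -> preprocess -> decode -> fuse
# -> test, with a manifest for reproducibility.

#' Pipeline configuration
#'
#' Flat declarative configuration for [run_pipeline()]. Per-stage and
#' per-participant seeds are derived from the single master `seed` via
#' [derive_seed()].
#'
#' @param n_participants synthetic cohort size.
#' @param generator base [generator_config()] for the cohort.
#' @param layouts decoding layouts (subset of `one_channel`,
#'   `three_channel`, `full`).
#' @param windows window lengths in samples at 32 Hz.
#' @param fusion fusion modes (subset of `eeg_only`, `pupil_only`, `sf`,
#'   `bf`).
#' @param reps,folds cross-validation scheme.
#' @param seed master seed.
#' @param out_dir output directory for result tables and the manifest.
#' @param stages character vector of enabled stages, in fixed order
#'   `simulate`, `preprocess`, `decode`, `cardiac`, `stats`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_participants = 19,
                            generator = generator_config(),
                            layouts = c("one_channel", "three_channel",
                                        "full"),
                            windows = c(1, 4, 8, 16),
                            fusion = c("eeg_only", "pupil_only", "sf",
                                       "bf"),
                            reps = 10, folds = 5, seed = 1L,
                            out_dir = tempfile("errpfusion_run_"),
                            stages = c("simulate", "preprocess", "decode",
                                       "cardiac", "stats")) {
  cfg <- list(n_participants = n_participants, generator = generator,
              layouts = layouts, windows = windows, fusion = fusion,
              reps = reps, folds = folds, seed = as.integer(seed),
              out_dir = out_dir, stages = stages)
  validate_pipeline_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_pipeline_config <- function(cfg) {
  stopifnot(cfg$n_participants >= 1,
            inherits(cfg$generator, "generator_config"),
            all(cfg$layouts %in% c("one_channel", "three_channel", "full")),
            all(cfg$windows %in% c(1, 4, 8, 16)),
            all(cfg$fusion %in% c("eeg_only", "pupil_only", "sf", "bf")),
            cfg$reps >= 1, cfg$folds >= 2,
            all(cfg$stages %in% c("simulate", "preprocess", "decode",
                                  "cardiac", "stats")))
  invisible(cfg)
}

#' Deterministic seed derivation
#'
#' Maps (master seed, stage, unit) to a reproducible 31-bit seed, so
#' every stochastic step of the pipeline is replayable from the single
#' master seed.
#'
#' @param master master seed.
#' @param stage stage index (1-based).
#' @param unit unit index within the stage (participant, seed repeat...).
#' @return integer seed below 2^31.
#' @export
derive_seed <- function(master, stage, unit = 1L) {
  as.integer((as.numeric(master) * 7919 + stage * 104729 + unit * 1299709) %%
               2147483647)
}

#' Preprocess one simulated participant
#'
#' Runs the full per-modality chains on a [simulate_recording()] output:
#' EEG (broadband filter, block-wise ocular subtraction using the two eye
#' runs, 1-10 Hz, 64 Hz, frontal drop, epoching, artifact rejection,
#' bad-channel interpolation), pupil (blink interpolation, 128 Hz
#' 0.1-10 Hz, foreshortening correction fitted on the first eye run,
#' epoching with variance rejection and baselines) and heart rate (4 Hz
#' interpolation, \[-0.5, 3\] s epochs).
#'
#' @param rec a [multimodal_recording()] with `calibrations`.
#' @param reject apply EEG artifact rejection / channel interpolation
#'   (disable only for controlled noise-free checks).
#' @return list with `eeg_epochs`, `pupil_epochs`, `hr_epochs`, `events`.
#' @export
preprocess_participant <- function(rec, reject = TRUE) {
  events <- rec$events
  # --- EEG ---
  eeg <- filter_raw(rec$eeg)
  rec$eeg <- NULL   # drop the raw copy; continuous EEG is large
  models <- lapply(rec$calibrations, fit_ocular_model)
  # block-wise application: model 1 up to the end of run 4 (or the whole
  # session for short simulations), model 2 afterwards; the subtraction
  # is applied per column block to avoid duplicating the recording
  n_runs <- max(events$run_index)
  n <- ncol(eeg$data)
  R <- ocular_references(rec$stream, n, eeg$fs)
  blocks <- if (n_runs >= 5 && length(models) >= 2) {
    split_t <- max(events$pass_s[events$run_index == 4]) + 1
    i_split <- round(split_t * eeg$fs)
    list(list(model = models[[1]], cols = 1:i_split),
         list(model = models[[2]], cols = (i_split + 1):n))
  } else {
    list(list(model = models[[1]], cols = 1:n))
  }
  for (b in blocks)
    eeg$data[, b$cols] <- eeg$data[, b$cols] -
      b$model$weights %*% R[, b$cols, drop = FALSE]
  rm(R)
  eeg <- narrowband_resample_select(eeg)
  eeg_epochs <- epoch_trials(eeg, events)
  if (reject) {
    eeg_epochs <- reject_artifacts(eeg_epochs)
    eeg_epochs <- interpolate_bad_channels(eeg_epochs)
  }
  # --- pupil ---
  stream <- interpolate_blinks(rec$stream)
  stream <- resample_filter_pupil(stream)
  calib1 <- rec$calibrations[[1]]
  pfe <- fit_pfe(interpolate_blinks(calib1$stream),
                 calib1$segments[calib1$segments$kind == "horizontal", ])
  stream <- correct_pfe(stream, pfe)
  pupil_epochs <- epoch_pupil(stream, events)
  # --- cardiac ---
  hr_epochs <- if (!is.null(rec$rr))
    epoch_hr(rr_to_hr(rec$rr), events) else NULL
  list(eeg_epochs = eeg_epochs, pupil_epochs = pupil_epochs,
       hr_epochs = hr_epochs, events = events)
}

#' Simulate and preprocess one participant with bounded memory
#'
#' Equivalent to [simulate_recording()] followed by
#' [preprocess_participant()], but composed so that at most one full-size
#' copy of the continuous EEG is alive alongside the filtering buffers
#' (a nine-run 63-channel session at 512 Hz is ~0.7 GB per copy). The
#' numerical result is identical to the two-step path.
#'
#' @param cfg a [generator_config()].
#' @param reject apply the trial/channel artifact stages.
#' @return as [preprocess_participant()].
#' @export
simulate_and_preprocess <- function(cfg, reject = TRUE) {
  events <- simulate_paradigm(cfg$n_runs, seed = cfg$seed)
  stream <- synth_pupil(events, cfg)
  rr <- synth_rr(events, cfg)
  calibs <- list(
    synth_eye_calibration(modify_config(cfg, seed = cfg$seed + 11L)),
    synth_eye_calibration(modify_config(cfg, seed = cfg$seed + 12L)))
  # --- EEG, with single ownership of the big matrix ---
  eeg <- synth_eeg(events, cfg, stream)
  fs <- eeg$fs
  eeg <- filter_raw(eeg)
  models <- lapply(calibs, fit_ocular_model)
  n <- ncol(eeg$data)
  R <- ocular_references(stream, n, fs)
  n_runs <- max(events$run_index)
  blocks <- if (n_runs >= 5) {
    split_t <- max(events$pass_s[events$run_index == 4]) + 1
    i_split <- round(split_t * fs)
    list(list(model = models[[1]], cols = 1:i_split),
         list(model = models[[2]], cols = (i_split + 1):n))
  } else {
    list(list(model = models[[1]], cols = 1:n))
  }
  for (b in blocks)
    for (blk in col_chunks(length(b$cols))) {
      cols <- b$cols[blk]
      eeg$data[, cols] <- eeg$data[, cols] -
        b$model$weights %*% R[, cols, drop = FALSE]
    }
  rm(R)
  eeg <- narrowband_resample_select(eeg)
  eeg_epochs <- epoch_trials(eeg, events)
  rm(eeg)
  if (reject) {
    eeg_epochs <- reject_artifacts(eeg_epochs)
    eeg_epochs <- interpolate_bad_channels(eeg_epochs)
  }
  # --- pupil ---
  pstream <- resample_filter_pupil(interpolate_blinks(stream))
  pfe <- fit_pfe(interpolate_blinks(calibs[[1]]$stream),
                 calibs[[1]]$segments[
                   calibs[[1]]$segments$kind == "horizontal", ])
  pupil_epochs <- epoch_pupil(correct_pfe(pstream, pfe), events)
  hr_epochs <- epoch_hr(rr_to_hr(rr), events)
  list(eeg_epochs = eeg_epochs, pupil_epochs = pupil_epochs,
       hr_epochs = hr_epochs, events = events)
}

#' Run the full synthetic-cohort pipeline
#'
#' Executes the enabled stages in fixed order and writes tidy result
#' tables plus a JSON manifest to `cfg$out_dir`. Every stochastic step is
#' seeded from the master seed through [derive_seed()]; re-running with
#' an identical configuration reproduces identical outputs.
#'
#' @param cfg a [pipeline_config()].
#' @return the run manifest (invisibly also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(cfg) {
  validate_pipeline_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  gens <- cohort_configs(cfg$n_participants, cfg$generator,
                         seed = derive_seed(cfg$seed, 1))
  acc_rows <- list(); peak_rows <- list(); hr_rows <- list()
  part_data <- vector("list", cfg$n_participants)
  for (p in seq_len(cfg$n_participants)) {
    if (!all(c("simulate", "preprocess") %in% cfg$stages)) break
    pre <- simulate_and_preprocess(gens[[p]])
    if (!"cardiac" %in% cfg$stages) pre$hr_epochs <- NULL
    part_data[[p]] <- pre
    gc(verbose = FALSE)
  }
  if ("decode" %in% cfg$stages && "preprocess" %in% cfg$stages) {
    for (p in seq_len(cfg$n_participants)) {
      pre <- part_data[[p]]
      eeg32 <- resample_epochs(balance_classes(
        pre$eeg_epochs, seed = derive_seed(cfg$seed, 2, p)))
      pup32 <- resample_epochs(pre$pupil_epochs)
      for (w in cfg$windows) for (lay in cfg$layouts) {
        ch <- layout_channels(lay, eeg32$channel_names)
        need_fused <- any(c("sf", "bf") %in% cfg$fusion)
        plan_seed <- derive_seed(cfg$seed, 3, p)
        results <- list()
        if (need_fused || "bf" %in% cfg$fusion) {
          al <- align_epochs(eeg32, pup32)
          plan <- make_folds(al$a$labels, cfg$reps, cfg$folds, plan_seed)
          if ("eeg_only" %in% cfg$fusion || "bf" %in% cfg$fusion)
            results$eeg_only <- decode_sliding(
              al$a, ch, w, fold_plan = plan, collect = "bf" %in% cfg$fusion)
          if ("pupil_only" %in% cfg$fusion || "bf" %in% cfg$fusion)
            results$pupil_only <- decode_sliding(
              al$b, "pupil", w, fold_plan = plan,
              collect = "bf" %in% cfg$fusion)
          if ("sf" %in% cfg$fusion)
            results$sf <- decode_sliding(
              simple_fusion_features(al$a, al$b), c(ch, "pupil"), w,
              fold_plan = plan)
          if ("bf" %in% cfg$fusion)
            results$bf <- bayes_fuse_results(results$eeg_only,
                                             results$pupil_only)
        } else {
          if ("eeg_only" %in% cfg$fusion)
            results$eeg_only <- decode_sliding(eeg32, ch, w,
                                               reps = cfg$reps,
                                               k = cfg$folds,
                                               seed = plan_seed)
          if ("pupil_only" %in% cfg$fusion)
            results$pupil_only <- decode_sliding(
              balance_classes(pup32, seed = derive_seed(cfg$seed, 2, p)),
              "pupil", w, reps = cfg$reps, k = cfg$folds,
              seed = plan_seed)
        }
        for (mode in intersect(cfg$fusion, names(results))) {
          res <- results[[mode]]
          pm <- peak_metrics(res)
          acc_rows[[length(acc_rows) + 1]] <- data.frame(
            participant = p, layout = lay, window = w, fusion = mode,
            time_s = res$times, accuracy = res$accuracy)
          peak_rows[[length(peak_rows) + 1]] <- data.frame(
            participant = p, layout = lay, window = w, fusion = mode,
            peak_accuracy = pm$peak_accuracy,
            peak_time_s = pm$peak_time_s,
            mean_correct_post = pm$mean_correct_post)
        }
      }
    }
  }
  if ("cardiac" %in% cfg$stages && "preprocess" %in% cfg$stages) {
    for (p in seq_len(cfg$n_participants)) {
      if (is.null(part_data[[p]]$hr_epochs)) next
      dec <- peak_deceleration(part_data[[p]]$hr_epochs)
      hr_rows[[length(hr_rows) + 1]] <- data.frame(
        participant = p, condition = names(dec), peak_decel_bpm = dec)
    }
  }
  write_tab <- function(rows, name) {
    if (!length(rows)) return(NULL)
    tab <- do.call(rbind, rows)
    path <- file.path(cfg$out_dir, name)
    utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    files <<- c(files, path)
    tab
  }
  acc_tab <- write_tab(acc_rows, "accuracy.tsv")
  peak_tab <- write_tab(peak_rows, "peak_metrics.tsv")
  write_tab(hr_rows, "hr_deceleration.tsv")
  if ("stats" %in% cfg$stages && !is.null(peak_tab) &&
      cfg$n_participants >= 3) {
    metric_list <- list()
    for (w in unique(peak_tab$window)) {
      sub <- peak_tab[peak_tab$window == w & peak_tab$layout ==
                        cfg$layouts[1], ]
      m <- tapply(sub$peak_accuracy, list(sub$participant, sub$fusion),
                  identity)
      if (!anyNA(m) && ncol(m) >= 2)
        metric_list[[paste0("window_", w)]] <- m
    }
    if (length(metric_list)) {
      cmp <- compare_decoders(metric_list)
      path <- file.path(cfg$out_dir, "friedman.tsv")
      utils::write.table(cmp$omnibus, path, sep = "\t",
                         row.names = FALSE, quote = FALSE)
      files <- c(files, path)
    }
  }
  # significance threshold from the per-participant balanced trial counts
  thr <- NA_real_
  if (!is.null(acc_tab)) {
    n_bal <- vapply(part_data, function(pd) {
      bc <- balance_classes(pd$eeg_epochs, seed = 1)
      sum(bc$kept)
    }, numeric(1))
    thr <- average_binomial_threshold(n_bal)
  }
  cfg_path <- file.path(cfg$out_dir, "config.json")
  cfg_json <- cfg
  cfg_json$generator <- cfg$generator[
    !vapply(cfg$generator, is.matrix, logical(1))]
  jsonlite::write_json(cfg_json, cfg_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  manifest <- list(config_hash = unname(tools::md5sum(cfg_path)),
                   files = basename(c(files, cfg_path)),
                   seed = cfg$seed,
                   chance_level = 0.25,
                   significance_threshold = thr,
                   out_dir = cfg$out_dir)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Summarise a pipeline run
#'
#' Renders a plain-markdown summary of a completed run: peak-accuracy and
#' mean-correct tables per layout/window/fusion mode with the theoretical
#' chance level (25%) and the cohort binomial significance threshold, the
#' heart-rate deceleration table, and the Friedman statistics where
#' present. Missing stage outputs are skipped with a notice.
#'
#' @param manifest a manifest from [run_pipeline()].
#' @param path output file (default `report.md` in the run directory).
#' @return the report path, invisibly.
#' @export
pipeline_report <- function(manifest, path = file.path(manifest$out_dir,
                                                       "report.md")) {
  lines <- c("# Pipeline report", "",
             sprintf("Theoretical chance level: 25%%"),
             sprintf("Average binomial significance threshold: %s",
                     if (is.na(manifest$significance_threshold)) "n/a"
                     else sprintf("%.1f%%",
                                  100 * manifest$significance_threshold)),
             "")
  rd <- function(name) {
    p <- file.path(manifest$out_dir, name)
    if (!file.exists(p)) return(NULL)
    utils::read.table(p, header = TRUE, sep = "\t")
  }
  pk <- rd("peak_metrics.tsv")
  if (is.null(pk)) {
    lines <- c(lines, "_Decoding stage outputs missing; section skipped._")
  } else {
    lines <- c(lines, "## Peak accuracies", "",
               "| layout | window | fusion | peak acc | peak t (ms) | mean correct [0,1] s |",
               "|---|---|---|---|---|---|")
    agg <- stats::aggregate(
      cbind(peak_accuracy, peak_time_s, mean_correct_post) ~
        layout + window + fusion, data = pk, FUN = mean)
    for (i in seq_len(nrow(agg)))
      lines <- c(lines, sprintf("| %s | %d | %s | %.1f%% | %.0f | %.1f%% |",
                                agg$layout[i], agg$window[i], agg$fusion[i],
                                100 * agg$peak_accuracy[i],
                                1000 * agg$peak_time_s[i],
                                100 * agg$mean_correct_post[i]))
  }
  hr <- rd("hr_deceleration.tsv")
  if (!is.null(hr)) {
    lines <- c(lines, "", "## Peak heart-rate decelerations (bpm)", "")
    agg <- stats::aggregate(peak_decel_bpm ~ condition, data = hr,
                            FUN = mean)
    for (i in seq_len(nrow(agg)))
      lines <- c(lines, sprintf("- %s: %.2f", agg$condition[i],
                                agg$peak_decel_bpm[i]))
  }
  fr <- rd("friedman.tsv")
  if (!is.null(fr)) {
    lines <- c(lines, "", "## Friedman omnibus tests", "")
    for (i in seq_len(nrow(fr)))
      lines <- c(lines, sprintf("- %s: chi-squared %.2f, p (FDR) %.3g",
                                fr$group[i], fr$chisq[i], fr$p_fdr[i]))
  }
  writeLines(lines, path)
  invisible(path)
}
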