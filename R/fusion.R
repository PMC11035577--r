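# Hybrid EEG-pupil fusion: feature concatenation (simple fusion) and
# confusion-matrix Bayesian belief combination.

#' Align two epoch sets on common events
#'
#' After independent artifact rejections the two modalities may retain
#' different trials; fusion uses the intersection, matched by event
#' identity and ordered identically.
#'
#' @param a,b [epoch_set()]s carrying `event_id`.
#' @return list of the two restricted epoch sets.
#' @export
align_epochs <- function(a, b) {
  ids <- intersect(a$event_id[a$kept], b$event_id[b$kept])
  if (!length(ids)) stop("no common trials between the modalities")
  list(a = subset_trials(a, match(ids, a$event_id)),
       b = subset_trials(b, match(ids, b$event_id)))
}

#' Simple fusion: append the pupil as an extra channel
#'
#' The pupil epochs (same decoding rate and time axis) are appended to
#' the EEG epochs as one additional channel. The trials are intersected
#' by event identity. Equal footing of the modalities is ensured later by
#' the per-feature training-fold z-scoring inside
#' [train_window_decoder()], which gives every channel zero mean and unit
#' variance before the PCA.
#'
#' @param eeg_epochs,pupil_epochs [epoch_set()]s at the decoding rate.
#' @return fused [epoch_set()] with `C + 1` channels.
#' @export
simple_fusion_features <- function(eeg_epochs, pupil_epochs) {
  stopifnot(eeg_epochs$fs == pupil_epochs$fs,
            dim(eeg_epochs$data)[3] == dim(pupil_epochs$data)[3])
  al <- align_epochs(eeg_epochs, pupil_epochs)
  ne <- dim(al$a$data)[2]
  dat <- array(0, c(dim(al$a$data)[1], ne + 1, dim(al$a$data)[3]))
  dat[, seq_len(ne), ] <- al$a$data
  dat[, ne + 1, ] <- al$b$data[, 1, ]
  epoch_set(dat, al$a$labels, al$a$t_axis, al$a$fs,
            event_id = al$a$event_id,
            channel_names = c(al$a$channel_names, "pupil"))
}

#' Confusion matrix of a trained decoder
#'
#' Counts of (true class, predicted class) over the given trials; rows
#' index the true class, columns the prediction.
#'
#' @param decoder a `window_decoder`.
#' @param epochs the [epoch_set()] it was trained on.
#' @param trials trial indices to evaluate (typically the training
#'   folds).
#' @return M x M integer matrix.
#' @export
estimate_confusion <- function(decoder, epochs, trials) {
  p <- predict(decoder, epochs, trials = trials)
  classes <- decoder$slda$classes
  truth <- factor(as.character(epochs$labels[trials]), levels = classes)
  as.matrix(table(truth, factor(as.character(p), levels = classes)))
}

#' Bayesian belief fusion of classifier predictions
#'
#' Combines the hard predictions of K classifiers using their confusion
#' matrices: the belief for class i is the prior times the product over
#' classifiers of `P(true = i | predicted = e_k)`, where the conditional
#' is the prediction-column-normalised (optionally Laplace-smoothed)
#' confusion count. Returns the class with maximal belief; ties break to
#' the lowest class index.
#'
#' @param predictions integer vector (length K) of predicted class
#'   indices, or a factor/character vector matched against `class_order`.
#' @param confusions list of K square count matrices (rows = true class,
#'   columns = predicted class).
#' @param priors class priors (default uniform).
#' @param smoothing Laplace constant added to every count before column
#'   normalisation (default 1; 0 reproduces the raw conditional).
#' @param class_order optional class labels for non-integer predictions.
#' @return integer index of the fused class (attribute `belief` holds the
#'   normalised belief vector).
#' @export
bayes_fuse <- function(predictions, confusions, priors = NULL,
                       smoothing = 1, class_order = NULL) {
  M <- nrow(confusions[[1]])
  if (!is.numeric(predictions)) {
    if (is.null(class_order)) class_order <- rownames(confusions[[1]])
    predictions <- match(as.character(predictions), class_order)
  }
  stopifnot(length(predictions) == length(confusions),
            all(predictions >= 1 & predictions <= M))
  if (is.null(priors)) priors <- rep(1 / M, M)
  stopifnot(abs(sum(priors) - 1) < 1e-8)
  O <- priors
  for (kk in seq_along(confusions)) {
    cnt <- confusions[[kk]] + smoothing
    col <- cnt[, predictions[kk]]
    O <- O * col / sum(col)
  }
  out <- which.max(O)  # ties: lowest index
  attr(out, "belief") <- if (sum(O) > 0) O / sum(O) else O
  out
}

#' Bayesian fusion of two sliding-window decoding results
#'
#' Requires both results to come from [decode_sliding()] with
#' `collect = TRUE`, the same trials (in the same order) and the same
#' fold plan. At every (repetition, fold, evaluation position) the two
#' test predictions of each trial are fused via [bayes_fuse()] using the
#' confusion matrices the two decoders produced on their training folds.
#'
#' @param res_a,res_b `decoding_result`s with collected predictions.
#' @param priors class priors (default uniform).
#' @param smoothing Laplace smoothing constant.
#' @return a `decoding_result` for the fused classifier.
#' @export
bayes_fuse_results <- function(res_a, res_b, priors = NULL, smoothing = 1) {
  stopifnot(identical(res_a$fold_plan, res_b$fold_plan),
            identical(as.character(res_a$labels),
                      as.character(res_b$labels)),
            !is.null(res_a$predictions), !is.null(res_b$predictions))
  plan <- res_a$fold_plan
  classes <- res_a$classes
  M <- length(classes)
  npos <- dim(res_a$predictions)[1]
  ntr <- dim(res_a$predictions)[2]
  reps <- dim(res_a$predictions)[3]
  k <- max(plan)
  truth <- match(as.character(res_a$labels), classes)
  acc_rep <- matrix(0, npos, reps)
  conf <- array(0L, c(M, M, npos), dimnames = list(classes, classes, NULL))
  for (r in seq_len(reps)) {
    for (fold in seq_len(k)) {
      te <- which(plan[, r] == fold)
      for (pi in seq_len(npos)) {
        ca <- res_a$train_confusion[, , pi, fold, r]
        cb <- res_b$train_confusion[, , pi, fold, r]
        for (u in te) {
          fu <- bayes_fuse(c(res_a$predictions[pi, u, r],
                             res_b$predictions[pi, u, r]),
                           list(ca, cb), priors = priors,
                           smoothing = smoothing)
          acc_rep[pi, r] <- acc_rep[pi, r] + (fu == truth[u])
          conf[truth[u], fu, pi] <- conf[truth[u], fu, pi] + 1L
        }
      }
    }
  }
  acc_rep <- acc_rep / ntr
  structure(list(times = res_a$times, accuracy = rowMeans(acc_rep),
                 accuracy_rep = acc_rep, confusion = conf,
                 classes = classes, labels = res_a$labels,
                 fold_plan = plan,
                 window_samples = res_a$window_samples),
            class = "decoding_result")
}
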