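# Asynchronous sliding-window multiclass decoding: class balancing,
# stratified repeated cross-validation, per-window feature extraction
# with standardization + 99%-variance PCA, and shrinkage LDA.

#' Channel layouts for decoding
#'
#' @param name `one_channel` (FCz), `three_channel` (FCz, Cz, Pz) or
#'   `full` (all available channels).
#' @param available channel labels present in the epochs.
#' @return character vector of layout channels.
#' @export
layout_channels <- function(name = c("one_channel", "three_channel", "full"),
                            available) {
  name <- match.arg(name)
  ch <- switch(name,
               one_channel = "FCz",
               three_channel = c("FCz", "Cz", "Pz"),
               full = available)
  missing <- setdiff(ch, available)
  if (length(missing))
    stop("layout channels not in data: ", paste(missing, collapse = ", "))
  ch
}

#' Subsample correct trials to balance the classes
#'
#' Keeps all error trials and randomly subsamples the correct trials to
#' the rounded mean of the three error-class counts (round half to even).
#'
#' @param epochs an [epoch_set()]; only kept trials are considered.
#' @param seed RNG seed for the subsample.
#' @return a new [epoch_set()] containing the balanced kept trials.
#' @export
balance_classes <- function(epochs, seed = 1L) {
  keep <- which(epochs$kept)
  labs <- epochs$labels[keep]
  err_counts <- table(labs)[c("target", "passive", "active")]
  if (any(err_counts == 0) || !any(labs == "correct"))
    stop("all four classes must be present")
  target <- round(mean(err_counts))
  corr <- keep[labs == "correct"]
  set.seed(as.integer(seed))
  chosen <- if (length(corr) < target) {
    warning("fewer correct trials than the balancing target; keeping all")
    corr
  } else if (length(corr) == target) corr
  else sort(sample(corr, target))
  subset_trials(epochs, sort(c(keep[labs != "correct"], chosen)))
}

#' Stratified repeated k-fold assignments
#'
#' @param labels per-trial class labels.
#' @param reps number of independent repetitions.
#' @param k folds per repetition.
#' @param seed RNG seed.
#' @return integer matrix trials-by-reps of fold ids (1..k); within each
#'   repetition the folds partition the trials with per-class balance.
#' @export
make_folds <- function(labels, reps = 10, k = 5, seed = 1L) {
  labels <- as.factor(labels)
  if (min(table(droplevels(labels))) < k)
    stop("need at least ", k, " trials per class")
  set.seed(as.integer(seed))
  n <- length(labels)
  out <- matrix(0L, n, reps)
  for (r in seq_len(reps)) {
    for (cl in levels(droplevels(labels))) {
      idx <- sample(which(labels == cl))
      out[idx, r] <- rep_len(seq_len(k), length(idx))
    }
  }
  out
}

# Ledoit-Wolf-type analytic shrinkage of a covariance toward nu * I,
# computed from centered data rows X (n x p). Returns the shrunk
# covariance and the intensity.
shrink_cov <- function(X) {
  n <- nrow(X); p <- ncol(X)
  S <- crossprod(X) / n
  nu <- sum(diag(S)) / p
  xx <- rowSums(X^2)
  num <- (sum(xx^2) - 2 * sum(X * (X %*% S)) + n * sum(S^2)) / n^2
  den <- sum(S^2) - p * nu^2
  lambda <- if (den <= 0) 1 else max(0, min(1, num / den))
  list(sigma = (1 - lambda) * S + lambda * nu * diag(p),
       lambda = lambda)
}

# Fit a multiclass shrinkage LDA on features X (n x p) and factor y.
slda_fit <- function(X, y) {
  y <- droplevels(as.factor(y))
  classes <- levels(y)
  if (nrow(X) < length(classes)) stop("fewer training trials than classes")
  mu <- do.call(rbind, lapply(classes, function(cl)
    colMeans(X[y == cl, , drop = FALSE])))
  Xc <- X - mu[as.integer(y), , drop = FALSE]
  sh <- shrink_cov(Xc)
  W <- t(solve(sh$sigma, t(mu)))          # class x p discriminant weights
  b <- -0.5 * rowSums(W * mu) + log(1 / length(classes))
  list(W = W, b = b, classes = classes, lambda = sh$lambda)
}

# Predict class indices (into model$classes); ties broken by lowest index.
slda_predict <- function(model, X) {
  sc <- X %*% t(model$W) + rep(model$b, each = nrow(X))
  max.col(sc, ties.method = "first")
}

#' Train a single-window decoder
#'
#' Features are the raw amplitudes of the layout channels within the
#' window (`C * W` values per trial), z-scored with training statistics,
#' projected onto the minimal PCA basis explaining at least 99% of the
#' training variance, and classified with a four-class shrinkage LDA
#' (analytic shrinkage toward the scaled identity).
#'
#' @param epochs an [epoch_set()] at the decoding rate.
#' @param channels layout channel labels.
#' @param window_samples window length in samples.
#' @param position index of the sample at which the window ends.
#' @param trials trial indices to train on (default: all kept).
#' @param var_explained PCA variance fraction to retain.
#' @return object of class `window_decoder`.
#' @export
train_window_decoder <- function(epochs, channels, window_samples, position,
                                 trials = which(epochs$kept),
                                 var_explained = 0.99) {
  X <- window_features(epochs, channels, window_samples, position, trials)
  y <- droplevels(epochs$labels[trials])
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sd, "/")
  pc <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  v <- pc$sdev^2
  ncomp <- if (sum(v) == 0) 1L else
    which(cumsum(v) / sum(v) >= var_explained)[1]
  basis <- pc$rotation[, seq_len(ncomp), drop = FALSE]
  Z <- Xs %*% basis
  model <- slda_fit(Z, y)
  structure(list(mu = mu, sd = sd, basis = basis, slda = model,
                 channels = channels, window_samples = window_samples,
                 position = position),
            class = "window_decoder")
}

# Feature matrix: trials x (channels * window).
window_features <- function(epochs, channels, window_samples, position,
                            trials) {
  if (position < window_samples || position > dim(epochs$data)[3])
    stop("window does not fit at this position")
  chi <- match(channels, epochs$channel_names)
  stopifnot(!anyNA(chi))
  idx <- (position - window_samples + 1L):position
  X <- epochs$data[trials, chi, idx, drop = FALSE]
  dim(X) <- c(length(trials), length(chi) * length(idx))
  X
}

#' Predict with a trained window decoder
#'
#' @param object a `window_decoder`.
#' @param epochs an [epoch_set()] on the same layout and rate.
#' @param trials trial indices to predict.
#' @param ... unused.
#' @return factor of predicted labels.
#' @export
predict.window_decoder <- function(object, epochs,
                                   trials = which(epochs$kept), ...) {
  X <- window_features(epochs, object$channels, object$window_samples,
                       object$position, trials)
  Xs <- sweep(sweep(X, 2, object$mu), 2, object$sd, "/")
  Z <- Xs %*% object$basis
  factor(object$slda$classes[slda_predict(object$slda, Z)],
         levels = object$slda$classes)
}

#' Resample an epoch set to the decoding rate
#'
#' Subsamples by an integer factor (the signals are band-limited to 10 Hz
#' before any decoding, far below the 16 Hz output Nyquist rate).
#'
#' @param epochs an [epoch_set()] whose `fs` is an integer multiple of
#'   `fs_out`.
#' @param fs_out output rate, default 32 Hz.
#' @return resampled [epoch_set()].
#' @export
resample_epochs <- function(epochs, fs_out = 32) {
  fac <- epochs$fs / fs_out
  if (abs(fac - round(fac)) > 1e-9)
    stop("fs must be an integer multiple of fs_out")
  fac <- as.integer(round(fac))
  if (fac == 1L) return(epochs)
  idx <- seq(1L, dim(epochs$data)[3], by = fac)
  epoch_set(epochs$data[, , idx, drop = FALSE], epochs$labels,
            epochs$t_axis[idx], fs_out, event_id = epochs$event_id,
            channel_names = epochs$channel_names, kept = epochs$kept)
}

#' Asynchronous sliding-window decoding with repeated cross-validation
#'
#' Slides a window through the epochs in steps of one sample at the
#' decoding rate (an output every 31.25 ms at 32 Hz); the output at time
#' t uses the window ending at t. For every evaluation position and every
#' (repetition, fold) a fresh decoder is trained on the training folds
#' and evaluated on the test fold; all standardization, projection and
#' discriminant statistics come from the training folds only.
#'
#' @param epochs an [epoch_set()] at the decoding rate (e.g. from
#'   [resample_epochs()]), typically class-balanced.
#' @param channels layout channel labels (see [layout_channels()]).
#' @param window_samples window length in samples (1, 4, 8 or 16 at
#'   32 Hz).
#' @param reps,k cross-validation scheme (default 10 times 5-fold).
#' @param seed seed for the fold plan.
#' @param fold_plan optional precomputed fold matrix from [make_folds()]
#'   (required for fusing decoders across modalities).
#' @param collect when TRUE, stores per-trial test predictions and
#'   training-set confusion matrices per (rep, fold, position) for
#'   Bayesian fusion.
#' @return object of class `decoding_result`: `times` (s), `accuracy`
#'   (mean fraction correct per evaluation time), `accuracy_rep`
#'   (positions x reps), `confusion` (M x M x positions test counts,
#'   rows = true class), and with `collect = TRUE` also `predictions`
#'   (positions x trials x reps) and `train_confusion`
#'   (M x M x positions x k x reps).
#' @export
decode_sliding <- function(epochs, channels, window_samples, reps = 10,
                           k = 5, seed = 1L, fold_plan = NULL,
                           collect = FALSE) {
  trials <- which(epochs$kept)
  labs <- droplevels(epochs$labels[trials])
  classes <- levels(labs)
  M <- length(classes)
  nsamp <- dim(epochs$data)[3]
  positions <- seq(window_samples, nsamp)
  if (is.null(fold_plan))
    fold_plan <- make_folds(labs, reps = reps, k = k, seed = seed)
  reps <- ncol(fold_plan)
  k <- max(fold_plan)
  npos <- length(positions)
  acc_rep <- matrix(0, npos, reps)
  conf <- array(0L, c(M, M, npos), dimnames = list(classes, classes, NULL))
  preds <- if (collect) array(NA_integer_, c(npos, length(trials), reps))
  tconf <- if (collect) array(0L, c(M, M, npos, k, reps),
                              dimnames = list(classes, classes, NULL,
                                              NULL, NULL))
  for (r in seq_len(reps)) {
    hits <- matrix(0, npos, 1)
    for (fold in seq_len(k)) {
      te <- which(fold_plan[, r] == fold)
      tr <- which(fold_plan[, r] != fold)
      for (pi in seq_len(npos)) {
        dec <- train_window_decoder(epochs, channels, window_samples,
                                    positions[pi], trials = trials[tr])
        p <- predict(dec, epochs, trials = trials[te])
        hits[pi] <- hits[pi] + sum(p == labs[te])
        ti <- match(as.character(labs[te]), classes)
        pj <- match(as.character(p), classes)
        for (u in seq_along(te))
          conf[ti[u], pj[u], pi] <- conf[ti[u], pj[u], pi] + 1L
        if (collect) {
          preds[pi, te, r] <- match(as.character(p), classes)
          ptr <- predict(dec, epochs, trials = trials[tr])
          ttr <- match(as.character(labs[tr]), classes)
          pjr <- match(as.character(ptr), classes)
          for (u in seq_along(tr))
            tconf[ttr[u], pjr[u], pi, fold, r] <-
              tconf[ttr[u], pjr[u], pi, fold, r] + 1L
        }
      }
    }
    acc_rep[, r] <- hits / length(trials)
  }
  structure(list(times = epochs$t_axis[positions],
                 accuracy = rowMeans(acc_rep),
                 accuracy_rep = acc_rep,
                 confusion = conf,
                 classes = classes,
                 labels = labs,
                 fold_plan = fold_plan,
                 window_samples = window_samples,
                 predictions = preds,
                 train_confusion = tconf),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  pm <- peak_metrics(x)
  cat(sprintf(
    "<decoding_result> %d evaluation times; peak %.1f%% at %.0f ms; mean correct [0,1] s: %.1f%%\n",
    length(x$times), 100 * pm$peak_accuracy, 1000 * pm$peak_time_s,
    100 * pm$mean_correct_post))
  invisible(x)
}

#' Peak and post-onset summary metrics of a decoding result
#'
#' @param result a `decoding_result`.
#' @param post_window window (s) for the mean fraction of correctly
#'   classified samples after error onset.
#' @return list with `peak_accuracy`, `peak_time_s` and
#'   `mean_correct_post`.
#' @export
peak_metrics <- function(result, post_window = c(0, 1)) {
  i <- which.max(result$accuracy)
  post <- result$times >= post_window[1] & result$times <= post_window[2]
  list(peak_accuracy = result$accuracy[i],
       peak_time_s = result$times[i],
       mean_correct_post = mean(result$accuracy[post]))
}

#' Generic (leave-one-participant-out) pupil decoding
#'
#' For each held-out participant, trains one decoder per evaluation
#' position on the pooled, per-participant-balanced trials of all other
#' participants and evaluates it on the held-out participant's balanced
#' trials.
#'
#' @param epoch_sets list (length >= 3) of per-participant
#'   [epoch_set()]s at the decoding rate (single pupil channel).
#' @param window_samples window length in samples.
#' @param seed RNG seed for the per-participant balancing.
#' @return list of per-participant `decoding_result`-like objects
#'   (`times`, `accuracy`).
#' @export
generic_decode <- function(epoch_sets, window_samples, seed = 1L) {
  stopifnot(length(epoch_sets) >= 3)
  balanced <- lapply(seq_along(epoch_sets), function(i)
    balance_classes(epoch_sets[[i]], seed = as.integer(seed) + i))
  nsamp <- dim(balanced[[1]]$data)[3]
  positions <- seq(window_samples, nsamp)
  lapply(seq_along(balanced), function(held) {
    pool <- balanced[-held]
    dat <- do.call(abind3, lapply(pool, `[[`, "data"))
    labs <- factor(unlist(lapply(pool, function(e) as.character(e$labels))),
                   levels = condition_levels())
    train <- epoch_set(dat, labs, balanced[[held]]$t_axis,
                       balanced[[held]]$fs,
                       channel_names = balanced[[held]]$channel_names)
    test <- balanced[[held]]
    acc <- vapply(positions, function(pos) {
      dec <- train_window_decoder(train, train$channel_names,
                                  window_samples, pos)
      mean(predict(dec, test) == test$labels[test$kept])
    }, numeric(1))
    structure(list(times = test$t_axis[positions], accuracy = acc,
                   classes = levels(droplevels(labs))),
              class = "decoding_result")
  })
}

# rbind 3-d arrays along the first (trial) dimension.
abind3 <- function(...) {
  args <- list(...)
  d <- dim(args[[1]])
  out <- array(0, c(sum(vapply(args, function(a) dim(a)[1], numeric(1))),
                    d[2], d[3]))
  at <- 0
  for (a in args) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  dimnames(out)[[2]] <- dimnames(args[[1]])[[2]]
  out
}
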