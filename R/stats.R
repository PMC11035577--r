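# Significance statistics: cumulative-binomial chance thresholds,
# paired signed-rank comparisons of peak physiological responses,
# sample-wise decoder comparisons, and Friedman/Nemenyi group tests,
# all with Benjamini-Hochberg FDR correction.

#' Binomial chance-level accuracy threshold
#'
#' Smallest accuracy `k/n` such that the upper-tail probability of `k` or
#' more correct predictions out of `n` under random guessing with `1/c`
#' success probability is at most `alpha`. The upper tail is the standard
#' cumulative binomial `sum_{i=k}^{n} choose(n,i) (1/c)^i ((c-1)/c)^(n-i)`
#' (note the `n - i` exponent; the commonly printed `n - 1` variant does
#' not form a probability distribution).
#'
#' @param n number of test trials.
#' @param classes number of conditions (default 4).
#' @param alpha significance level (default 0.05).
#' @return threshold accuracy in \[0, 1\].
#' @export
binomial_threshold <- function(n, classes = 4, alpha = 0.05) {
  stopifnot(n >= 1, alpha > 0, alpha < 1, classes >= 2)
  # smallest k with P(X >= k) <= alpha, X ~ Bin(n, 1/classes)
  k <- stats::qbinom(1 - alpha, n, 1 / classes) + 1L
  while (k > 0 &&
         stats::pbinom(k - 2, n, 1 / classes, lower.tail = FALSE) <= alpha)
    k <- k - 1L
  k / n
}

#' Cohort-average significance threshold
#'
#' @param n_per_participant vector of per-participant trial counts.
#' @param classes,alpha as in [binomial_threshold()].
#' @return mean of the per-participant thresholds.
#' @export
average_binomial_threshold <- function(n_per_participant, classes = 4,
                                       alpha = 0.05) {
  mean(vapply(n_per_participant, binomial_threshold, numeric(1),
              classes = classes, alpha = alpha))
}

# Extremum of the trial-average trace of one condition within a window.
condition_peak <- function(epochs, cond, window, mode) {
  idx <- which(epochs$t_axis >= window[1] - 1e-9 & epochs$t_axis <= window[2] + 1e-9)
  tr <- which(epochs$kept & epochs$labels == cond)
  if (!length(tr)) return(NA_real_)
  avg <- apply(epochs$data[tr, 1, , drop = FALSE], 3, mean)
  if (mode == "max") max(avg[idx]) else min(avg[idx])
}

#' Paired tests of peak error-related responses vs. correct
#'
#' For each error condition, compares the per-participant peak response
#' against the correct-condition extremum in the same window with a
#' paired Wilcoxon signed-rank test, then FDR-corrects across the three
#' conditions. Pupil responses use the dilation maximum in
#' \[0.5, 0.8\] s; heart rate uses the deceleration minimum in
#' \[0.7, 1.7\] s.
#'
#' @param pupil_sets list of per-participant pupil [epoch_set()]s (or
#'   NULL to skip).
#' @param hr_sets list of per-participant HR [epoch_set()]s (or NULL).
#' @param pupil_window,hr_window search windows (s).
#' @param alpha FDR level.
#' @return data.frame (`modality`, `condition`, `statistic`, `p_raw`,
#'   `p_fdr`, `significant`); FDR applied within modality.
#' @export
peak_response_tests <- function(pupil_sets = NULL, hr_sets = NULL,
                                pupil_window = c(0.5, 0.8),
                                hr_window = c(0.7, 1.7), alpha = 0.05) {
  one_modality <- function(sets, window, mode, modality) {
    conds <- c("target", "passive", "active")
    peaks <- sapply(c(conds, "correct"), function(cond)
      vapply(sets, condition_peak, numeric(1), cond = cond,
             window = window, mode = mode))
    rows <- lapply(conds, function(cond) {
      w <- signed_rank_test(peaks[, cond], peaks[, "correct"])
      data.frame(modality = modality, condition = cond,
                 statistic = unname(w$statistic), p_raw = w$p.value)
    })
    do.call(rbind, rows)
  }
  out <- NULL
  if (!is.null(pupil_sets))
    out <- rbind(out, one_modality(pupil_sets, pupil_window, "max", "pupil"))
  if (!is.null(hr_sets))
    out <- rbind(out, one_modality(hr_sets, hr_window, "min", "hr"))
  out$p_fdr <- stats::ave(out$p_raw, out$modality,
                          FUN = function(p) stats::p.adjust(p, "BH"))
  out$significant <- out$p_fdr < alpha
  out
}

# Paired Wilcoxon signed-rank test; exact null for small samples, normal
# approximation above n = 25 (or with ties/zeros).
signed_rank_test <- function(x, y) {
  n <- sum(!is.na(x) & !is.na(y))
  suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                      exact = n <= 25))
}

#' Sample-wise comparison of two decoders
#'
#' Paired signed-rank test per evaluation time between two accuracy
#' traces across participants, FDR-corrected across times.
#'
#' @param acc_a,acc_b participants-by-times accuracy matrices (same
#'   shape).
#' @param times evaluation times (s).
#' @param alpha FDR level.
#' @return data.frame (`time_s`, `statistic`, `p_raw`, `p_fdr`,
#'   `significant`).
#' @export
samplewise_decoder_test <- function(acc_a, acc_b, times, alpha = 0.05) {
  stopifnot(identical(dim(acc_a), dim(acc_b)),
            ncol(acc_a) == length(times))
  res <- lapply(seq_along(times), function(j) {
    if (isTRUE(all.equal(acc_a[, j], acc_b[, j])))
      return(data.frame(time_s = times[j], statistic = 0, p_raw = 1))
    w <- signed_rank_test(acc_a[, j], acc_b[, j])
    data.frame(time_s = times[j], statistic = unname(w$statistic),
               p_raw = w$p.value)
  })
  out <- do.call(rbind, res)
  out$p_fdr <- stats::p.adjust(out$p_raw, "BH")
  out$significant <- out$p_fdr < alpha
  out
}

#' Nemenyi post-hoc test
#'
#' All-pairs comparison of methods after a significant Friedman test:
#' methods are ranked within participants; the pairwise p-value uses the
#' studentized-range distribution of the mean-rank differences.
#'
#' @param x participants-by-methods matrix.
#' @return matrix of pairwise p-values (upper storage, symmetric).
#' @export
nemenyi_test <- function(x) {
  n <- nrow(x); k <- ncol(x)
  R <- colMeans(t(apply(x, 1, rank)))
  se <- sqrt(k * (k + 1) / (6 * n))
  p <- matrix(NA_real_, k, k, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    q <- abs(R[i] - R[j]) / se * sqrt(2)
    p[i, j] <- p[j, i] <- stats::ptukey(q, k, Inf, lower.tail = FALSE)
  }
  p
}

#' Friedman omnibus tests with gated Nemenyi post-hocs
#'
#' One Friedman test per metric column group (e.g. per window length)
#' across methods, FDR-corrected; Nemenyi post-hoc comparisons are run
#' only where the corrected omnibus p-value is below `alpha`.
#'
#' @param metric_list named list of participants-by-methods matrices
#'   (one per window length / metric).
#' @param alpha significance level.
#' @return list with `omnibus` (data.frame `group`, `chisq`, `p_raw`,
#'   `p_fdr`, `significant`) and `posthoc` (named list of Nemenyi
#'   p-value matrices for significant groups).
#' @export
compare_decoders <- function(metric_list, alpha = 0.05) {
  stopifnot(length(metric_list) >= 1)
  om <- lapply(names(metric_list), function(nm) {
    x <- metric_list[[nm]]
    if (all(apply(x, 1, function(r) length(unique(r)) == 1)))
      return(data.frame(group = nm, chisq = 0, p_raw = 1))
    ft <- stats::friedman.test(as.matrix(x))
    data.frame(group = nm, chisq = unname(ft$statistic),
               p_raw = ft$p.value)
  })
  omnibus <- do.call(rbind, om)
  omnibus$p_fdr <- stats::p.adjust(omnibus$p_raw, "BH")
  omnibus$significant <- omnibus$p_fdr < alpha
  posthoc <- list()
  for (i in which(omnibus$significant))
    posthoc[[omnibus$group[i]]] <- nemenyi_test(metric_list[[i]])
  list(omnibus = omnibus, posthoc = posthoc)
}
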