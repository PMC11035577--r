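# Sliding-window sLDA decoding: balancing, folds, features, training,
# chance level and information timing.

test_that("class balancing subsamples correct trials to the error mean", {
  set.seed(61)
  counts <- c(target = 52, passive = 55, active = 49, correct = 300)
  labs <- rep(names(counts), counts)
  dat <- array(rnorm(sum(counts) * 1 * 8), c(sum(counts), 1, 8))
  ep <- epoch_set(dat, labs, seq(-0.5, by = 1 / 32, length.out = 8), 32,
                  channel_names = "FCz")
  bal <- balance_classes(ep, seed = 1)
  tab <- table(bal$labels)
  expect_equal(as.integer(tab["correct"]), 52L)  # round(mean(52,55,49))
  expect_equal(as.integer(tab[c("target", "passive", "active")]),
               c(52L, 55L, 49L))
  expect_identical(balance_classes(ep, seed = 1)$event_id, bal$event_id)
  # fewer correct than the target: keep all, warn
  few <- subset_trials(ep, c(1:156, 157:186))
  expect_warning(b2 <- balance_classes(few, seed = 1), "keeping all")
  expect_equal(sum(b2$labels == "correct"), 30)
})

test_that("fold plans are stratified partitions", {
  labs <- factor(rep(condition_levels(), times = c(12, 11, 13, 12)))
  plan <- make_folds(labs, reps = 10, k = 5, seed = 3)
  expect_equal(dim(plan), c(48L, 10L))
  for (r in 1:10) {
    expect_setequal(unique(plan[, r]), 1:5)
    # stratification: per-fold class counts within one of the ideal share
    for (cl in condition_levels()) {
      per_fold <- table(factor(plan[labs == cl, r], levels = 1:5))
      expect_lte(max(per_fold) - min(per_fold), 1)
    }
  }
  expect_identical(plan, make_folds(labs, 10, 5, seed = 3))
  expect_error(make_folds(factor(rep("target", 3),
                                 levels = condition_levels()),
                          k = 5), "at least")
})

test_that("window features have C x W columns and positions respect bounds", {
  ep <- toy_epochs(n_per = 8, channels = paste0("ch", 1:58))
  X <- errpfusion:::window_features(ep, paste0("ch", 1:58), 16, 48, 1:32)
  expect_equal(dim(X), c(32L, 928L))    # 58 channels x 16 samples
  expect_error(errpfusion:::window_features(ep, "ch1", 16, 10, 1:32),
               "does not fit")
})

test_that("perfectly separated classes are classified perfectly", {
  ep <- toy_epochs(n_per = 12, effect = 50, noise = 0.01, seed = 2)
  dec <- train_window_decoder(ep, "FCz", 8, 35)
  pred <- predict(dec, ep)
  expect_equal(mean(pred == ep$labels), 1)
  # duplicated features do not enlarge the projection basis
  ep2 <- ep
  dat2 <- array(0, c(dim(ep$data)[1], 2, dim(ep$data)[3]))
  dat2[, 1, ] <- ep$data[, 1, ]
  dat2[, 2, ] <- ep$data[, 1, ]
  ep2 <- epoch_set(dat2, ep$labels, ep$t_axis, 32,
                   channel_names = c("FCz", "dup"))
  dec2 <- train_window_decoder(ep2, c("FCz", "dup"), 8, 35)
  expect_equal(ncol(dec2$basis), ncol(dec$basis))
})

test_that("permuted labels decode at chance (0.25)", {
  set.seed(71)
  ep <- toy_epochs(n_per = 25, effect = 2, seed = 7)
  perm <- epoch_set(ep$data, sample(as.character(ep$labels)), ep$t_axis,
                    32, channel_names = "FCz")
  res <- decode_sliding(perm, "FCz", 8, reps = 2, k = 5, seed = 7)
  # binomial noise on the mean over positions and folds
  expect_lt(abs(mean(res$accuracy) - 0.25), 0.05)
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 1))
})

test_that("evaluation grid steps one sample (31.25 ms) and confusions add up", {
  ep <- toy_epochs(n_per = 10, effect = 3, seed = 8)
  res <- decode_sliding(ep, "FCz", 8, reps = 2, k = 5, seed = 8)
  expect_equal(length(res$times), 48 - 8 + 1)
  expect_equal(unique(round(diff(res$times), 6)), 0.03125)
  # per-position confusion rows sum to (trials per class) x reps
  rs <- apply(res$confusion, c(1, 3), sum)
  expect_true(all(rs == 10 * 2))
  pm <- peak_metrics(res)
  expect_gte(pm$peak_accuracy, max(res$accuracy) - 1e-12)
  # constant trace: peak equals mean
  fake <- res
  fake$accuracy[] <- 0.25
  pmf <- peak_metrics(fake)
  expect_equal(pmf$peak_accuracy, 0.25)
  expect_equal(pmf$mean_correct_post, 0.25)
})

test_that("an injected deflection is decoded at or after its onset", {
  ep <- toy_epochs(n_per = 25, effect = 3, at = 0.3, seed = 9)
  res <- decode_sliding(ep, "FCz", 8, reps = 2, k = 5, seed = 9)
  pm <- peak_metrics(res)
  expect_gte(pm$peak_time_s, 0.3)   # causal window labelling
  expect_gt(pm$peak_accuracy, 0.5)
})

test_that("generic decoding transfers between statistically identical participants", {
  sets <- lapply(1:3, function(s)
    toy_epochs(n_per = 20, channels = "pupil", effect = 2, seed = 100 + s))
  res <- generic_decode(sets, window_samples = 8, seed = 1)
  expect_equal(length(res), 3)
  for (r in res) expect_gt(max(r$accuracy), 0.4)
  # polarity flipped in one participant: its transfer accuracy collapses
  flip <- sets
  flip[[3]]$data <- -flip[[3]]$data
  res2 <- generic_decode(flip, window_samples = 8, seed = 1)
  expect_lt(max(res2[[3]]$accuracy), max(res[[3]]$accuracy))
})
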