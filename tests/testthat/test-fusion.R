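# Simple and Bayesian fusion.

test_that("simple fusion appends the pupil as one extra channel", {
  eeg <- toy_epochs(n_per = 10, channels = "FCz", effect = 1, seed = 1)
  pup <- toy_epochs(n_per = 10, channels = "pupil", effect = 1, seed = 2)
  fused <- simple_fusion_features(eeg, pup)
  expect_equal(dim(fused$data)[2], 2L)
  expect_equal(fused$channel_names, c("FCz", "pupil"))
  expect_equal(fused$data[, 2, ], pup$data[, 1, ])
  # intersection by event identity after disjoint rejections
  eeg$kept[1:5] <- FALSE
  pup$kept[6:10] <- FALSE
  fused2 <- simple_fusion_features(eeg, pup)
  expect_equal(dim(fused2$data)[1], 30L)
  pup$kept[] <- FALSE
  expect_error(simple_fusion_features(eeg, pup), "no common trials")
})

test_that("standardization gives the pupil channel unit variance in features", {
  eeg <- toy_epochs(n_per = 10, channels = "FCz", seed = 3)
  pup <- toy_epochs(n_per = 10, channels = "pupil", seed = 4)
  pup$data <- pup$data * 1000   # wildly different scale
  fused <- simple_fusion_features(eeg, pup)
  dec <- train_window_decoder(fused, c("FCz", "pupil"), 4, 20)
  X <- errpfusion:::window_features(fused, c("FCz", "pupil"), 4, 20,
                                    seq_len(40))
  Xs <- sweep(sweep(X, 2, dec$mu), 2, dec$sd, "/")
  expect_equal(unname(apply(Xs, 2, stats::sd)), rep(1, 8),
               tolerance = 1e-9)
})

test_that("belief fusion reproduces the hand-computed example", {
  C1 <- matrix(c(8, 2, 2, 8), 2, byrow = TRUE)
  C2 <- matrix(c(6, 4, 4, 6), 2, byrow = TRUE)
  f <- bayes_fuse(c(1, 2), list(C1, C2), smoothing = 0)
  expect_equal(as.integer(f), 1L)   # O ~ (.5*.8*.4, .5*.2*.6)
  expect_equal(attr(f, "belief"), c(0.16, 0.06) / 0.22, tolerance = 1e-12)
  # identity confusions + agreement return the unanimous class
  I4 <- diag(4) * 10
  for (cl in 1:4)
    expect_equal(as.integer(bayes_fuse(c(cl, cl), list(I4, I4),
                                       smoothing = 0)), cl)
  # K = 1 reduces to the argmax of the predicted column's conditional
  C <- matrix(c(5, 1, 2, 9), 2, byrow = TRUE)
  expect_equal(as.integer(bayes_fuse(2, list(C), smoothing = 0)), 2L)
})

test_that("belief fusion matches brute-force evaluation on random instances", {
  set.seed(77)
  for (rep in 1:20) {
    M <- 4
    conf <- list(matrix(rpois(M * M, 3), M),
                 matrix(rpois(M * M, 3), M))
    priors <- as.vector(stats::runif(M)); priors <- priors / sum(priors)
    for (e1 in 1:M) for (e2 in 1:M) {
      got <- bayes_fuse(c(e1, e2), conf, priors = priors, smoothing = 1)
      O <- brute_force_belief(c(e1, e2), conf, priors, smoothing = 1)
      expect_equal(as.integer(got), which.max(O))
      expect_equal(attr(got, "belief"), O / sum(O), tolerance = 1e-12)
    }
  }
})

test_that("fused outputs are invariant to count scaling (before smoothing)", {
  set.seed(78)
  conf <- list(matrix(rpois(16, 5) + 1, 4), matrix(rpois(16, 5) + 1, 4))
  scaled <- list(conf[[1]] * 7, conf[[2]])
  for (e1 in 1:4) for (e2 in 1:4)
    expect_equal(as.integer(bayes_fuse(c(e1, e2), conf, smoothing = 0)),
                 as.integer(bayes_fuse(c(e1, e2), scaled, smoothing = 0)))
})

test_that("Bayesian fusion of two decoders beats the weaker one", {
  eeg <- toy_epochs(n_per = 15, channels = "FCz", effect = 0, seed = 11)
  pup <- toy_epochs(n_per = 15, channels = "pupil", effect = 3, at = 0.6,
                    seed = 12)
  plan <- make_folds(eeg$labels, reps = 2, k = 5, seed = 1)
  re <- decode_sliding(eeg, "FCz", 8, fold_plan = plan, collect = TRUE)
  rp <- decode_sliding(pup, "pupil", 8, fold_plan = plan, collect = TRUE)
  bf <- bayes_fuse_results(re, rp)
  late <- bf$times > 0.5
  expect_gt(mean(bf$accuracy[late]), mean(re$accuracy[late]) + 0.1)
  # training-set confusion rows sum to the training per-class counts
  r <- 1; fold <- 1; pos <- 10
  n_train <- sum(plan[, r] != fold)
  expect_equal(sum(re$train_confusion[, , pos, fold, r]), n_train)
})
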