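# EEG preprocessing: ocular model recovery, channel selection, epoching,
# artifact rejection, bad-channel interpolation, grand averages.

make_calib <- function(cfg) synth_eye_calibration(cfg)

test_that("ocular model recovers the injected mixing exactly without noise", {
  cfg <- noise_free_config(seed = 21,
                           ocular_gain = default_ocular_gain(),
                           blink_rate_hz = 0.4)
  cal <- make_calib(cfg)
  m <- fit_ocular_model(cal)
  expect_equal(unname(m$weights), unname(cfg$ocular_gain),
               tolerance = 1e-8)
  # subtraction removes essentially all ocular power on a fresh session
  ev <- simulate_paradigm(1, seed = 22)
  cfg2 <- modify_config(cfg, seed = 22,
                        erp_components = lapply(cfg$erp_components,
                                                function(tab) {
                                                  tab$amplitude_uV <- 0
                                                  tab
                                                }))
  st <- synth_pupil(ev, cfg2)
  eeg <- synth_eeg(ev, cfg2, st)       # pure ocular contamination
  clean <- remove_ocular(eeg, m, st)
  expect_lt(mean(clean$data["Fp1", ]^2) / mean(eeg$data["Fp1", ]^2), 0.01)
})

test_that("zero ocular model is the identity and quiet segments stay put", {
  cfg <- noise_free_config(seed = 23)
  ev <- simulate_paradigm(1, seed = 23)
  st <- synth_pupil(ev, cfg)
  eeg <- synth_eeg(ev, cfg, st)
  m <- structure(list(weights = matrix(0, 63, 3,
                                       dimnames = list(eeg_montage(),
                                                       c("gaze_h", "gaze_v",
                                                         "blink"))),
                      fs = cfg$fs_eeg), class = "ocular_model")
  out <- remove_ocular(eeg, m, st)
  expect_equal(out$data, eeg$data)
})

test_that("channel selection leaves 58 channels at 64 Hz", {
  eeg <- continuous_eeg(matrix(rnorm(63 * 5120), 63,
                               dimnames = list(eeg_montage(), NULL)),
                        512, eeg_montage())
  out <- narrowband_resample_select(eeg)
  expect_equal(nrow(out$data), 58)
  expect_equal(out$fs, 64)
  expect_false(any(frontal_drop_channels() %in% out$channel_names))
  # unknown montage: warn and pass through the drop step
  small <- continuous_eeg(matrix(rnorm(2 * 5120), 2,
                                 dimnames = list(c("A1", "A2"), NULL)),
                          512, c("A1", "A2"))
  expect_warning(out2 <- narrowband_resample_select(small), "not present")
  expect_equal(nrow(out2$data), 2)
})

test_that("epoching yields 96-sample trials and skips boundary events", {
  cfg <- noise_free_config(seed = 24)
  ev <- simulate_paradigm(1, seed = 24)
  eeg <- synth_eeg(ev, cfg)
  nb <- narrowband_resample_select(filter_raw(eeg))
  epo <- epoch_trials(nb, ev)
  expect_equal(dim(epo$data)[3], 96)    # 1.5 s x 64 Hz
  expect_equal(length(epo$t_axis), 96)
  expect_equal(dim(epo$data)[1], 70)
  # an event before the epoch start is skipped and logged
  ev2 <- ev
  ev2$onset_s[1] <- 0.2
  epo2 <- epoch_trials(nb, ev2)
  expect_equal(dim(epo2$data)[1], 69)
  expect_equal(epo2$rejection_log$reason, "outside recording")
})

test_that("amplitude spikes are rejected with the right reason; clean data mostly kept", {
  set.seed(31)
  n <- 60
  dat <- array(rnorm(n * 4 * 96, sd = 5), c(n, 4, 96))
  labs <- rep(condition_levels(), length.out = n)
  epo <- epoch_set(dat, labs, seq(-0.5, by = 1 / 64, length.out = 96), 64,
                   channel_names = c("FCz", "Cz", "Pz", "Oz"))
  epo$data[7, 2, 40] <- 50              # 50 uV spike
  out <- reject_artifacts(epo)
  expect_false(out$kept[7])
  expect_true("amplitude" %in%
                out$rejection_log$reason[out$rejection_log$trial == 7])
  # clean Gaussian data: < 5% rejected by the 5-SD rules
  out2 <- reject_artifacts(epoch_set(array(rnorm(100 * 4 * 96, sd = 5),
                                           c(100, 4, 96)),
                                     rep(condition_levels(), 25),
                                     epo$t_axis, 64,
                                     channel_names = c("FCz", "Cz", "Pz",
                                                       "Oz")))
  expect_lt(mean(!out2$kept), 0.05)
  expect_error(reject_artifacts(subset_trials(epo, 1:5)), "at least")
})

test_that("a noisy channel is flagged and its interpolation beats the corruption", {
  cfg <- noise_free_config(seed = 25)
  ev <- simulate_paradigm(1, seed = 25)
  eeg <- synth_eeg(ev, cfg)
  nb <- narrowband_resample_select(filter_raw(eeg))
  epo <- epoch_trials(nb, ev)
  truth <- epo$data[, match("C1", epo$channel_names), ]
  set.seed(25)
  corrupted <- truth + rnorm(length(truth), sd = 10 * stats::sd(truth) + 1)
  epo$data[, match("C1", epo$channel_names), ] <- corrupted
  out <- interpolate_bad_channels(epo)
  expect_true("C1" %in% attr(out, "interpolated"))
  rebuilt <- out$data[, match("C1", out$channel_names), ]
  err <- which(epo$labels != "correct")
  expect_gt(stats::cor(as.vector(rebuilt[err, ]), as.vector(truth[err, ])),
            stats::cor(as.vector(corrupted[err, ]), as.vector(truth[err, ])))
  # equal variances: nothing flagged
  flat <- epoch_set(array(rep(rnorm(96), each = 40 * 4), c(40, 4, 96)),
                    rep(condition_levels(), 10), epo$t_axis, 64,
                    channel_names = c("FCz", "Cz", "Pz", "Oz"))
  out2 <- interpolate_bad_channels(flat)
  expect_equal(length(attr(out2, "interpolated")), 0)
})

test_that("grand averages: single trial identity and zero SEM for clones", {
  set.seed(33)
  dat <- array(rnorm(4 * 3 * 96), c(4, 3, 96))
  labs <- c("target", "passive", "active", "correct")
  es <- epoch_set(dat, labs, seq(-0.5, by = 1 / 64, length.out = 96), 64,
                  channel_names = c("FCz", "Cz", "Pz"))
  ga <- grand_average_erp(list(es), conditions = "target")
  reref <- sweep(dat[1, , ], 2, colMeans(dat[1, , ]))
  expect_equal(unname(ga$target$mean), reref, tolerance = 1e-12)
  ga2 <- grand_average_erp(list(es, es, es), conditions = "target")
  expect_lt(max(abs(ga2$target$sem)), 1e-12)
  es2 <- es
  es2$t_axis <- es2$t_axis + 1
  expect_error(grand_average_erp(list(es, es2)), "mismatched")
})

test_that("full noise-free chain preserves injected component latencies", {
  cfg <- noise_free_config(n_runs = 2, seed = 26)
  ev <- simulate_paradigm(2, seed = 26)
  epo <- epoch_trials(narrowband_resample_select(filter_raw(
    synth_eeg(ev, cfg))), ev)
  ga <- grand_average_erp(list(epo))
  one_sample <- 1 / 64
  ern <- peak_latency(ga$target$mean["FCz", ], ga$t_axis, c(0.18, 0.30),
                      "min")
  expect_lte(abs(ern$latency_s - 0.234), one_sample + 1e-9)
  pe <- peak_latency(ga$target$mean["FCz", ], ga$t_axis, c(0.25, 0.45),
                     "max")
  expect_lte(abs(pe$latency_s - 0.313), one_sample + 1e-9)
  # the active-condition components are delayed relative to passive
  ern_p <- peak_latency(ga$passive$mean["FCz", ], ga$t_axis, c(0.2, 0.32),
                        "min")
  ern_a <- peak_latency(ga$active$mean["FCz", ], ga$t_axis, c(0.2, 0.32),
                        "min")
  expect_gte(ern_a$latency_s, ern_p$latency_s)
})
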