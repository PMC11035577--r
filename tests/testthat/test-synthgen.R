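# Paradigm generator: schedule invariants, determinism, linearity of the
# generated EEG, and recoverability of injected parameters.

test_that("one run schedules 70 targets with 21 errors (7 per type)", {
  ev <- simulate_paradigm(1, seed = 7)
  expect_equal(nrow(ev), 70)
  expect_equal(as.integer(table(ev$condition)[c("target", "passive",
                                                "active", "correct")]),
               c(7L, 7L, 7L, 49L))
  # error timing relative to the projected pass
  lead <- ev$pass_s - ev$onset_s
  expect_true(all(abs(lead[ev$condition == "target"] - 1.6) < 1e-9))
  pa <- ev$condition %in% c("passive", "active")
  expect_true(all(lead[pa] >= 1.1 & lead[pa] <= 1.8))
  expect_true(all(lead[ev$condition == "correct"] == 0))
  # ~4 s target spacing
  expect_true(all(abs(diff(ev$pass_s) - 4) <= 0.4 + 1e-9))
})

test_that("schedule counts hold for every run and seed; seeds reproduce", {
  ev <- simulate_paradigm(3, seed = 42)
  expect_equal(sum(ev$condition != "correct"), 3 * 21)
  for (r in 1:3) {
    tab <- table(ev$condition[ev$run_index == r])
    expect_equal(as.integer(tab[c("target", "passive", "active",
                                  "correct")]),
                 c(7L, 7L, 7L, 49L))
  }
  expect_identical(ev, simulate_paradigm(3, seed = 42))
  expect_false(identical(ev$onset_s, simulate_paradigm(3, seed = 43)$onset_s))
  expect_error(simulate_paradigm(0), "positive")
})

test_that("noise-free EEG equals the component kernels exactly at FCz", {
  cfg <- noise_free_config(seed = 5)
  ev <- simulate_paradigm(1, seed = 5)
  eeg <- synth_eeg(ev, cfg)
  fs <- cfg$fs_eeg
  tgt <- ev[ev$condition == "target", ][1, ]
  # sample exactly on the kernel's own grid (placed at the rounded onset;
  # the kernel time base starts 0.1 s before onset, which is not an
  # integer number of samples, so evaluate at the kernel's actual times)
  i0 <- round((tgt$onset_s - 0.1) * fs) + 1L
  j <- round((seq(0, 0.8, by = 1 / fs) + 0.1) * fs)
  idx <- i0 + j
  tt <- -0.1 + j / fs
  comp <- cfg$erp_components$target
  # FCz gain is 1 for FCz-centred components, < 1 for Cz-centred ones
  pos <- electrode_positions(eeg_montage())
  xyz <- as.matrix(pos[, c("x", "y", "z")])
  gain_at <- function(center) {
    arc <- acos(pmin(1, sum(xyz[match("FCz", pos$label), ] *
                              xyz[match(center, pos$label), ])))
    exp(-arc^2 / (2 * cfg$topo_sd_rad^2))
  }
  expected <- rowSums(sapply(seq_len(nrow(comp)), function(i)
    gain_at(comp$center[i]) * comp$amplitude_uV[i] *
      exp(-(tt - comp$latency_s[i])^2 / (2 * comp$width_s[i]^2))))
  expect_lt(max(abs(eeg$data["FCz", idx] - expected)), 1e-6)
  # correct trials carry no event-locked signal
  corr <- ev[ev$condition == "correct", ][3, ]
  cidx <- round((corr$prev_target_pass_s + 1.5) * fs):
    (round((corr$prev_target_pass_s + 1.5) * fs) + 100)
  expect_lt(max(abs(eeg$data["FCz", cidx])), 1e-6)
})

test_that("generated EEG is linear in its component amplitudes", {
  cfg <- noise_free_config(seed = 6)
  cfg2 <- cfg
  cfg2$erp_components <- lapply(cfg$erp_components, function(tab) {
    tab$amplitude_uV[tab$name == "Pe"] <- 2 * tab$amplitude_uV[tab$name == "Pe"]
    tab
  })
  ev <- simulate_paradigm(1, seed = 6)
  e1 <- synth_eeg(ev, cfg)$data
  e2 <- synth_eeg(ev, cfg2)$data
  diffsig <- e2 - e1
  # the difference is exactly one extra Pe kernel per error event
  pe <- cfg$erp_components$target
  pe <- pe[pe$name == "Pe", ]
  tgt <- ev[ev$condition == "target", ][1, ]
  i0 <- round((tgt$onset_s + pe$latency_s) * cfg$fs_eeg) + 1L
  # peak sampled up to half a sample off-centre
  expect_equal(max(diffsig["Cz", (i0 - 10):(i0 + 10)]),
               pe$amplitude_uV, tolerance = 1e-3)
  # and zero away from events
  gap <- round((ev$pass_s[1] + 2.2) * cfg$fs_eeg)
  expect_lt(max(abs(diffsig[, gap:(gap + 50)])), 1e-9)
})

test_that("generator output is bit-identical under a fixed seed", {
  cfg <- generator_config(n_runs = 1, seed = 11)
  ev <- simulate_paradigm(1, seed = 11)
  expect_identical(synth_pupil(ev, cfg), synth_pupil(ev, cfg))
  expect_identical(synth_rr(ev, cfg), synth_rr(ev, cfg))
})

test_that("RR series reduces to a constant without modulation", {
  cfg <- noise_free_config(seed = 2, rsa_amp_s = 0,
                           hr_decel = list(magnitude_bpm = 0,
                                           latency_s = 1.1, width_s = 0.35,
                                           condition_scale = c(target = 1,
                                                               passive = 1,
                                                               active = 1)))
  ev <- simulate_paradigm(1, seed = 2)
  rr <- synth_rr(ev, cfg)
  expect_true(all(abs(rr$rr_s - cfg$rr_base_s) < 1e-12))
  he <- epoch_hr(rr_to_hr(rr), ev)
  expect_lt(max(abs(he$data)), 1e-9)
  expect_error(synth_rr(ev, modify_config(cfg, rr_base_s = -1)),
               "positive")
})

test_that("injected HR deceleration is recovered from the epochs", {
  # respiratory modulation off: this checks the kernel in isolation
  cfg <- noise_free_config(n_runs = 4, seed = 3, rsa_amp_s = 0)
  ev <- simulate_paradigm(4, seed = 3)
  rr <- synth_rr(ev, cfg)
  he <- epoch_hr(rr_to_hr(rr), ev)
  dec <- peak_deceleration(he)
  hd <- cfg$hr_decel
  for (cond in c("target", "passive", "active")) {
    injected <- -hd$magnitude_bpm * unname(hd$condition_scale[cond])
    # heart rate is only observed at beat times (~1.25 Hz) and linearly
    # interpolated, which attenuates a 0.45 s kernel by up to ~25%
    expect_lt(abs(dec[[cond]] - injected), 0.3 * abs(injected))
    # minimum of the window-restricted average sits at the kernel latency
    tr <- which(he$labels == cond)
    avg <- apply(he$data[tr, 1, , drop = FALSE], 3, mean)
    win <- which(he$t_axis >= 0.5 & he$t_axis <= 2)
    tmin <- he$t_axis[win][which.min(avg[win])]
    expect_lt(abs(tmin - hd$latency_s), 0.5)
  }
  # ordering follows the injected per-condition scaling
  expect_lt(dec[["passive"]], dec[["active"]])
  expect_lt(dec[["active"]], dec[["target"]])
  # correct trials are far shallower than error trials
  expect_gt(dec[["correct"]], dec[["passive"]] + 0.5)
})

test_that("blink-free configuration yields all-valid pupil samples", {
  cfg <- noise_free_config(seed = 4)
  ev <- simulate_paradigm(1, seed = 4)
  st <- synth_pupil(ev, cfg)
  expect_true(all(st$valid_left) && all(st$valid_right))
  expect_false(anyNA(st$pupil_left_mm))
})

test_that("eye-calibration segments partition the recording and sweep angles", {
  cfg <- generator_config(seed = 9)
  cal <- synth_eye_calibration(cfg)
  seg <- cal$segments
  expect_equal(seg$start_s[-1], seg$end_s[-nrow(seg)])
  expect_equal(seg$start_s[1], 0)
  dur <- nrow(cal$stream) / cfg$fs_gaze
  expect_equal(seg$end_s[nrow(seg)], dur, tolerance = 0.1)
  hseg <- seg[seg$kind == "horizontal", ]
  sel <- cal$stream$t_s >= hseg$start_s & cal$stream$t_s < hseg$end_s
  expect_gte(length(unique(round(cal$stream$gaze_h_deg[sel]))), 4)
})
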