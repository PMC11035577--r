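# Pupil preprocessing: blink interpolation, resampling/filtering,
# foreshortening fit/correction, epoching with baselines.

test_that("blink gaps are filled linearly with bounded error", {
  t <- seq(0, 10, by = 1 / 120)
  f <- 1.0
  x <- sin(2 * pi * f * t)
  valid <- rep(TRUE, length(t))
  gap <- t > 5 & t < 5.25            # 250 ms blink
  valid[gap] <- FALSE
  st <- gaze_pupil_stream(t, 0 * t, 0 * t, x, x, valid, valid, 120)
  st$pupil_left_mm[gap] <- NA
  out <- interpolate_blinks(st)
  expect_false(anyNA(out$pupil_left_mm))
  # Taylor bound for linear interpolation over a gap of length g:
  # max error <= max|x''| (g/2)^2 / 2
  g <- 0.25 + 2 / 120
  bound <- (2 * pi * f)^2 * (g / 2)^2 / 2
  expect_lte(max(abs(out$pupil_left_mm[gap] - x[gap])), bound)
  # equal flanking values are filled with that value
  st2 <- st
  st2$pupil_left_mm[] <- 3.3
  st2$pupil_left_mm[gap] <- NA
  out2 <- interpolate_blinks(st2)
  expect_true(all(out2$pupil_left_mm == 3.3))
  st3 <- st
  st3$valid_left[] <- FALSE
  expect_error(interpolate_blinks(st3), "entirely invalid")
})

test_that("pupil resampling/filtering meets rate and band contracts", {
  t <- seq(0, 60, by = 1 / 120)
  x <- 3.5 + 0.2 * sin(2 * pi * 0.5 * t)
  st <- gaze_pupil_stream(t, 0 * t, 0 * t, x, x, !logical(length(t)),
                          !logical(length(t)), 120)
  out <- resample_filter_pupil(st)
  expect_equal(attr(out, "fs"), 128)
  expect_equal(diff(out$t_s)[1], 1 / 128)
  # 0.5 Hz passes with gain within 5% of unity
  mid <- out$t_s > 20 & out$t_s < 40
  expect_lt(abs(max(abs(out$pupil_left_mm[mid])) - 0.2) / 0.2, 0.05)
  # constant input is removed by the 0.1 Hz high-pass
  stc <- gaze_pupil_stream(t, 0 * t, 0 * t, rep(3.5, length(t)),
                           rep(3.5, length(t)), !logical(length(t)),
                           !logical(length(t)), 120)
  outc <- resample_filter_pupil(stc)
  expect_lt(max(abs(outc$pupil_left_mm)), 1e-6)
})

test_that("foreshortening cubic is recovered exactly and correction decorrelates", {
  cfg <- noise_free_config(seed = 41)
  cal <- synth_eye_calibration(cfg)
  hseg <- cal$segments[cal$segments$kind == "horizontal", ]
  m <- fit_pfe(cal$stream, hseg)
  # the intercept absorbs the resting pupil diameter; the gaze-dependent
  # coefficients are recovered exactly
  expect_equal(unname(m$coeffs_left[-1]), cfg$pfe_coeffs$left[-1],
               tolerance = 1e-8)
  expect_equal(unname(m$coeffs_right[-1]), cfg$pfe_coeffs$right[-1],
               tolerance = 1e-8)
  expect_equal(unname(m$coeffs_left[1]),
               cfg$pupil_baseline_mm + cfg$pfe_coeffs$left[1],
               tolerance = 1e-6)
  # ordering invariance
  m2 <- fit_pfe(cal$stream, hseg[rev(seq_len(nrow(hseg))), , drop = FALSE])
  expect_equal(m2$coeffs_left, m$coeffs_left)
  # correction removes the gaze-pupil correlation on a fresh session
  ev <- simulate_paradigm(1, seed = 42)
  st <- synth_pupil(ev, modify_config(cfg, seed = 42))
  cor_before <- stats::cor(st$gaze_h_deg, st$pupil_left_mm)
  out <- correct_pfe(st, m)
  expect_lt(abs(stats::cor(out$gaze_h_deg, out$pupil_left_mm)),
            max(0.02, abs(cor_before) / 20))
  # zero-coefficient model is the identity
  m0 <- m
  m0$coeffs_left <- m0$coeffs_right <- c(0, 0, 0, 0)
  expect_equal(correct_pfe(st, m0)$pupil_left_mm, st$pupil_left_mm)
  # gaze-independent pupil: fitted polynomial is a constant
  stc <- cal$stream
  stc$pupil_left_mm <- rep(3.5, nrow(stc))
  stc$pupil_right_mm <- rep(3.5, nrow(stc))
  mc <- fit_pfe(stc, hseg)
  expect_lt(max(abs(mc$coeffs_left[-1] *
                      c(25, 25^2, 25^3))), 1e-6)
})

test_that("pupil epochs satisfy the baseline conventions", {
  cfg <- noise_free_config(seed = 43)
  ev <- simulate_paradigm(1, seed = 43)
  st <- resample_filter_pupil(interpolate_blinks(synth_pupil(ev, cfg)))
  pe <- epoch_pupil(st, ev)
  expect_equal(pe$fs, 128)
  base <- which(pe$t_axis < 0)
  for (i in which(pe$labels != "correct"))
    expect_lt(abs(mean(pe$data[i, 1, base])), 1e-9)
  for (i in which(pe$labels == "correct"))
    expect_lt(abs(mean(pe$data[i, 1, ])), 1e-9)
  # strictly equal trial variances reject nothing (IQR = 0)
  tgrid <- seq(0, 300, by = 1 / 120)
  flat <- gaze_pupil_stream(tgrid, sin(tgrid), 0 * tgrid,
                            3.5 + sin(2 * pi * 0.5 * tgrid),
                            3.5 + sin(2 * pi * 0.5 * tgrid),
                            !logical(length(tgrid)),
                            !logical(length(tgrid)), 120)
  attr(flat, "fs") <- 120
  pf <- epoch_pupil(flat, ev)
  expect_equal(sum(!pf$kept), 0)
})

test_that("variance rejection pools error and correct trials separately", {
  cfg <- generator_config(n_runs = 1, seed = 44)
  ev <- simulate_paradigm(1, seed = 44)
  st <- resample_filter_pupil(interpolate_blinks(synth_pupil(ev, cfg)))
  pe <- epoch_pupil(st, ev)
  # kept fraction is high without injected outliers
  expect_gt(mean(pe$kept), 0.9)
  # duplicating the stream with an extreme correct trial leaves the
  # error-pool decisions unchanged
  st2 <- st
  corr_ev <- ev[ev$condition == "correct", ][5, ]
  idx <- which(st2$t_s > corr_ev$prev_target_pass_s + 1.5 &
                 st2$t_s < corr_ev$prev_target_pass_s + 3)
  st2$pupil_left_mm[idx] <- st2$pupil_left_mm[idx] +
    rnorm(length(idx), sd = 2)
  pe2 <- epoch_pupil(st2, ev)
  errs <- pe$labels != "correct"
  expect_equal(pe2$kept[errs], pe$kept[errs])
})
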