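# Build an SCR segment (100 Hz) with a cosine trough-to-peak deflection:
# baseline `base`, trough of depth reaching `v_min` at `t_min`, peak `v_max`
# at `t_max` (times relative to segment start).
scr_wave <- function(v_min, t_min, v_max, t_max, base = 0.2, dur = 12,
                     rate = 100) {
  tt <- seq(0, dur, by = 1 / rate)
  x <- rep(base, length(tt))
  fall <- tt >= t_min - 1 & tt < t_min
  x[fall] <- v_min + (base - v_min) * (1 + cos(pi * (tt[fall] - (t_min - 1)))) / 2
  rise <- tt >= t_min & tt <= t_max
  x[rise] <- v_min + (v_max - v_min) * (1 - cos(pi * (tt[rise] - t_min) /
                                                  (t_max - t_min))) / 2
  x[tt > t_max] <- v_max * exp(-(tt[tt > t_max] - t_max) / 4)
  x
}

test_that("SCR scoring finds the trough-to-peak amplitude in the window", {
  # cue at 1 s; trough 0.10 at 1.5 s post-cue, peak 0.60 at 4.0 s post-cue
  x <- scr_wave(v_min = 0.10, t_min = 2.5, v_max = 0.60, t_max = 5.0)
  tr <- signal_trace(x, 100, cue_onset_s = 1, stimulus_onset_s = 1.3, "scr")
  sc <- score_scr(tr)
  expect_true(sc$valid)
  expect_equal(sc$amplitude, 0.50, tolerance = 0.02)
  expect_equal(sc$t_trough_s, 2.5, tolerance = 0.1)
  expect_equal(sc$t_peak_s, 5.0, tolerance = 0.1)
  # invariance to adding a constant to the whole trace
  tr2 <- signal_trace(x + 7.5, 100, 1, 1.3, "scr")
  expect_equal(score_scr(tr2)$amplitude, sc$amplitude, tolerance = 1e-9)
})

test_that("SCR trials without a qualifying response are invalid", {
  flat <- signal_trace(rep(1, 1201), 100, 1, 1.3, "scr")
  sc <- score_scr(flat)
  expect_false(sc$valid)
  expect_equal(sc$amplitude, 0)
  # only rise begins 0.5 s post-cue and decays again before 1 s post-cue:
  # the trough precedes the 1 s onset-delay bound, so no response counts
  tt <- seq(0, 12, by = 0.01)
  early <- 0.5 * exp(-((tt - 1.75)^2) / (2 * 0.01)) # bump peaking 0.75 s post-cue
  tr <- signal_trace(0.3 + early, 100, cue_onset_s = 1,
                     stimulus_onset_s = 1.3, "scr")
  expect_false(score_scr(tr)$valid)
  expect_error(score_scr(signal_trace(rep(1, 50), 100, 0.1, 0.2, "scr")),
               "10 s")
})

test_that("pupil preprocessing enforces the missing-sample exclusion rule", {
  n <- 13001  # 13 s at 1000 Hz
  x <- rep(3, n)
  # blink intervals covering ~60% of the trial once padded
  blinks <- cbind(start_s = seq(0.5, 12, by = 1.3),
                  end_s = seq(0.5, 12, by = 1.3) + 0.6)
  tr <- signal_trace(x, 1000, cue_onset_s = 2.7, stimulus_onset_s = 3,
                     "pupil", blinks = blinks)
  out <- preprocess_pupil(tr)
  expect_true(out$discard)
  expect_gt(out$missing_fraction, 0.5)
  expect_null(out$trace)
  # constant trace with no blinks survives untouched
  tr0 <- signal_trace(x, 1000, 2.7, 3, "pupil")
  out0 <- preprocess_pupil(tr0)
  expect_false(out0$discard)
  expect_equal(out0$trace$rate, 250)
  expect_equal(out0$trace$samples, rep(3, length(out0$trace$samples)),
               tolerance = 1e-4)
})

test_that("the 2 Hz low-pass attenuates fast components and keeps slow ones", {
  rate <- 1000; dur <- 13
  tt <- seq(0, dur, by = 1 / rate)
  slow <- exp(-((tt - 6)^2) / (2 * 1.5^2))        # ~0.3 Hz-scale bump
  fast <- 0.5 * sin(2 * pi * 10 * tt)             # 10 Hz component
  tr <- signal_trace(4 + slow + fast, rate, 2.7, 3, "pupil")
  out <- preprocess_pupil(tr)
  expect_false(out$discard)
  t250 <- seq(0, dur, by = 1 / 250)
  slow250 <- exp(-((t250 - 6)^2) / (2 * 1.5^2))
  resid <- out$trace$samples - (4 + slow250)
  # 10 Hz residual attenuated by >= 20 dB (amplitude factor 10)
  core <- t250 > 1 & t250 < 12   # ignore filter edge transients
  expect_lt(max(abs(resid[core])), 0.5 / 10)
  # slow bump preserved within 5% at its peak
  expect_equal(max(out$trace$samples) - 4, max(slow), tolerance = 0.05)
})

test_that("band-limited input is reproduced at 250 Hz with no blinks", {
  rate <- 1000
  tt <- seq(0, 13, by = 1 / rate)
  x <- 5 + 0.8 * sin(2 * pi * 0.5 * tt)  # well below the 2 Hz cutoff
  out <- preprocess_pupil(signal_trace(x, rate, 2.7, 3, "pupil"))
  t250 <- seq(0, 13, by = 1 / 250)
  want <- 5 + 0.8 * sin(2 * pi * 0.5 * t250)
  core <- t250 > 1 & t250 < 12
  expect_equal(out$trace$samples[core], want[core], tolerance = 0.02)
})

test_that("pupil amplitude is baseline-to-peak and may be negative", {
  rate <- 250
  tt <- seq(0, 13, by = 1 / rate)
  bump <- 0.8 * exp(-((tt - 5)^2) / (2 * 0.6^2))
  tr <- signal_trace(3 + bump, rate, 2.7, 3, "pupil")
  sc <- score_pupil(tr)
  expect_true(sc$valid)
  expect_equal(sc$amplitude, 0.8, tolerance = 0.01)
  # constant trace scores zero
  sc0 <- score_pupil(signal_trace(rep(3, length(tt)), rate, 2.7, 3, "pupil"))
  expect_equal(sc0$amplitude, 0)
  expect_true(sc0$nonpositive)
  # trace whose only maximum precedes the stimulus: negative, flagged
  pre <- 0.5 * exp(-((tt - 1.5)^2) / (2 * 0.3^2)) - 0.2 * (tt > 3)
  scn <- score_pupil(signal_trace(3 + pre, rate, 2.7, 3, "pupil"))
  expect_true(scn$valid)
  expect_lte(scn$amplitude, 0)
  expect_true(scn$nonpositive)
  # missing baseline window: invalid
  short <- signal_trace(rep(3, 100), 250, 0.1, 0.2, "pupil")
  expect_false(score_pupil(short)$valid)
})

test_that("log transform maps zero to zero and preserves order", {
  expect_equal(log_amplitude(0), 0)
  expect_equal(log_amplitude(exp(1) - 1), 1)
  set.seed(2)
  a <- sort(runif(50, 0, 5))
  expect_true(all(diff(log_amplitude(a)) >= 0))
  expect_equal(log_amplitude(-0.3), 0)  # negatives clamp to zero
  expect_error(log_amplitude(c(1, NA)), "finite")
})
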