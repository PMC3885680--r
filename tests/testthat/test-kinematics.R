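fs <- 250

test_that("kinematic band-pass keeps 1 Hz, rejects 10 Hz and DC", {
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  one <- sin(2 * pi * 1 * t)
  out <- bandpass_kinematic(one, fs)
  expect_lt(abs(fft_amplitude(out, fs, 1) - 1), 0.05)

  ten <- sin(2 * pi * 10 * t)
  expect_lt(fft_amplitude(bandpass_kinematic(ten, fs), fs, 10), 0.1)  # >=20 dB

  dc <- rep(500, length(t))
  expect_lt(abs(mean(bandpass_kinematic(dc, fs))), 1)
  expect_error(bandpass_kinematic(rep(0, 10), fs), "shorter")
})

test_that("detector honours amplitude, latency, tail and merge criteria", {
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  tt <- trial_table(cue_onset = 4, finger = "index")
  # 1 Hz sinusoid, amplitude 300, spanning the whole recording: peaks of |x|
  # occur every 0.5 s; only those in [4.4, 5.5] survive
  x <- 300 * sin(2 * pi * 1 * t)
  ev <- detect_peaks(x, fs, tt, detector_params())
  expect_identical(nrow(ev$events), 2L)
  expect_true(all(ev$events$time >= 4.4 & ev$events$time <= 5.5))
  expect_identical(unique(ev$events$finger), "index")
  # brute-force oracle agreement
  expect_equal(ev$events$time,
               oracle_detect(abs(x), fs, 4, 6), tolerance = 1e-9)

  # below threshold: nothing
  ev2 <- detect_peaks(150 * sin(2 * pi * 1 * t), fs, tt, detector_params())
  expect_identical(nrow(ev2$events), 0L)

  # scaling above threshold leaves event times unchanged
  ev3 <- detect_peaks(2 * x, fs, tt, detector_params())
  expect_equal(ev3$events$time, ev$events$time)

  expect_error(detect_peaks(x, fs, tt[0, ], detector_params()), "empty")
})

test_that("within a 400 ms window only the strongest candidate is kept", {
  n <- 10 * fs
  x <- numeric(n)
  at <- function(s) round(s * fs) + 1
  # two candidate maxima 0.3 s apart, second larger
  x[at(4.80) + -1:1] <- c(240, 250, 240)
  x[at(5.10) + -1:1] <- c(280, 300, 280)
  tt <- trial_table(cue_onset = 4, finger = "ring")
  ev <- detect_peaks(x, fs, tt, detector_params())
  expect_identical(nrow(ev$events), 1L)
  expect_equal(ev$events$time, 5.10, tolerance = 1e-9)
  expect_equal(ev$events$amplitude, 300)

  # exactly equal amplitudes: the earlier peak wins
  x2 <- numeric(n)
  x2[at(4.80) + -1:1] <- c(240, 250, 240)
  x2[at(5.10) + -1:1] <- c(240, 250, 240)
  ev2 <- detect_peaks(x2, fs, tt, detector_params())
  expect_equal(ev2$events$time, 4.80, tolerance = 1e-9)
})

test_that("glove detector thresholds at 2 with plateau handling", {
  n <- 10 * fs
  pos <- numeric(n)
  # plateaus at 5 for 0.5 s each, separated by 1 s at 0
  for (s in c(2, 3.5, 5)) pos[round(s * fs):round((s + 0.5) * fs)] <- 5
  ev <- detect_peaks_glove(pos, fs)
  expect_identical(nrow(ev$events), 3L)
  expect_identical(ev$provenance, "glove")

  expect_identical(nrow(detect_peaks_glove(rep(1.9, n), fs)$events), 0L)
  expect_identical(nrow(detect_peaks_glove(rep(0, n), fs)$events), 0L)

  # two crossings 100 ms apart merge into a single event
  pos2 <- numeric(n)
  pos2[round(2.0 * fs) + -1:1] <- c(4, 5, 4)
  pos2[round(2.1 * fs) + -1:1] <- c(3, 4, 3)
  expect_identical(nrow(detect_peaks_glove(pos2, fs)$events), 1L)
})

test_that("synthetic pulses are band-limited and located at event times", {
  n <- 20 * fs
  expect_identical(synth_kinematic_trace(numeric(0), n, fs), numeric(n))

  x <- synth_kinematic_trace(5.0, n, fs, 300)
  xf <- bandpass_kinematic(x, fs)
  expect_lt(abs((which.max(abs(xf)) - 1) / fs - 5.0), 0.1)
  expect_gt(max(abs(xf)), 250)       # detector-band amplitude preserved

  expect_error(synth_kinematic_trace(c(5, 5.1), n, fs), "200 ms")
  expect_error(synth_kinematic_trace(c(5, 4), n, fs), "increasing")

  # two events 1 s apart -> exactly 2 detected peaks end to end
  x2 <- synth_kinematic_trace(c(4.5, 5.5), n, fs, 300)
  tt <- trial_table(cue_onset = 4, finger = "thumb")
  ev <- detect_peaks(bandpass_kinematic(x2, fs), fs, tt, detector_params())
  expect_identical(nrow(ev$events), 2L)
  expect_equal(ev$events$time, c(4.5, 5.5), tolerance = 0.06)
})

test_that("detector recall and precision on generated data", {
  cf <- small_config(seed = 21)
  ds <- generate_dataset(cf)
  ev <- fingerbci:::detect_all_fingers(ds$kinematics, cf$fs, ds$trials,
                                       detector_params())
  gt <- ds$ground_truth$events$events
  de <- ev$events
  hit <- vapply(seq_len(nrow(gt)), function(i)
    any(de$trial == gt$trial[i] & abs(de$time - gt$time[i]) < 0.1), TRUE)
  fp <- vapply(seq_len(nrow(de)), function(i)
    !any(gt$trial == de$trial[i] & abs(gt$time - de$time[i]) < 0.1), TRUE)
  expect_gte(mean(hit), 0.95)
  expect_lte(mean(fp), 0.05)

  # determinism
  ev2 <- fingerbci:::detect_all_fingers(ds$kinematics, cf$fs, ds$trials,
                                        detector_params())
  expect_identical(ev$events, ev2$events)
})

test_that("events round-trip through TSV", {
  ev <- event_set(c(1.5, 2.5), c("thumb", "index"), c(1L, 2L), c(300, 280))
  path <- file.path(tempdir(), "ev.tsv")
  write_event_set(ev, path)
  back <- read_event_set(path)
  expect_equal(back$events, ev$events, tolerance = 1e-12)
})
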