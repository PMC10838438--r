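test_that("harmonicity: clean voice is near-noiseless, HNR tracks SNR", {
  h <- harmonicity_metrics(clean_voice())
  expect_gt(h$hnr_mean, 30)
  expect_gt(h$ac_mean, 0.99)
  expect_gt(h$cc_mean, 0.99)
  hnr <- vapply(c(20, 10, 0), function(snr) {
    rec <- synthesize_voice(voice_spec(f0_hz = 150, duration_s = 1,
                                       noise_snr_db = snr, seed = 7))
    harmonicity_metrics(rec)$hnr_mean
  }, numeric(1))
  expect_lt(abs(hnr[2] - 10), 3)
  expect_true(all(diff(hnr) < 0))
})

test_that("harmonicity of unvoiced input is missing", {
  x <- withr::with_seed(3, rnorm(22050) * 0.3)
  rec <- audio_recording(pmin(pmax(x, -1), 1), 44100)
  expect_true(is.na(harmonicity_metrics(rec)$hnr_mean))
})

test_that("intensity statistics behave like decibel order statistics", {
  rec <- tone_rec(200, dur = 1, amp = 0.3)
  i1 <- intensity_metrics(rec)
  expect_lt(i1$variance, 0.1)
  expect_true(i1$min <= i1$median && i1$median <= i1$max)
  i2 <- intensity_metrics(tone_rec(200, dur = 1, amp = 0.6))
  expect_lt(abs((i2$mean - i1$mean) - 20 * log10(2)), 0.1)
  expect_true(is.na(intensity_metrics(audio_recording(numeric(4410) + 0, 44100))$mean))
})

test_that("zero-crossing rate matches closed forms", {
  z <- zcr_metrics(tone_rec(100, dur = 1))
  expect_lt(abs(z$mean * 44100 - 200) / 200, 0.02)
  # positive-constant signal never crosses
  expect_equal(zcr_metrics(audio_recording(rep(0.5, 44100), 44100))$mean, 0)
  # i.i.d. symmetric noise flips sign with probability 1/2
  x <- withr::with_seed(6, rnorm(44100) * 0.2)
  zn <- zcr_metrics(audio_recording(pmin(pmax(x, -1), 1), 44100))
  expect_lt(abs(zn$mean - 0.5), 0.02)
})

test_that("segmentation recovers a constructed pause schedule", {
  fs <- 44100
  tt <- function(n) (0:(n - 1)) / fs
  x <- c(0.5 * sin(2 * pi * 200 * tt(round(0.5 * fs))),
         numeric(round(0.4 * fs)),
         0.5 * sin(2 * pi * 200 * tt(round(0.6 * fs))))
  seg <- segment_speech_pauses(audio_recording(x, fs))
  expect_equal(nrow(seg$pauses), 1)
  expect_lt(abs((seg$pauses$end - seg$pauses$start) - 0.40), 0.02)
  # boundaries within one frame
  expect_lt(abs(seg$pauses$start - 0.5), seg$frame_s + 1e-9)
  expect_lt(abs(seg$pauses$end - 0.9), seg$frame_s + 1e-9)
  # segments tile [0, duration)
  all_seg <- rbind(seg$speech, seg$pauses)
  all_seg <- all_seg[order(all_seg$start), ]
  expect_equal(all_seg$start[1], 0)
  expect_equal(all_seg$end[nrow(all_seg)], seg$duration)
  expect_true(all(abs(all_seg$end[-nrow(all_seg)] - all_seg$start[-1]) < 1e-9))
})

test_that("sub-minimum silences are not pauses; all-silence has no speech", {
  fs <- 44100
  tt <- function(n) (0:(n - 1)) / fs
  x <- c(0.5 * sin(2 * pi * 200 * tt(round(0.5 * fs))),
         numeric(round(0.10 * fs)),
         0.5 * sin(2 * pi * 200 * tt(round(0.5 * fs))))
  seg <- segment_speech_pauses(audio_recording(x, fs))
  expect_equal(nrow(seg$pauses), 0)
  seg0 <- segment_speech_pauses(audio_recording(numeric(fs) + 0, fs))
  expect_equal(nrow(seg0$speech), 0)
})

test_that("timing metrics follow their definitions", {
  seg <- structure(list(
    speech = data.frame(start = c(0, 0.9), end = c(0.5, 2.4)),
    pauses = data.frame(start = 0.5, end = 0.9),
    nuclei = seq(0.1, 2.35, length.out = 10),
    duration = 2.5, frame_s = 0.01), class = "segmentation_result")
  tm <- timing_rate_metrics(seg)
  expect_equal(tm$speech_time, 2.0)
  expect_equal(tm$speech_rate, 10 / 2.5)
  expect_equal(tm$articulation_rate, 10 / 2.0)
  expect_equal(tm$phonation_ratio, 0.8)
  # pause classes
  seg$pauses <- data.frame(start = c(0, 1, 2), end = c(0.3, 1.7, 3.2))
  tm2 <- timing_rate_metrics(seg)
  expect_equal(c(tm2$n_pauses_short, tm2$n_pauses_medium, tm2$n_pauses_long),
               c(1, 1, 1))
  expect_equal(tm2$pause_mean_dur, mean(c(0.3, 0.7, 1.2)), tolerance = 1e-9)
  # no pauses
  seg$pauses <- data.frame(start = numeric(0), end = numeric(0))
  tm3 <- timing_rate_metrics(seg)
  expect_equal(tm3$pause_time, 0)
  expect_equal(tm3$n_pauses + tm3$n_pauses_short + tm3$n_pauses_medium +
                 tm3$n_pauses_long, 0)
})

test_that("extract_features returns exactly the 53 manifest features, deterministically", {
  rec <- synthesize_voice(voice_spec(f0_hz = 140, duration_s = 1.2,
                                     jitter_pct = 0.5, shimmer_pct = 1,
                                     pause_schedule = list(c(0.5, 0.25)),
                                     seed = 12))
  fv <- extract_features(rec)
  expect_length(fv, 53)
  expect_identical(names(fv), feature_names())
  expect_identical(fv, extract_features(rec))
  expect_equal(length(attr(fv, "missing")), 53)
})

test_that("an unvoiced recording has missing phonatory but present timing features", {
  fs <- 44100
  x <- withr::with_seed(5, rnorm(fs) * 0.3)  # "whispered": aperiodic
  x[round(0.45 * fs):round(0.65 * fs)] <- 0
  fv <- extract_features(audio_recording(pmin(pmax(x, -1), 1), fs))
  expect_true(is.na(fv[["jitter_local"]]))
  expect_true(is.na(fv[["f0_mean"]]))
  expect_false(is.na(fv[["speech_time"]]))
  expect_false(is.na(fv[["n_pauses"]]))
})

test_that("F0 statistics satisfy order relations", {
  rec <- synthesize_voice(voice_spec(f0_hz = 180, duration_s = 1,
                                     jitter_pct = 2, seed = 4))
  s <- f0_statistics(track_f0(rec))
  expect_true(s$min <= s$median && s$median <= s$max)
  expect_equal(s$range, s$max - s$min)
  expect_equal(s$sd^2, s$variance, tolerance = 1e-9)
})
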