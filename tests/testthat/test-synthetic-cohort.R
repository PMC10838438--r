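test_that("cohort_config validates sizes, rho and feature names", {
  expect_error(cohort_config(n_control = 1), ">= 2")
  expect_error(cohort_config(rho = 1), "rho")
  expect_error(cohort_config(effect_map = list(not_a_feature = 1)),
               "unknown feature name")
})

test_that("generated cohort has the study dimensions and is deterministic", {
  cfg <- cohort_config(seed = 3)
  tab <- generate_cohort(cfg)
  expect_equal(nrow(tab), 141)
  expect_equal(sum(tab$group == "ALS"), 119)
  expect_equal(sum(tab$group == "control"), 22)
  expect_identical(setdiff(names(tab), c("subject_id", "group", "frs_bulb", "sex")),
                   feature_names())
  expect_identical(tab, generate_cohort(cfg))
  # FRS-bulbar targets: integer scores in range, missing fraction as configured
  frs <- tab$frs_bulb[tab$group == "ALS"]
  expect_equal(sum(is.na(frs)), round(26 / 119 * 119))
  expect_true(all(frs[!is.na(frs)] %in% 0:12))
  expect_lte(abs(median(frs, na.rm = TRUE) - 11), 1)
})

test_that("null-cohort standardized differences match the sampling-error bound", {
  # oracle: with no true effects, d-hat ~ N(0, (n1+n2)/(n1*n2)); the
  # expected count of |d| < 0.3 at the 22 + 119 study sizes follows from
  # the normal CDF (seed-averaged)
  se <- sqrt((22 + 119) / (22 * 119))
  expected <- 53 * (pnorm(0.3 / se) - pnorm(-0.3 / se))
  counts <- vapply(1:3, function(s) {
    tab <- generate_cohort(cohort_config(seed = 300 + s))
    d <- vapply(feature_names(), function(f) {
      a <- tab[[f]][tab$group == "control"]
      b <- tab[[f]][tab$group == "ALS"]
      abs(mean(a) - mean(b)) / sqrt((var(a) + var(b)) / 2)
    }, numeric(1))
    sum(d < 0.3)
  }, numeric(1))
  expect_lt(abs(mean(counts) - expected), 6)
})

test_that("configured effects are realized within tolerance", {
  tab <- generate_cohort(cohort_config(effect_map = list(speech_rate = 1.5),
                                       seed = 17))
  a <- tab$speech_rate[tab$group == "control"]
  b <- tab$speech_rate[tab$group == "ALS"]
  d <- (mean(a) - mean(b)) / sqrt((var(a) + var(b)) / 2)
  expect_lt(abs(d - 1.5), 0.4)
})

test_that("realized effects converge to the configured value at large n", {
  ds <- vapply(1:3, function(s) {
    tab <- generate_cohort(cohort_config(n_control = 500, n_als = 500,
                                         effect_map = list(hnr_mean = 1.0),
                                         seed = 500 + s))
    a <- tab$hnr_mean[tab$group == "control"]
    b <- tab$hnr_mean[tab$group == "ALS"]
    (mean(a) - mean(b)) / sqrt((var(a) + var(b)) / 2)
  }, numeric(1))
  expect_lt(abs(mean(ds) - 1.0), 0.1)
})

test_that("within-category correlation is present and cross-category absent", {
  tab <- generate_cohort(cohort_config(n_control = 400, n_als = 400, seed = 23))
  within <- cor(tab$jitter_local, tab$jitter_rap)
  across <- cor(tab$jitter_local, tab$int_mean)
  expect_gt(within, 0.3)
  expect_lt(abs(across), 0.15)
})

test_that("audio cohort: doubled pauses raise extracted pause time in impaired group", {
  tpl <- voice_spec(f0_hz = 140, duration_s = 1.6,
                    pause_schedule = list(c(0.6, 0.25)),
                    sample_rate_hz = 16000L, seed = 1)
  coh <- generate_audio_cohort(cohort_config(n_control = 5, n_als = 5, seed = 5),
                               tpl, audio_effects = list(pause_mult = 2))
  pt <- vapply(coh, function(s) {
    seg <- segment_speech_pauses(s$rec)
    sum(seg$pauses$end - seg$pauses$start)
  }, numeric(1))
  grp <- vapply(coh, `[[`, character(1), "group")
  wins <- sum(outer(pt[grp == "ALS"], pt[grp == "control"], `>`))
  expect_gte(wins, 20)  # >= 4/5 of the 25 cross-group pairs
  # determinism of the audio fixtures
  coh2 <- generate_audio_cohort(cohort_config(n_control = 5, n_als = 5, seed = 5),
                                tpl, audio_effects = list(pause_mult = 2))
  expect_identical(coh[[1]]$rec$samples, coh2[[1]]$rec$samples)
  expect_identical(coh[[10]]$rec$samples, coh2[[10]]$rec$samples)
})

test_that("cohort CSV round-trips", {
  tab <- generate_cohort(cohort_config(n_control = 4, n_als = 6, seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(tab, path)
  back <- read_cohort_csv(path)
  expect_equal(back$subject_id, tab$subject_id)
  expect_equal(back$speech_rate, tab$speech_rate, tolerance = 1e-12)
})
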