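test_that("cardiac trains have the requested rate, jitter and amplitude", {
  z <- synthesize_cardiac(60, 333, 10, seed = 1)
  # threshold crossing count: one wavelet per second at 60 bpm
  thr <- mean(z) + 1.5 * sd(z)
  up <- which(diff(z > thr) == 1)
  expect_gte(length(up), 9)
  expect_lte(length(up), 11)

  z2 <- synthesize_cardiac(72, 333, 60, seed = 1)
  psd <- welch_psd(z2, 333, segment_len = 8192)
  expect_lt(abs(psd$freq[which.max(psd$power)] - 1.2), 0.05)

  prof <- subject_profile(cardiac_amp = 0.05)
  z3 <- synthesize_cardiac(80, 333, 10, profile = prof, seed = 2)
  expect_gt(max(z3), 0.04)  # scales with cardiac_amp

  expect_error(synthesize_cardiac(0, 333, 10), "hr_bpm")
  expect_error(synthesize_cardiac(300, 333, 10), "hr_bpm")
  expect_error(synthesize_cardiac(40, 333, 1), "two cardiac cycles")
})

test_that("respiration has the requested fundamental and zero crossings", {
  y <- synthesize_respiration(12, 333, 60, seed = 4)
  m <- mean(y)
  up <- sum(diff(y > m) == 1)
  expect_gte(up, 11)
  expect_lte(up, 13)

  y2 <- synthesize_respiration(16, 333, 60, seed = 5)
  psd <- welch_psd(y2, 333, segment_len = length(y2), overlap = 0)
  expect_lt(abs(psd$freq[which.max(psd$power)] - 16 / 60), 0.01)

  expect_error(synthesize_respiration(100, 333, 60), "rr_bpm")
  expect_error(synthesize_respiration(2, 333, 60), "rr_bpm")
})

test_that("laryngeal events are band-limited and below 0.4 g", {
  for (kind in c("swallow", "drink", "cough", "pinyin1", "vowel5")) {
    ev <- synthesize_event(kind, 333, 1.5, intensity = 1, seed = 9)
    expect_lt(max(abs(ev$az)), 0.4)
    psd <- welch_psd(ev$az, 333, segment_len = 256)
    frac <- sum(psd$power[psd$freq < 200]) / sum(psd$power)
    expect_gt(frac, 0.9)
  }
})

test_that("locomotion dominates the y-axis with a low fundamental", {
  for (kind in c("walk", "jump")) {
    ev <- synthesize_event(kind, 333, 3, seed = 10)
    expect_gt(sqrt(mean(ev$ay^2)), sqrt(mean(ev$az^2)))
    psd <- welch_psd(ev$ay, 333, segment_len = 512)
    expect_lt(psd$freq[which.max(psd$power)], 5)
    # larger amplitude than any laryngeal event
    sw <- synthesize_event("swallow", 333, 1.5, seed = 10)
    expect_gt(max(abs(ev$ay)), max(abs(sw$az)))
  }
})

test_that("acoustic class templates are distinct and jitter-free reproducible", {
  cents <- vapply(laryx_classes()[1:10],
                  function(k) acoustic_template(k)$centroid, numeric(1))
  expect_true(all(diff(sort(cents)) > 10))
  # generated spectra land on the designed formants with zero jitter
  prof <- subject_profile(spectral_jitter = 0, baseline_noise_sd = 0)
  for (k in c("pinyin1", "vowel3")) {
    ev <- synthesize_event(k, 333, 2, profile = prof, seed = 3)
    psd <- welch_psd(ev$az, 333, segment_len = 512)
    pk <- psd$freq[which.max(psd$power)]
    tm <- acoustic_template(k)
    expect_lt(min(abs(pk - c(tm$f1, tm$f2))), 3)
  }
  expect_error(synthesize_event("yodel", 333, 1), "Unknown event kind")
})

test_that("sEMG is envelope-modulated band-limited noise", {
  prof <- subject_profile(baseline_noise_sd = 0.01)
  n <- 3330
  quiet <- synthesize_semg(numeric(n), 333, prof, seed = 1)
  expect_lt(abs(sqrt(mean(quiet^2)) - 0.01) / 0.01, 0.1)

  env <- c(numeric(1000), rep(1, 1330), numeric(1000))
  burst <- synthesize_semg(env, 333, prof, seed = 2)
  rms_in <- sqrt(mean(burst[1001:2330]^2))
  rms_out <- sqrt(mean(burst[c(1:1000, 2331:3330)]^2))
  expect_gt(rms_in, 5 * rms_out)
  # carrier band 20-150 Hz
  psd <- welch_psd(burst[1001:2330], 333, segment_len = 512)
  in_band <- sum(psd$power[psd$freq >= 15 & psd$freq <= 155])
  expect_gt(in_band / sum(psd$power), 0.95)

  expect_error(synthesize_semg(c(-1, 0, 1), 333, prof), ">= 0")
  expect_error(synthesize_semg(numeric(10), 0, prof), "fs")
})

test_that("recordings superpose components, keep annotations, and are seeded", {
  rec <- synthesize_recording(hr_bpm = 60, rr_bpm = 12, duration = 30,
                              seed = 7)
  psd_z <- welch_psd(rec$az, 333, segment_len = 4096)
  psd_y <- welch_psd(rec$ay, 333, segment_len = length(rec$ay), overlap = 0)
  expect_lt(abs(psd_z$freq[which.max(psd_z$power)] - 1), 0.1)
  expect_lt(abs(psd_y$freq[which.max(psd_y$power)] - 0.2), 0.05)

  rec2 <- synthesize_recording(hr_bpm = 60, rr_bpm = 12, duration = 30,
                               seed = 7)
  expect_identical(recording_channels(rec), recording_channels(rec2))

  sched <- event_schedule("swallow", onset = 5, duration = 1.5)
  rec3 <- synthesize_recording(sched, duration = 10, seed = 8)
  ann <- recording_annotations(rec3)
  expect_equal(nrow(ann), 1)
  expect_equal(ann$onset, 5)
  expect_equal(ann$kind, "swallow")

  dup <- event_schedule(c("cough", "cough"), onset = c(2, 2),
                        duration = c(1, 1))
  expect_warning(synthesize_recording(dup, duration = 10, seed = 9),
                 "identical onsets")
  expect_error(synthesize_recording(event_schedule("cough", 9.5, 2),
                                    duration = 10), "within the recording")
})

test_that("cohorts give per-subject profiles and the full class grid", {
  cohort <- synthesize_cohort(3, small_classes(), reps_per_class = 2,
                              seed = 1)
  expect_equal(nrow(cohort), 3 * 4 * 2)
  expect_equal(length(unique(cohort$subject_id)), 3)
  amps <- vapply(unique(cohort$subject_id), function(s) {
    recording_profile(cohort$recording[[match(s, cohort$subject_id)]])$cardiac_amp
  }, numeric(1))
  expect_gt(length(unique(amps)), 1)
  expect_error(synthesize_cohort(1, small_classes()), "n_subjects")
})
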