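# Shared fixtures, built once per test run and memoized.

.laryx_fixtures <- new.env(parent = emptyenv())

# Separable 13-class cohort at the subject-holdout study scale (16 training
# + 2 held-out subjects) and a model trained on it. Desk-scale training
# settings: 6 windows per recording, batch 16, 20 epochs, cosine annealing
# from 1e-2.
get_sep_fit <- function() {
  if (is.null(.laryx_fixtures$sep)) {
    cohort <- synthesize_cohort(18, laryx_classes(), reps_per_class = 1,
                                seed = 11, spectral_jitter = 0,
                                baseline_noise_sd = 0.001)
    ds <- assemble_dataset(cohort, test_subjects = c("S17", "S18"),
                           n_sequences = 6, length = 1000, seed = 11)
    model <- build_sfe(sfe_config(n_classes = 13, loss_mix = 0.3,
                                  batch_size = 16), seed = 11)
    fit <- train_sfe(model, ds,
                     schedule = lr_schedule_config(iLR = 0.01, epochs = 20),
                     epochs = 20, seed = 11)
    .laryx_fixtures$sep <- list(cohort = cohort, ds = ds, fit = fit)
  }
  .laryx_fixtures$sep
}

# Small 4-class model trained once and reused across training/adaptation
# tests.
get_small_fit <- function() {
  if (is.null(.laryx_fixtures$small_fit)) {
    fx <- make_small_dataset(n_subjects = 4, n_sequences = 12, seed = 42)
    model <- build_sfe(sfe_config(n_classes = 4, loss_mix = 0.3,
                                  batch_size = 16), seed = 7)
    fit <- train_sfe(model, fx$ds,
                     schedule = lr_schedule_config(iLR = 0.01, epochs = 30),
                     epochs = 30, seed = 7)
    .laryx_fixtures$small_fit <- list(fit = fit, fx = fx)
  }
  .laryx_fixtures$small_fit
}

# A small 4-class cohort/dataset (well-separated classes) for fast training
# tests.
small_classes <- function() c("pinyin1", "vowel2", "swallow", "cough")

make_small_dataset <- function(n_subjects = 4, classes = small_classes(),
                               n_sequences = 8, spectral_jitter = 0,
                               seed = 42) {
  cohort <- synthesize_cohort(n_subjects, classes, reps_per_class = 1,
                              seed = seed, spectral_jitter = spectral_jitter,
                              baseline_noise_sd = 0.001)
  test_subj <- sprintf("S%02d", n_subjects)
  list(cohort = cohort,
       ds = assemble_dataset(cohort, test_subjects = test_subj,
                             n_sequences = n_sequences, length = 1000,
                             seed = seed))
}

# Labeled windows from a subject with a perturbed profile (strong formant
# jitter, weak sEMG gain) relative to the jitter-free training cohort.
perturbed_subject_windows <- function(seed, classes, class_levels) {
  set.seed(seed)
  prof <- subject_profile(sprintf("P%02d", seed),
                          cardiac_amp = 0.02 * exp(rnorm(1, 0, 0.2)),
                          resp_amp = 0.05 * exp(rnorm(1, 0, 0.2)),
                          semg_gain = 0.5,
                          spectral_jitter = 0.18,
                          baseline_noise_sd = 0.004)
  rows <- list()
  for (ci in seq_along(classes)) {
    kind <- classes[ci]
    sched <- event_schedule(kind, onset = 0.5,
                            duration = min(default_event_duration(kind), 3))
    rec <- synthesize_recording(sched, hr_bpm = 75, rr_bpm = 15, fs = 333,
                                duration = 4, profile = prof,
                                seed = 200 * seed + ci)
    rows[[ci]] <- segment_sequences(
      suppressWarnings(normalize_recording(rec)), kind,
      n_sequences = 8, length = 1000, seed = 300 * seed + ci)
  }
  meta <- dplyr::bind_rows(rows)
  x <- array(0, c(4, 1000, nrow(meta)))
  for (i in seq_len(nrow(meta))) x[, , i] <- meta$window[[i]]
  list(x = x, labels = match(meta$label, class_levels))
}

# Brute-force check that the union of windows covers all sample indices.
covers_all <- function(offsets, n, L) {
  cov <- logical(n)
  for (o in offsets) cov[(o + 1):(o + L)] <- TRUE
  all(cov)
}
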