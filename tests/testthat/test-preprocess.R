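test_that("normalization is per-channel, idempotent and scale invariant", {
  rec <- synthesize_recording(duration = 10, seed = 1)
  nr <- normalize_recording(rec)
  for (ch in c("ax", "ay", "az", "semg")) {
    expect_lt(abs(mean(nr[[ch]])), 1e-10)
    expect_lt(abs(sd(nr[[ch]]) - 1), 1e-10)
  }
  nr2 <- normalize_recording(nr)
  expect_equal(recording_channels(nr2), recording_channels(nr),
               tolerance = 1e-10)
  scaled <- rec
  scaled$az <- rec$az * 10
  expect_equal(normalize_recording(scaled)$az, nr$az, tolerance = 1e-10)

  const <- rec
  const$semg <- rep(2, nrow(rec))
  expect_warning(cn <- normalize_recording(const), "constant")
  expect_true(all(cn$semg == 0))
})

test_that("random windowing yields exact counts, lengths and full coverage", {
  rec <- synthesize_recording(duration = 60, seed = 2)
  seg <- segment_sequences(rec, "rest", n_sequences = 100, length = 1000,
                           seed = 3)
  expect_equal(nrow(seg), 100)
  expect_true(all(vapply(seg$window, function(w) all(dim(w) == c(4, 1000)),
                         logical(1))))
  expect_true(covers_all(seg$offset, nrow(rec), 1000))
  expect_true(all(seg$label == "rest"))

  # exact-length recording: every window is forced to offset 0
  rec1k <- as_recording(as.data.frame(recording_channels(rec)[1:1000, ]),
                        fs = 333)
  seg1 <- segment_sequences(rec1k, "x", n_sequences = 5, length = 1000,
                            seed = 1)
  expect_true(all(seg1$offset == 0))

  # coverage property across lengths and seeds (brute force)
  for (n in c(1000, 1500, 5000)) {
    recn <- as_recording(as.data.frame(recording_channels(rec)[1:n, ]),
                         fs = 333)
    for (sd_ in 1:3) {
      sg <- segment_sequences(recn, "x", n_sequences = 100, length = 1000,
                              seed = sd_)
      expect_true(covers_all(sg$offset, n, 1000))
    }
  }

  # determinism and seed sensitivity
  a <- segment_sequences(rec, "r", 50, 1000, seed = 5)$offset
  b <- segment_sequences(rec, "r", 50, 1000, seed = 5)$offset
  c <- segment_sequences(rec, "r", 50, 1000, seed = 6)$offset
  expect_identical(a, b)
  expect_false(identical(sort(a), sort(c)))

  short <- as_recording(as.data.frame(recording_channels(rec)[1:500, ]),
                        fs = 333)
  expect_error(segment_sequences(short, "x", 10, 1000), "samples")
})

test_that("one-hot coding is a bijection with correct column counts", {
  m <- one_hot(1, 13)
  expect_equal(m[1, ], c(1, rep(0, 12)))
  m2 <- one_hot(c(3, 3, 6), 13)
  expect_equal(colSums(m2)[c(3, 6)], c(2, 1), ignore_attr = TRUE)
  expect_true(all(rowSums(m2) == 1))
  labs <- sample.int(13, 50, replace = TRUE)
  expect_equal(max.col(one_hot(labs, 13)), labs)
  expect_error(one_hot(14, 13), "1..13")
  expect_error(one_hot(0, 13), "1..13")
})

test_that("datasets are subject-disjoint and support class merging", {
  fx <- make_small_dataset(n_subjects = 3, n_sequences = 3)
  ds <- fx$ds
  tr_subj <- unique(ds$meta$subject_id[ds$meta$split %in% c("train", "holdout")])
  te_subj <- unique(ds$meta$subject_id[ds$meta$split == "test"])
  expect_length(intersect(tr_subj, te_subj), 0)
  expect_equal(ds$n_classes, 4)
  expect_true(all(rowSums(ds$one_hot) == 1))

  # 13-to-4 reduction: ten acoustic classes merge into `talk`
  cohort <- synthesize_cohort(2, laryx_classes(), seed = 3)
  cmap <- c(setNames(rep("talk", 10), laryx_classes()[1:10]),
            swallow = "swallow", drink = "drink", cough = "cough")
  ds4 <- assemble_dataset(cohort, test_subjects = "S02", class_map = cmap,
                          n_sequences = 2, seed = 4)
  expect_equal(ds4$n_classes, 4)
  expect_setequal(ds4$classes, c("talk", "swallow", "drink", "cough"))

  expect_error(assemble_dataset(cohort, test_subjects = character()),
               "non-empty")
  expect_error(assemble_dataset(cohort, test_subjects = c("S01", "S02")),
               "training split")
})
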