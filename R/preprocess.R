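# From labeled recordings to the fixed-length channel x time sequence dataset
# the classifier consumes.

#' Per-channel normalization of a recording
#'
#' Each of the four channels is centered and scaled to unit variance over the
#' whole recording (streaming-style, not per window). A constant channel is
#' mapped to zeros with a warning.
#'
#' @param recording A `laryx_recording`.
#' @return The recording with normalized channels.
#' @export
normalize_recording <- function(recording) {
  if (!nrow(recording)) abort("Empty recording.")
  for (ch in c("ax", "ay", "az", "semg")) {
    v <- recording[[ch]]
    s <- sd(v)
    if (s < .Machine$double.eps) {
      warn(sprintf("Channel `%s` is constant; normalized to zeros.", ch))
      recording[[ch]] <- rep(0, length(v))
    } else {
      recording[[ch]] <- (v - mean(v)) / s
    }
  }
  attr(recording, "normalized") <- TRUE
  recording
}

#' Randomly segment a recording into covering fixed-length windows
#'
#' Draws `n_sequences` window start offsets uniformly at random (seeded), then
#' repositions the fewest redundant windows needed so that the union of
#' windows covers every sample index of the recording. Windows may overlap;
#' each carries the recording's label and subject.
#'
#' @param recording A `laryx_recording` of at least `length` samples.
#' @param label Class label attached to every window.
#' @param n_sequences Number of windows (default 100).
#' @param length Window length in samples (default 1000).
#' @param seed Integer seed for the random offsets.
#' @return A tibble with one row per window: `window` (list of 4 x `length`
#'   channel matrices, rows ax/ay/az/semg), `label`, `subject_id`, `offset`
#'   (0-based start sample).
#' @export
segment_sequences <- function(recording, label, n_sequences = 100,
                              length = 1000, seed = 1) {
  n <- nrow(recording)
  L <- as.integer(length)
  if (n < L) {
    abort(sprintf("Recording has %d samples but windows need %d.", n, L))
  }
  if (n_sequences * L < n) {
    abort("`n_sequences * length` is smaller than the recording; full coverage is impossible.")
  }
  max_start <- n - L  # 0-based
  starts <- with_seed(seed,
                      sample.int(max_start + 1L, n_sequences, replace = TRUE) - 1L)
  starts <- repair_coverage(starts, n, L)
  ch <- t(recording_channels(recording))  # 4 x n
  rownames(ch) <- c("ax", "ay", "az", "semg")
  windows <- lapply(starts, function(s) ch[, (s + 1L):(s + L), drop = FALSE])
  tibble(window = windows,
         label = rep(label, n_sequences),
         subject_id = recording_profile(recording)$subject_id,
         offset = as.integer(starts))
}

# Greedy coverage repair: while uncovered samples remain, move one window to
# the leftmost uncovered index — preferring a redundant window (every sample
# it covers is covered at least twice), falling back to the movable window
# whose removal uncovers the least. Each window is moved at most once, so the
# leftmost gap advances monotonically; if the movable pool is exhausted the
# remaining windows are re-tiled deterministically (n_windows * L >= n
# guarantees feasibility).
repair_coverage <- function(starts, n, L) {
  cover <- integer(n)
  for (s in starts) cover[(s + 1L):(s + L)] <- cover[(s + 1L):(s + L)] + 1L
  movable <- rep(TRUE, length(starts))
  repeat {
    unc <- which(cover == 0L)
    if (!length(unc)) break
    a <- unc[1] - 1L                      # 0-based gap start
    new_start <- min(a, n - L)
    cand <- which(movable)
    if (!length(cand)) {
      # deterministic re-tile of the whole set
      tiles <- unique(pmin(seq(0L, n - 1L, by = L), n - L))
      starts[seq_along(tiles)] <- tiles
      cover <- integer(n)
      for (s in starts) cover[(s + 1L):(s + L)] <- cover[(s + 1L):(s + L)] + 1L
      next
    }
    red <- cand[vapply(cand, function(k) {
      s <- starts[k]
      all(cover[(s + 1L):(s + L)] >= 2L)
    }, logical(1))]
    k <- if (length(red)) {
      red[1]
    } else {
      costs <- vapply(cand, function(k) {
        s <- starts[k]
        sum(cover[(s + 1L):(s + L)] == 1L)
      }, integer(1))
      cand[which.min(costs)]
    }
    old <- starts[k]
    cover[(old + 1L):(old + L)] <- cover[(old + 1L):(old + L)] - 1L
    starts[k] <- new_start
    movable[k] <- FALSE
    cover[(new_start + 1L):(new_start + L)] <-
      cover[(new_start + 1L):(new_start + L)] + 1L
  }
  starts
}

#' One-hot label coding
#'
#' @param labels Integer class indices in `1..n_classes`.
#' @param n_classes Number of classes.
#' @return An indicator matrix with one row per label; row `i` has a single 1
#'   in column `labels[i]`.
#' @export
one_hot <- function(labels, n_classes) {
  labels <- as.integer(labels)
  if (any(is.na(labels)) || any(labels < 1L) || any(labels > n_classes)) {
    abort(sprintf("Labels must be integers in 1..%d.", n_classes))
  }
  m <- matrix(0, nrow = base::length(labels), ncol = n_classes)
  m[cbind(seq_along(labels), labels)] <- 1
  m
}

#' Assemble a subject-split sequence dataset from a cohort
#'
#' Normalizes each recording, windows it with [segment_sequences()], maps
#' event kinds to class labels (optionally merging classes, e.g. the ten
#' acoustic states into one `talk` class for the 13-to-4 reduction), one-hot
#' codes the labels, and assigns each window to the `train` or `test` split by
#' subject so the two subject sets are disjoint. A seeded fraction of the
#' training subjects' windows is additionally flagged `holdout` for
#' within-subject evaluation.
#'
#' @param cohort A `laryx_cohort` from [synthesize_cohort()].
#' @param test_subjects Character vector of held-out subject ids (non-empty).
#' @param class_map Named character vector mapping event kind to class name;
#'   defaults to the identity on the kinds present. Kinds absent from the map
#'   are dropped.
#' @param n_sequences,length Windowing parameters per recording.
#' @param holdout_frac Fraction of training windows flagged `holdout`
#'   (default 0.2).
#' @param seed Integer seed.
#' @return A `laryx_dataset` list: `x` (array `4 x length x n_windows`),
#'   `meta` (tibble `label_name, label, subject_id, offset, split`),
#'   `classes`, `n_classes`, `one_hot`, and the windowing parameters.
#' @export
assemble_dataset <- function(cohort, test_subjects, class_map = NULL,
                             n_sequences = 100, length = 1000,
                             holdout_frac = 0.2, seed = 1) {
  subjects <- unique(cohort$subject_id)
  test_subjects <- as.character(test_subjects)
  if (!base::length(test_subjects)) abort("`test_subjects` must be non-empty.")
  if (!all(test_subjects %in% subjects)) {
    abort("`test_subjects` must be a subset of the cohort's subjects.")
  }
  train_subjects <- setdiff(subjects, test_subjects)
  if (!base::length(train_subjects)) {
    abort("At least one subject must remain in the training split.")
  }
  if (is.null(class_map)) {
    kinds <- unique(cohort$kind)
    class_map <- setNames(kinds, kinds)
  }
  keep <- cohort$kind %in% names(class_map)
  cohort <- cohort[keep, , drop = FALSE]
  classes <- unique(unname(class_map[unique(cohort$kind)]))
  parts <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    rec <- suppressWarnings(normalize_recording(cohort$recording[[i]]))
    lab <- unname(class_map[[cohort$kind[i]]])
    parts[[i]] <- segment_sequences(rec, lab, n_sequences, length,
                                    seed = derive_seed(seed, i))
  }
  meta <- dplyr::bind_rows(parts)
  n <- nrow(meta)
  x <- array(0, dim = c(4L, as.integer(length), n))
  for (i in seq_len(n)) x[, , i] <- meta$window[[i]]
  label <- match(meta$label, classes)
  split <- ifelse(meta$subject_id %in% test_subjects, "test", "train")
  train_idx <- which(split == "train")
  if (holdout_frac > 0 && base::length(train_idx) > 1L) {
    n_h <- max(1L, round(holdout_frac * base::length(train_idx)))
    hold <- with_seed(derive_seed(seed, 999), sample(train_idx, n_h))
    split[hold] <- "holdout"
  }
  out <- list(
    x = x,
    meta = tibble(label_name = meta$label, label = label,
                  subject_id = meta$subject_id, offset = meta$offset,
                  split = split),
    classes = classes,
    n_classes = base::length(classes),
    one_hot = one_hot(label, base::length(classes)),
    n_sequences = n_sequences,
    window_length = as.integer(length),
    seed = seed,
    test_subjects = test_subjects
  )
  class(out) <- "laryx_dataset"
  out
}

#' @export
print.laryx_dataset <- function(x, ...) {
  cat(sprintf("<laryx_dataset> %d windows (4 x %d), %d classes, splits: %s\n",
              dim(x$x)[3], x$window_length, x$n_classes,
              paste(names(table(x$meta$split)), table(x$meta$split),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

# Subset a dataset's windows by index, preserving structure.
dataset_subset <- function(dataset, idx) {
  dataset$x <- dataset$x[, , idx, drop = FALSE]
  dataset$meta <- dataset$meta[idx, , drop = FALSE]
  dataset$one_hot <- dataset$one_hot[idx, , drop = FALSE]
  dataset
}
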