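# Quantitative evaluation: confusion matrices, subject-holdout protocols,
# adaptation and artifact-robustness probes, t-SNE embedding diagnostics.

#' Confusion matrix
#'
#' @param true_labels,predicted_labels Integer class indices in
#'   `1..n_classes`, equal length.
#' @param n_classes Number of classes.
#' @param class_names Optional class names for dimnames.
#' @return A `laryx_confusion` integer matrix, rows = true, columns =
#'   predicted, with the overall accuracy as attribute `accuracy`.
#' @export
confusion_matrix <- function(true_labels, predicted_labels, n_classes,
                             class_names = NULL) {
  if (length(true_labels) != length(predicted_labels)) {
    abort("True and predicted label vectors must have equal length.")
  }
  lv <- seq_len(n_classes)
  if (!all(true_labels %in% lv) || !all(predicted_labels %in% lv)) {
    abort(sprintf("Labels must be integers in 1..%d.", n_classes))
  }
  counts <- table(factor(true_labels, levels = lv),
                  factor(predicted_labels, levels = lv))
  m <- matrix(as.integer(counts), n_classes, n_classes)
  if (!is.null(class_names)) dimnames(m) <- list(true = class_names,
                                                 predicted = class_names)
  attr(m, "accuracy") <- sum(diag(m)) / sum(m)
  class(m) <- c("laryx_confusion", class(m))
  m
}

#' @export
print.laryx_confusion <- function(x, ...) {
  cat(sprintf("<laryx_confusion> %d classes, accuracy %.3f\n",
              nrow(x), attr(x, "accuracy")))
  print(unclass(x))
  invisible(x)
}

#' @export
tidy.laryx_confusion <- function(x, ...) {
  nm <- rownames(x) %||% as.character(seq_len(nrow(x)))
  expand.grid(true = nm, predicted = nm, stringsAsFactors = FALSE) |>
    as_tibble() |>
    dplyr::mutate(count = as.vector(unclass(x)))
}

#' Overall and per-class accuracy of a confusion matrix
#'
#' @param confusion A `laryx_confusion`.
#' @return `accuracy()` the trace over the total; `per_class_accuracy()` the
#'   diagonal over the row sums.
#' @export
accuracy <- function(confusion) sum(diag(confusion)) / sum(confusion)

#' @rdname accuracy
#' @export
per_class_accuracy <- function(confusion) {
  rs <- rowSums(confusion)
  ifelse(rs > 0, diag(unclass(confusion)) / rs, NA_real_)
}

#' Seeded t-SNE embedding of feature vectors
#'
#' @param features Numeric matrix, one feature vector per row.
#' @param seed Integer seed; the same seed gives identical coordinates.
#' @param perplexity t-SNE perplexity; requires `nrow(features) > 3 *
#'   perplexity`.
#' @return A tibble with columns `x`, `y` (one row per feature vector).
#' @export
tsne_embed <- function(features, seed = 1, perplexity = 30) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n <= 3 * perplexity) {
    abort(sprintf("t-SNE needs n > 3 * perplexity (n = %d, perplexity = %g).",
                  n, perplexity))
  }
  res <- with_seed(seed,
                   Rtsne::Rtsne(features, dims = 2, perplexity = perplexity,
                                check_duplicates = FALSE, pca = FALSE,
                                verbose = FALSE, num_threads = 1))
  tibble(x = res$Y[, 1], y = res$Y[, 2])
}

#' Mean silhouette width of labeled points
#'
#' Scalar proxy for cluster separation in a feature or embedding space.
#'
#' @param x Numeric matrix of coordinates (rows = points).
#' @param labels Cluster labels, at least two distinct.
#' @return Mean silhouette width in `[-1, 1]`.
#' @export
silhouette_score <- function(x, labels) {
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2L) abort("Silhouette needs >= 2 clusters.")
  sil <- cluster::silhouette(labels, stats::dist(as.matrix(x)))
  mean(sil[, "sil_width"])
}

# Contaminate windows (normalized units) with a seeded motion artifact.
contaminate_windows <- function(x, fs, intensity, seed) {
  if (intensity <= 0) return(x)
  kinds <- c("chew", "nod", "choke")
  n <- dim(x)[3]
  L <- dim(x)[2]
  with_seed(seed, {
    for (i in seq_len(n)) {
      kind <- sample(kinds, 1)
      ev <- synthesize_event(kind, fs, L / fs, intensity = 1,
                             profile = subject_profile(),
                             seed = sample.int(1e6, 1))
      art <- rbind(ev$ax, ev$ay, ev$az, ev$semg_env)
      sc <- apply(art, 1, function(r) max(abs(r), 1e-9))
      x[, , i] <- x[, , i] + intensity * art / sc
    }
    x
  })
}

#' Evaluate a trained model under a named protocol
#'
#' * `within_subject`: held-out windows from the training subjects (the
#'   dataset's `holdout` split).
#' * `new_subject_zero_shot`: all windows of the untouched test subjects.
#' * `new_subject_adapted`: a seeded half of each test subject's windows is
#'   used to adapt the fully connected head ([adapt_sfe()]); the other half is
#'   evaluated.
#' * `artifact_noise`: the within-subject windows with chew/nod/choke
#'   contamination injected at `artifact_intensity` (0 reduces exactly to
#'   `within_subject`).
#'
#' @param fit A `laryx_fit` (or `laryx_sfe` with class names attached).
#' @param dataset The `laryx_dataset` the model was trained on.
#' @param protocol One of the four protocol names.
#' @param seed Integer seed (adaptation split, artifact draws).
#' @param epochs_adapt,adapt_lr Adaptation parameters.
#' @param artifact_intensity Contamination scale for `artifact_noise`.
#' @param embed Also compute a t-SNE embedding of the evaluated features
#'   (needs enough windows).
#' @return A `laryx_report` list: `protocol`, `overall_accuracy`, `per_class`
#'   tibble, `confusion`, `n_windows`, and optionally `embedding`.
#' @export
evaluate_protocol <- function(fit, dataset,
                              protocol = c("within_subject",
                                           "new_subject_zero_shot",
                                           "new_subject_adapted",
                                           "artifact_noise"),
                              seed = 1, epochs_adapt = 20, adapt_lr = 1e-2,
                              artifact_intensity = 0.5, embed = FALSE) {
  protocol <- match.arg(protocol)
  model <- if (inherits(fit, "laryx_fit")) fit$model else fit
  meta <- dataset$meta
  fs <- 333  # window sample rate; artifacts only need a nominal rate
  if (protocol %in% c("within_subject", "artifact_noise")) {
    idx <- which(meta$split == "holdout")
    if (!length(idx)) {
      abort("No held-out training-subject windows; assemble the dataset with holdout_frac > 0.")
    }
    x <- dataset$x[, , idx, drop = FALSE]
    if (protocol == "artifact_noise") {
      x <- contaminate_windows(x, fs, artifact_intensity,
                               derive_seed(seed, 5))
    }
    pred <- predict(model, x)
    truth <- meta$label[idx]
  } else {
    idx <- which(meta$split == "test")
    if (!length(idx)) abort("No held-out test subjects in this dataset.")
    if (protocol == "new_subject_zero_shot") {
      pred <- predict(model, dataset$x[, , idx, drop = FALSE])
      truth <- meta$label[idx]
    } else {
      adapt_idx <- eval_idx <- integer()
      for (sid in unique(meta$subject_id[idx])) {
        si <- idx[meta$subject_id[idx] == sid]
        half <- with_seed(derive_seed(seed, match(sid, unique(meta$subject_id))),
                          sample(si, floor(length(si) / 2)))
        adapt_idx <- c(adapt_idx, half)
        eval_idx <- c(eval_idx, setdiff(si, half))
      }
      adapted <- adapt_sfe(model, dataset$x[, , adapt_idx, drop = FALSE],
                           meta$label[adapt_idx], epochs_adapt = epochs_adapt,
                           lr = adapt_lr, seed = derive_seed(seed, 7))
      pred <- predict(adapted, dataset$x[, , eval_idx, drop = FALSE])
      truth <- meta$label[eval_idx]
    }
  }
  cm <- confusion_matrix(truth, pred$class_id, dataset$n_classes,
                         dataset$classes)
  out <- list(protocol = protocol,
              overall_accuracy = accuracy(cm),
              per_class = tibble(class = dataset$classes,
                                 accuracy = per_class_accuracy(cm),
                                 n = as.integer(rowSums(cm))),
              confusion = cm,
              n_windows = length(truth))
  if (embed && length(truth) > 3 * 10) {
    out$embedding <- dplyr::mutate(
      tsne_embed(pred$features, seed = derive_seed(seed, 11),
                 perplexity = min(30, floor((length(truth) - 1) / 3) - 1)),
      label = dataset$classes[truth])
  }
  class(out) <- "laryx_report"
  out
}

#' @export
print.laryx_report <- function(x, ...) {
  cat(sprintf("<laryx_report> protocol %s: accuracy %.3f on %d windows\n",
              x$protocol, x$overall_accuracy, x$n_windows))
  invisible(x)
}

#' @export
glance.laryx_report <- function(x, ...) {
  tibble(protocol = x$protocol, overall_accuracy = x$overall_accuracy,
         n_windows = x$n_windows)
}

#' Write an evaluation report as structured text
#'
#' JSON summary plus a labeled CSV confusion grid, both deterministic for
#' identical inputs.
#'
#' @param report A `laryx_report`.
#' @param path Output path for the JSON report; the confusion grid is written
#'   next to it with suffix `_confusion.csv`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  body <- list(
    protocol = report$protocol,
    overall_accuracy = round(report$overall_accuracy, 10),
    n_windows = report$n_windows,
    per_class = lapply(seq_len(nrow(report$per_class)), function(i) {
      list(class = report$per_class$class[i],
           accuracy = round(report$per_class$accuracy[i], 10),
           n = report$per_class$n[i])
    })
  )
  jsonlite::write_json(body, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  cm <- as.data.frame(unclass(report$confusion))
  utils::write.csv(cbind(true = rownames(report$confusion) %||%
                           seq_len(nrow(report$confusion)), cm),
                   sub("\\.json$", "_confusion.csv", path),
                   row.names = FALSE)
  invisible(path)
}
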