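test_that("confusion matrices conserve counts and expose accuracies", {
  cm <- confusion_matrix(c(1, 1, 2), c(1, 2, 2), 2)
  expect_equal(unclass(cm)[1, ], c(1, 1), ignore_attr = TRUE)
  expect_equal(unclass(cm)[2, ], c(0, 1), ignore_attr = TRUE)
  expect_equal(accuracy(cm), 2 / 3)
  expect_equal(sum(cm), 3)

  perfect <- confusion_matrix(1:4, 1:4, 4)
  expect_equal(accuracy(perfect), 1)
  expect_true(all(unclass(perfect)[row(perfect) != col(perfect)] == 0))

  cm13 <- confusion_matrix(rep(1:13, 2), rep(1:13, 2), 13, laryx_classes())
  expect_equal(dim(cm13), c(13, 13))
  expect_equal(per_class_accuracy(cm13), rep(1, 13), ignore_attr = TRUE)

  expect_error(confusion_matrix(1:3, 1:4, 4), "equal length")
  expect_error(confusion_matrix(1:3, c(1, 2, 9), 4), "1..4")
})

test_that("t-SNE embeddings are seeded and separate distinct blobs", {
  set.seed(1)
  blob1 <- matrix(rnorm(60 * 5), 60, 5)
  blob2 <- matrix(rnorm(60 * 5, mean = 12), 60, 5)
  X <- rbind(blob1, blob2)
  emb <- tsne_embed(X, seed = 4, perplexity = 15)
  expect_equal(dim(emb), c(120, 2))
  expect_gt(silhouette_score(emb, rep(1:2, each = 60)), 0.5)
  emb2 <- tsne_embed(X, seed = 4, perplexity = 15)
  expect_identical(emb, emb2)
  expect_error(tsne_embed(matrix(rnorm(10), 5, 2), perplexity = 30),
               "perplexity")
})

test_that("evaluation protocols report holdout accuracy and feature gains", {
  sf <- get_small_fit()
  fit <- sf$fit
  ds <- sf$fx$ds
  rep_ws <- evaluate_protocol(fit, ds, "within_subject")
  expect_equal(rep_ws$protocol, "within_subject")
  expect_equal(rep_ws$overall_accuracy,
               sum(diag(rep_ws$confusion)) / sum(rep_ws$confusion))
  expect_equal(rep_ws$n_windows, sum(rep_ws$confusion))
  expect_gte(rep_ws$overall_accuracy, 0.9)

  # zero artifact intensity degenerates to the within-subject report
  rep_a0 <- evaluate_protocol(fit, ds, "artifact_noise",
                              artifact_intensity = 0)
  expect_equal(unclass(rep_a0$confusion), unclass(rep_ws$confusion),
               ignore_attr = TRUE)

  # artifact contamination cannot improve accuracy on a saturated model
  rep_a <- evaluate_protocol(fit, ds, "artifact_noise",
                             artifact_intensity = 1.5, seed = 2)
  expect_lte(rep_a$overall_accuracy, rep_ws$overall_accuracy + 1e-9)

  # training concentrates classes: silhouette grows versus the untrained net
  hold <- which(ds$meta$split == "holdout")
  untrained <- build_sfe(fit$model$config, seed = 99)
  s0 <- silhouette_score(predict(untrained, ds$x[, , hold])$features,
                         ds$meta$label[hold])
  s1 <- silhouette_score(predict(fit, ds$x[, , hold])$features,
                         ds$meta$label[hold])
  expect_gt(s1, s0)
})

test_that("protocol accuracies order as within >= adapted >= zero-shot under subject shift", {
  sep <- get_sep_fit()
  within_acc <- evaluate_protocol(sep$fit, sep$ds,
                                  "within_subject")$overall_accuracy
  res <- t(vapply(1:5, function(s) {
    pw <- perturbed_subject_windows(s, laryx_classes(), sep$ds$classes)
    n <- dim(pw$x)[3]
    set.seed(600 + s)
    half <- sample(n, floor(n / 2))
    rest <- setdiff(seq_len(n), half)
    zs <- mean(predict(sep$fit, pw$x[, , rest])$class_id == pw$labels[rest])
    ad <- adapt_sfe(sep$fit, pw$x[, , half], pw$labels[half],
                    epochs_adapt = 30, lr = 1e-2, seed = s)
    c(zs, mean(predict(ad, pw$x[, , rest])$class_id == pw$labels[rest]))
  }, numeric(2)))
  expect_gte(within_acc, mean(res[, 2]))
  expect_gte(mean(res[, 2]), mean(res[, 1]))
})

test_that("merging confusable classes cannot reduce accuracy", {
  sep <- get_sep_fit()
  rep13 <- evaluate_protocol(sep$fit, sep$ds, "within_subject")
  cm <- unclass(rep13$confusion)
  groups <- c(rep(1, 10), 2, 3, 4)  # acoustic -> talk; S/D/C kept
  cm4 <- rowsum(t(rowsum(cm, groups)), groups)
  acc4 <- sum(diag(cm4)) / sum(cm4)
  expect_gte(acc4, rep13$overall_accuracy)
})

test_that("evaluation reports serialize as structured text", {
  sf <- get_small_fit()
  rep_ws <- evaluate_protocol(sf$fit, sf$fx$ds, "within_subject")
  path <- file.path(withr::local_tempdir(), "report.json")
  write_report(rep_ws, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$protocol, "within_subject")
  expect_equal(parsed$overall_accuracy, rep_ws$overall_accuracy,
               tolerance = 1e-9)
  expect_true(file.exists(sub("\\.json$", "_confusion.csv", path)))
})
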