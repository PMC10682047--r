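# Dual-objective training of the sequential feature extractor: a triplet
# metric-learning term on the embeddings plus cross-entropy on the softmax
# head, a cosine learning-rate schedule, and an Adam-style update that also
# tracks the scalar attenuation-rate diagnostic.

#' Learning-rate schedule configuration
#'
#' Two modes are provided. `as_printed` evaluates the schedule literally as
#' `(1 + 0.5 cos(x + pi/epochs)) * (1 - iLR)` — the fidelity form, whose
#' values hover near 1.5 and which is therefore unsuitable for actual
#' optimization. `cosine_annealing` is the conventional reading,
#' `iLR * 0.5 * (1 + cos(pi x / epochs))`, decaying from the initial rate to
#' zero, and is the default training mode.
#'
#' @param iLR Initial learning rate (default 1e-4).
#' @param epochs Schedule horizon in epochs.
#' @param mode `"cosine_annealing"` or `"as_printed"`.
#' @return An `laryx_lr_config` list.
#' @export
lr_schedule_config <- function(iLR = 1e-4, epochs = 100,
                               mode = c("cosine_annealing", "as_printed")) {
  check_scalar(iLR, "iLR", lower = .Machine$double.xmin)
  check_scalar(epochs, "epochs", lower = 1)
  structure(list(iLR = iLR, epochs = as.integer(epochs),
                 mode = match.arg(mode)),
            class = "laryx_lr_config")
}

#' Evaluate the learning-rate schedule
#'
#' @param x Zero-based epoch index.
#' @param cfg An [lr_schedule_config()].
#' @return The learning rate at step `x`.
#' @export
lr_schedule <- function(x, cfg) {
  stopifnot(inherits(cfg, "laryx_lr_config"), all(x >= 0))
  if (cfg$mode == "as_printed") {
    (1 + 0.5 * cos(x + pi / cfg$epochs)) * (1 - cfg$iLR)
  } else {
    cfg$iLR * 0.5 * (1 + cos(pi * x / cfg$epochs))
  }
}

#' Adam-style optimizer configuration and state
#'
#' The update keeps exponential moving averages of gradients and squared
#' gradients (`m_t`, `v_t`, decay `beta1`/`beta2`), applies the bias-corrected
#' ratio `m_hat / (eps + sqrt(v_hat))` scaled by the learning rate, and tracks
#' a scalar attenuation-rate diagnostic `AR` (initial value 0.9) decremented
#' by the mean update ratio at each step.
#'
#' @param beta1,beta2 First- and second-order attenuation coefficients.
#' @param eps Numerical floor added to the root second moment.
#' @param ar0 Initial attenuation-rate value (default 0.9).
#' @return An `laryx_adam_config` list.
#' @export
adam_config <- function(beta1 = 0.9, beta2 = 0.999, eps = 1e-8, ar0 = 0.9) {
  check_scalar(beta1, "beta1", lower = 1e-12, upper = 1 - 1e-12)
  check_scalar(beta2, "beta2", lower = 1e-12, upper = 1 - 1e-12)
  check_scalar(eps, "eps", lower = .Machine$double.xmin)
  structure(list(beta1 = beta1, beta2 = beta2, eps = eps, ar0 = ar0),
            class = "laryx_adam_config")
}

#' @rdname adam_config
#' @param params Named list of parameter tensors (or a single numeric vector)
#'   the optimizer will update.
#' @param config An `adam_config()`.
#' @export
init_optimizer <- function(params, config = adam_config()) {
  params <- as_param_list(params)
  structure(list(
    t = 0L,
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    AR = config$ar0,
    config = config
  ), class = "laryx_optimizer")
}

as_param_list <- function(x) {
  if (is.numeric(x)) list(par = x) else x
}

#' One optimizer step
#'
#' Applies the Adam-style update to every parameter tensor. A zero gradient
#' leaves moments, parameters and the attenuation rate unchanged; non-finite
#' gradients reject the step with an error.
#'
#' @param state A `laryx_optimizer` from [init_optimizer()].
#' @param gradients Named list of gradient tensors matching the state (or a
#'   single numeric vector).
#' @param lr Learning rate for this step.
#' @param params Optional parameter list; when supplied the updated parameters
#'   are returned alongside the deltas.
#' @return A list with `state` (moments and `AR` advanced), `deltas` (the
#'   subtracted updates, same shapes as the gradients) and, when `params` was
#'   given, `params`.
#' @export
optimizer_step <- function(state, gradients, lr, params = NULL) {
  stopifnot(inherits(state, "laryx_optimizer"))
  gradients <- as_param_list(gradients)
  if (any(vapply(gradients, function(g) any(!is.finite(g)), logical(1)))) {
    abort("Non-finite gradient; optimizer step rejected.")
  }
  cfg <- state$config
  state$t <- state$t + 1L
  bc1 <- 1 - cfg$beta1^state$t
  bc2 <- 1 - cfg$beta2^state$t
  deltas <- vector("list", length(gradients))
  names(deltas) <- names(gradients)
  ratio_sum <- 0
  ratio_n <- 0
  for (nm in names(gradients)) {
    g <- gradients[[nm]]
    state$m[[nm]] <- cfg$beta1 * state$m[[nm]] + (1 - cfg$beta1) * g
    state$v[[nm]] <- cfg$beta2 * state$v[[nm]] + (1 - cfg$beta2) * g^2
    ratio <- (state$m[[nm]] / bc1) / (cfg$eps + sqrt(state$v[[nm]] / bc2))
    deltas[[nm]] <- lr * ratio
    ratio_sum <- ratio_sum + sum(ratio)
    ratio_n <- ratio_n + length(ratio)
  }
  state$AR <- state$AR - lr * ratio_sum / ratio_n
  out <- list(state = state, deltas = deltas)
  if (!is.null(params)) {
    params <- as_param_list(params)
    out$params <- mapply(function(p, d) p - d, params, deltas,
                         SIMPLIFY = FALSE)
  }
  out
}

#' Triplet loss
#'
#' `max(0, d(a, p) - d(a, n) + margin)` with Euclidean distance, averaged
#' over rows when matrices are supplied.
#'
#' @param anchor,positive,negative Feature vectors, or matrices with one
#'   triplet per row; dimensions must agree.
#' @param margin Margin (default 1).
#' @return Mean triplet loss.
#' @export
triplet_loss <- function(anchor, positive, negative, margin = 1) {
  a <- rbind(anchor); p <- rbind(positive); n <- rbind(negative)
  if (!all(dim(a) == dim(p)) || !all(dim(a) == dim(n))) {
    abort("Anchor, positive and negative must have identical dimensions.")
  }
  d_ap <- sqrt(rowSums((a - p)^2))
  d_an <- sqrt(rowSums((a - n)^2))
  mean(pmax(0, d_ap - d_an + margin))
}

#' Cross-entropy loss
#'
#' Mean `-log p_true` with a numerical floor of `1e-12` on probabilities.
#'
#' @param probabilities Matrix of class probabilities, rows summing to 1.
#' @param one_hot_targets Indicator matrix of the same shape.
#' @return Mean cross-entropy in nats.
#' @export
cross_entropy_loss <- function(probabilities, one_hot_targets) {
  p <- rbind(probabilities); y <- rbind(one_hot_targets)
  if (!all(dim(p) == dim(y))) {
    abort("Probability and target matrices must have identical shapes.")
  }
  if (any(abs(rowSums(p) - 1) > 1e-6)) {
    abort("Probability rows must sum to 1.")
  }
  p_true <- rowSums(p * y)
  mean(-log(pmax(p_true, 1e-12)))
}

# Within-batch triplet mining: hardest positive per anchor, semi-hard negative
# (smallest d_an exceeding d_ap) falling back to the hardest negative.
mine_triplets <- function(E, labels) {
  B <- nrow(E)
  G <- tcrossprod(E)
  sq <- diag(G)
  D2 <- pmax(outer(sq, sq, "+") - 2 * G, 0)
  D <- sqrt(D2)
  a_idx <- p_idx <- n_idx <- integer()
  for (i in seq_len(B)) {
    pos <- which(labels == labels[i])
    pos <- pos[pos != i]
    neg <- which(labels != labels[i])
    if (!length(pos) || !length(neg)) next
    p <- pos[which.max(D[i, pos])]
    d_ap <- D[i, p]
    semi <- neg[D[i, neg] > d_ap]
    n <- if (length(semi)) semi[which.min(D[i, semi])] else neg[which.max(D[i, neg])]
    a_idx <- c(a_idx, i); p_idx <- c(p_idx, p); n_idx <- c(n_idx, n)
  }
  list(a = a_idx, p = p_idx, n = n_idx, D = D)
}

# Loss and embedding gradient of the mined triplet term.
triplet_term <- function(E, labels, margin) {
  mt <- mine_triplets(E, labels)
  nT <- length(mt$a)
  dE <- matrix(0, nrow(E), ncol(E))
  if (nT == 0L) return(list(loss = 0, dE = dE))
  eps <- 1e-12
  losses <- numeric(nT)
  for (k in seq_len(nT)) {
    a <- mt$a[k]; p <- mt$p[k]; n <- mt$n[k]
    d_ap <- max(mt$D[a, p], eps)
    d_an <- max(mt$D[a, n], eps)
    l <- d_ap - d_an + margin
    if (l > 0) {
      losses[k] <- l
      u <- (E[a, ] - E[p, ]) / d_ap
      v <- (E[a, ] - E[n, ]) / d_an
      dE[a, ] <- dE[a, ] + (u - v) / nT
      dE[p, ] <- dE[p, ] - u / nT
      dE[n, ] <- dE[n, ] + v / nT
    }
  }
  list(loss = mean(losses), dE = dE)
}

# Flatten model parameters to a named list (and back) for the optimizer.
get_params <- function(model) {
  ps <- list()
  for (i in seq_along(model$convs)) {
    ps[[sprintf("conv%02d.W", i)]] <- model$convs[[i]]$W
    ps[[sprintf("conv%02d.b", i)]] <- model$convs[[i]]$b
  }
  ps[["fc1.W"]] <- model$fc1$W; ps[["fc1.b"]] <- model$fc1$b
  ps[["fc2.W"]] <- model$fc2$W; ps[["fc2.b"]] <- model$fc2$b
  ps
}

set_params <- function(model, ps) {
  for (i in seq_along(model$convs)) {
    model$convs[[i]]$W <- ps[[sprintf("conv%02d.W", i)]]
    model$convs[[i]]$b <- ps[[sprintf("conv%02d.b", i)]]
  }
  model$fc1$W <- ps[["fc1.W"]]; model$fc1$b <- ps[["fc1.b"]]
  model$fc2$W <- ps[["fc2.W"]]; model$fc2$b <- ps[["fc2.b"]]
  model
}

grads_to_params <- function(model, g) {
  ps <- list()
  for (i in seq_along(g$convs)) {
    ps[[sprintf("conv%02d.W", i)]] <- g$convs[[i]]$W
    ps[[sprintf("conv%02d.b", i)]] <- g$convs[[i]]$b
  }
  ps[["fc1.W"]] <- g$fc1$W; ps[["fc1.b"]] <- g$fc1$b
  ps[["fc2.W"]] <- g$fc2$W; ps[["fc2.b"]] <- g$fc2$b
  ps
}

model_accuracy <- function(model, X_all, labels, idx, batch = 256L) {
  if (!length(idx)) return(NA_real_)
  correct <- 0L
  for (s in seq(1L, length(idx), by = batch)) {
    sel <- idx[s:min(s + batch - 1L, length(idx))]
    fw <- sfe_forward(model, X_all[sel, , , drop = FALSE])
    correct <- correct + sum(max.col(fw$P) == labels[sel])
  }
  correct / length(idx)
}

#' Train the sequential feature extractor
#'
#' Per epoch: seeded shuffle, minibatches, combined loss
#' `loss_mix * triplet + (1 - loss_mix) * cross-entropy`, Adam-style update at
#' the scheduled learning rate. Records both losses and both split accuracies
#' every epoch and returns the snapshot with the best test accuracy.
#'
#' @param model A `laryx_sfe` from [build_sfe()].
#' @param dataset A `laryx_dataset` with non-empty train and test splits.
#' @param schedule An [lr_schedule_config()]; its `epochs` horizon defaults to
#'   the number of epochs run.
#' @param optimizer An [adam_config()].
#' @param epochs Number of epochs (default from the model config).
#' @param seed Integer seed controlling shuffling; with a fixed seed two runs
#'   produce identical trajectories.
#' @param verbose Print one line per epoch.
#' @return A `laryx_fit`: `model` (best-test snapshot), `final_model`,
#'   `history` (tibble epoch, lr, loss_triplet, loss_ce, loss, train_acc,
#'   test_acc), `best_epoch`, `classes`, `optimizer_state`.
#' @export
train_sfe <- function(model, dataset, schedule = NULL,
                      optimizer = adam_config(), epochs = NULL, seed = 1,
                      verbose = FALSE) {
  stopifnot(inherits(model, "laryx_sfe"), inherits(dataset, "laryx_dataset"))
  if (dataset$n_classes != model$config$n_classes) {
    abort("Dataset and model disagree on the number of classes.")
  }
  epochs <- as.integer(epochs %||% model$config$epochs)
  if (is.null(schedule)) {
    schedule <- lr_schedule_config(iLR = 1e-2, epochs = epochs)
  }
  train_idx <- which(dataset$meta$split == "train")
  test_idx <- which(dataset$meta$split == "test")
  if (!length(train_idx) || !length(test_idx)) {
    abort("Dataset must contain both a train and a test split.")
  }
  labels <- dataset$meta$label
  if (length(unique(labels[train_idx])) < 2L) {
    abort("Training split has a single class; triplets are impossible.")
  }
  lambda <- model$config$loss_mix
  bs <- model$config$batch_size
  X_all <- aperm(dataset$x, c(3, 2, 1))  # N x L x C
  opt <- init_optimizer(get_params(model), optimizer)
  hist <- vector("list", epochs)
  best <- list(acc = -Inf, model = model, epoch = 0L)
  with_seed(seed, {
    for (e in seq_len(epochs)) {
      lr <- lr_schedule(e - 1, schedule)
      perm <- sample(train_idx)
      l_tri <- l_ce <- 0
      n_batches <- 0L
      for (s in seq(1L, length(perm), by = bs)) {
        sel <- perm[s:min(s + bs - 1L, length(perm))]
        if (length(sel) < 2L) next
        fw <- sfe_forward(model, X_all[sel, , , drop = FALSE], cache = TRUE)
        Y <- dataset$one_hot[sel, , drop = FALSE]
        ce <- cross_entropy_loss(fw$P, Y)
        tt <- triplet_term(fw$E, labels[sel], model$config$triplet_margin)
        dlogits <- (1 - lambda) * (fw$P - Y) / length(sel)
        g <- sfe_backward(model, fw, dlogits, lambda * tt$dE)
        step <- optimizer_step(opt, grads_to_params(model, g), lr,
                               get_params(model))
        opt <- step$state
        model <- set_params(model, step$params)
        l_tri <- l_tri + tt$loss
        l_ce <- l_ce + ce
        n_batches <- n_batches + 1L
      }
      tr_acc <- model_accuracy(model, X_all, labels, train_idx)
      te_acc <- model_accuracy(model, X_all, labels, test_idx)
      if (te_acc >= best$acc) {
        best <- list(acc = te_acc, model = model, epoch = e)
      }
      hist[[e]] <- tibble(epoch = e, lr = lr,
                          loss_triplet = l_tri / max(1L, n_batches),
                          loss_ce = l_ce / max(1L, n_batches),
                          loss = (lambda * l_tri + (1 - lambda) * l_ce) /
                            max(1L, n_batches),
                          train_acc = tr_acc, test_acc = te_acc)
      if (verbose) {
        message(sprintf(
          "epoch %3d lr %.2e triplet %.4f ce %.4f train %.3f test %.3f",
          e, lr, hist[[e]]$loss_triplet, hist[[e]]$loss_ce, tr_acc, te_acc))
      }
    }
  })
  best$model$classes <- dataset$classes
  model$classes <- dataset$classes
  structure(list(model = best$model, final_model = model,
                 history = dplyr::bind_rows(hist),
                 best_epoch = best$epoch, seed = seed,
                 schedule = schedule, optimizer_state = opt,
                 classes = dataset$classes),
            class = "laryx_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.laryx_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf(
    "<laryx_fit> %d epochs; best test accuracy %.3f at epoch %d (final train %.3f)\n",
    nrow(h), max(h$test_acc), x$best_epoch, h$train_acc[nrow(h)]))
  invisible(x)
}

#' @export
tidy.laryx_fit <- function(x, ...) x$history

#' @export
glance.laryx_fit <- function(x, ...) {
  h <- x$history
  tibble(epochs = nrow(h), best_epoch = x$best_epoch,
         best_test_acc = max(h$test_acc),
         final_train_acc = h$train_acc[nrow(h)],
         final_loss = h$loss[nrow(h)])
}

# Normalize window input to an N x L x C array.
as_window_array <- function(newdata, config) {
  if (inherits(newdata, "laryx_dataset")) newdata <- newdata$x
  if (is.matrix(newdata)) newdata <- array(newdata, c(dim(newdata), 1L))
  d <- dim(newdata)
  if (length(d) != 3L || d[1] != config$input_channels ||
      d[2] != config$input_length) {
    abort(sprintf("Windows must be %d x %d (x N); got %s.",
                  config$input_channels, config$input_length,
                  paste(d, collapse = " x ")))
  }
  aperm(newdata, c(3, 2, 1))
}

#' Predict classes and feature vectors for windows
#'
#' @param object A `laryx_sfe` model or `laryx_fit`.
#' @param newdata A `laryx_dataset`, an array `channels x length x N`, or a
#'   single `channels x length` matrix.
#' @param ... Unused.
#' @return A `laryx_prediction` list: `features` (N x embedding_dim), `probs`
#'   (N x n_classes, rows summing to 1), `class_id` and `class_name` (when
#'   class names are known).
#' @export
predict.laryx_sfe <- function(object, newdata, ...) {
  X <- as_window_array(newdata, object$config)
  n <- dim(X)[1]
  feats <- matrix(0, n, object$embedding_dim)
  probs <- matrix(0, n, object$config$n_classes)
  for (s in seq(1L, n, by = 256L)) {
    sel <- s:min(s + 255L, n)
    fw <- sfe_forward(object, X[sel, , , drop = FALSE])
    feats[sel, ] <- fw$E
    probs[sel, ] <- fw$P
  }
  cid <- max.col(probs, ties.method = "first")
  structure(list(features = feats, probs = probs, class_id = cid,
                 class_name = if (!is.null(object$classes)) {
                   object$classes[cid]
                 }),
            class = "laryx_prediction")
}

#' @export
predict.laryx_fit <- function(object, newdata, ...) {
  predict(object$model, newdata, ...)
}

#' Adapt a trained model to a new subject
#'
#' The convolutional extractor is frozen; only the two fully connected
#' classifying layers are re-trained (cross-entropy objective, Adam-style
#' update) on the new subject's labeled windows. With `epochs_adapt = 0` the
#' model is returned unchanged (zero-shot path).
#'
#' @param model A trained `laryx_sfe` or `laryx_fit`.
#' @param windows New-subject windows (array `channels x length x N` or
#'   `laryx_dataset`).
#' @param labels Integer class labels in `1..n_classes`.
#' @param epochs_adapt Number of adaptation epochs.
#' @param lr Adaptation learning rate (constant; default 1e-2).
#' @param seed Integer seed.
#' @return The adapted `laryx_sfe` model.
#' @export
adapt_sfe <- function(model, windows, labels, epochs_adapt = 10, lr = 1e-2,
                      seed = 1) {
  if (inherits(model, "laryx_fit")) model <- model$model
  stopifnot(inherits(model, "laryx_sfe"))
  if (epochs_adapt == 0) return(model)
  K <- model$config$n_classes
  labels <- as.integer(labels)
  if (any(labels < 1L) || any(labels > K)) {
    abort(sprintf("Adaptation labels must reference seen classes (1..%d).", K))
  }
  X <- as_window_array(windows, model$config)
  n <- dim(X)[1]
  if (n != length(labels)) abort("One label per window is required.")
  # embeddings through the frozen extractor, computed once
  E <- predict(model, windows)$features
  Y <- one_hot(labels, K)
  ps <- list(fc1.W = model$fc1$W, fc1.b = model$fc1$b,
             fc2.W = model$fc2$W, fc2.b = model$fc2$b)
  opt <- init_optimizer(ps)
  bs <- min(model$config$batch_size, n)
  with_seed(seed, {
    for (e in seq_len(epochs_adapt)) {
      perm <- sample.int(n)
      for (s in seq(1L, n, by = bs)) {
        sel <- perm[s:min(s + bs - 1L, n)]
        Z1 <- sweep(E[sel, , drop = FALSE] %*% ps$fc1.W, 2, ps$fc1.b, "+")
        H <- leaky_relu(Z1)
        P <- softmax_rows(sweep(H %*% ps$fc2.W, 2, ps$fc2.b, "+"))
        dlog <- (P - Y[sel, , drop = FALSE]) / length(sel)
        dZ1a <- (dlog %*% t(ps$fc2.W)) * leaky_grad(Z1 > 0)
        g <- list(fc1.W = crossprod(E[sel, , drop = FALSE], dZ1a),
                  fc1.b = colSums(dZ1a),
                  fc2.W = crossprod(H, dlog),
                  fc2.b = colSums(dlog))
        step <- optimizer_step(opt, g, lr, ps)
        opt <- step$state
        ps <- step$params
      }
    }
  })
  model$fc1$W <- ps$fc1.W; model$fc1$b <- ps$fc1.b
  model$fc2$W <- ps$fc2.W; model$fc2$b <- ps$fc2.b
  model
}
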