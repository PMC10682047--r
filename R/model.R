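# The 2D-like sequential feature extractor (2D-SFE): eight weight-bearing
# convolution blocks whose conv/pool/activation layers total exactly 62
# processing layers, followed by two fully connected classifying layers ending
# in softmax. Windows are treated as channel x time images; convolutions are
# implemented as BLAS-backed im2col matrix products so training runs in plain
# R.
#
# Fixed block layout (layers counted individually):
#   blocks 1..7: conv,act,pool, conv,act,pool, conv,act   (8 layers each)
#   block  8   : conv,act,pool, conv,act,pool             (6 layers)
# giving 8 weight blocks, 23 convs + 23 activations + 16 pools = 62
# processing layers, plus the 2 classifying layers.

#' Model configuration for the sequential feature extractor
#'
#' @param n_classes Number of output classes.
#' @param input_channels,input_length Window geometry (channels x samples);
#'   defaults 4 x 1000.
#' @param channels Output channel width of each of the 8 weight blocks.
#' @param kernel_len Convolution kernel length in samples.
#' @param hidden_units Width of the first fully connected classifying layer.
#' @param triplet_margin Margin of the triplet objective.
#' @param loss_mix Weight `lambda` of the triplet term in the combined loss
#'   `lambda * triplet + (1 - lambda) * cross-entropy`.
#' @param batch_size Minibatch size (default 64).
#' @param epochs Default number of training epochs (default 100).
#' @param n_weight_blocks,n_processing_layers,n_classifying_layers Layer
#'   accounting; the fixed block layout implies `8 * n_weight_blocks - 2`
#'   processing layers, and inconsistent values are rejected.
#' @return A validated `laryx_sfe_config` list.
#' @export
sfe_config <- function(n_classes,
                       input_channels = 4, input_length = 1000,
                       channels = c(8, 8, 12, 12, 16, 16, 16, 16),
                       kernel_len = 7,
                       hidden_units = 32,
                       triplet_margin = 1,
                       loss_mix = 0.5,
                       batch_size = 64,
                       epochs = 100,
                       n_weight_blocks = 8,
                       n_processing_layers = 62,
                       n_classifying_layers = 2) {
  check_scalar(n_classes, "n_classes", lower = 2)
  check_scalar(batch_size, "batch_size", lower = 2)
  check_scalar(epochs, "epochs", lower = 1)
  check_scalar(loss_mix, "loss_mix", lower = 0, upper = 1)
  if (kernel_len %% 2 != 1) abort("`kernel_len` must be odd (same-padding).")
  if (length(channels) != n_weight_blocks) {
    abort(sprintf("`channels` must give one width per weight block (%d).",
                  n_weight_blocks))
  }
  implied <- 8L * n_weight_blocks - 2L
  if (n_processing_layers != implied) {
    abort(sprintf(
      paste0("Inconsistent layer accounting: %d weight blocks of ",
             "(conv,act,pool,conv,act,pool,conv,act) with a final ",
             "(conv,act,pool,conv,act,pool) block give 8*%d - 2 = %d ",
             "processing layers, not %d."),
      n_weight_blocks, n_weight_blocks, implied, n_processing_layers))
  }
  if (n_classifying_layers != 2L) {
    abort("The classifying head has exactly 2 fully connected layers.")
  }
  structure(list(
    n_classes = as.integer(n_classes),
    input_channels = as.integer(input_channels),
    input_length = as.integer(input_length),
    channels = as.integer(channels),
    kernel_len = as.integer(kernel_len),
    hidden_units = as.integer(hidden_units),
    triplet_margin = triplet_margin,
    loss_mix = loss_mix,
    batch_size = as.integer(batch_size),
    epochs = as.integer(epochs),
    n_weight_blocks = as.integer(n_weight_blocks),
    n_processing_layers = as.integer(n_processing_layers),
    n_classifying_layers = as.integer(n_classifying_layers)
  ), class = "laryx_sfe_config")
}

# Per-block op sequences of the fixed layout.
block_ops <- function(b, n_blocks) {
  if (b < n_blocks) {
    c("conv", "act", "pool", "conv", "act", "pool", "conv", "act")
  } else {
    c("conv", "act", "pool", "conv", "act", "pool")
  }
}

#' Build a sequential feature-extractor model
#'
#' Seeded He-normal initialization of all convolution and fully connected
#' parameters under the fixed 8-block / 62-processing-layer / 2-classifying-
#' layer layout.
#'
#' @param config An [sfe_config()].
#' @param seed Integer seed; the same seed gives identical initial parameters.
#' @return A `laryx_sfe` model object.
#' @export
build_sfe <- function(config, seed = 1) {
  stopifnot(inherits(config, "laryx_sfe_config"))
  k <- config$kernel_len
  ops <- list()
  convs <- list()
  len <- config$input_length
  cin <- config$input_channels
  with_seed(seed, {
    for (b in seq_len(config$n_weight_blocks)) {
      cout <- config$channels[b]
      for (op in block_ops(b, config$n_weight_blocks)) {
        if (op == "conv") {
          fan_in <- k * cin
          # He scaling by the effective fan-in: at short feature maps the
          # same-padded kernel only ever sees min(k, len) samples
          fan_eff <- min(k, len) * cin
          W <- matrix(rnorm(fan_in * cout, 0, sqrt(2 / fan_eff)),
                      nrow = fan_in, ncol = cout)
          convs[[length(convs) + 1L]] <- list(W = W, b = numeric(cout))
          ops[[length(ops) + 1L]] <- list(type = "conv", id = length(convs),
                                          block = b, cin = cin, cout = cout)
          cin <- cout
        } else if (op == "pool") {
          len <- ceiling(len / 2)
          ops[[length(ops) + 1L]] <- list(type = "pool", block = b)
        } else {
          ops[[length(ops) + 1L]] <- list(type = "act", block = b)
        }
      }
    }
    emb <- len * cin
    fc1 <- list(W = matrix(rnorm(emb * config$hidden_units, 0, sqrt(2 / emb)),
                           nrow = emb),
                b = numeric(config$hidden_units))
    fc2 <- list(W = matrix(rnorm(config$hidden_units * config$n_classes, 0,
                                 sqrt(2 / config$hidden_units)),
                           nrow = config$hidden_units),
                b = numeric(config$n_classes))
    structure(list(config = config, ops = ops, convs = convs,
                   fc1 = fc1, fc2 = fc2,
                   final_length = len, final_channels = cin,
                   embedding_dim = emb, seed = seed,
                   classes = NULL),
              class = "laryx_sfe")
  })
}

#' Layer census of a model
#'
#' @param model A `laryx_sfe`.
#' @return A list with `n_weight_blocks`, `n_processing_layers` (convolution,
#'   pooling and activation layers counted individually), `n_classifying_layers`
#'   and the per-type counts.
#' @export
layer_census <- function(model) {
  stopifnot(inherits(model, "laryx_sfe"))
  types <- vapply(model$ops, `[[`, character(1), "type")
  list(
    n_weight_blocks = model$config$n_weight_blocks,
    n_processing_layers = length(types),
    n_classifying_layers = 2L,
    n_conv = sum(types == "conv"),
    n_pool = sum(types == "pool"),
    n_act = sum(types == "act")
  )
}

#' @export
print.laryx_sfe <- function(x, ...) {
  cen <- layer_census(x)
  cat(sprintf(
    "<laryx_sfe> %d weight blocks, %d processing layers (%d conv / %d pool / %d act), 2 classifying layers\n",
    cen$n_weight_blocks, cen$n_processing_layers, cen$n_conv, cen$n_pool,
    cen$n_act))
  cat(sprintf("  input %d x %d -> embedding %d -> %d classes\n",
              x$config$input_channels, x$config$input_length,
              x$embedding_dim, x$config$n_classes))
  invisible(x)
}

# ---- forward / backward primitives on [B, L, C] arrays ----------------------

conv1d_forward <- function(X, W, bias, k) {
  d <- dim(X)
  B <- d[1]; L <- d[2]; Cin <- d[3]
  p <- (k - 1L) %/% 2L
  Xp <- array(0, c(B, L + 2L * p, Cin))
  Xp[, p + seq_len(L), ] <- X
  M <- matrix(0, nrow = B * L, ncol = k * Cin)
  for (j in seq_len(k)) {
    M[, ((j - 1L) * Cin + 1L):(j * Cin)] <-
      matrix(Xp[, j:(j + L - 1L), , drop = FALSE], nrow = B * L)
  }
  Y <- M %*% W
  Y <- sweep(Y, 2, bias, "+")
  list(Y = array(Y, c(B, L, ncol(W))), M = M)
}

conv1d_backward <- function(dY, M, W, dimX, k) {
  B <- dimX[1]; L <- dimX[2]; Cin <- dimX[3]
  dYm <- matrix(dY, nrow = B * L)
  dW <- crossprod(M, dYm)
  db <- colSums(dYm)
  dM <- tcrossprod(dYm, W)  # (B*L) x (k*Cin)
  p <- (k - 1L) %/% 2L
  dXp <- array(0, c(B, L + 2L * p, Cin))
  for (j in seq_len(k)) {
    dXp[, j:(j + L - 1L), ] <- dXp[, j:(j + L - 1L), , drop = FALSE] +
      array(dM[, ((j - 1L) * Cin + 1L):(j * Cin)], c(B, L, Cin))
  }
  list(dX = dXp[, p + seq_len(L), , drop = FALSE], dW = dW, db = db)
}

maxpool_forward <- function(X) {
  d <- dim(X)
  B <- d[1]; L <- d[2]; C <- d[3]
  Lo <- ceiling(L / 2)
  Xp <- array(-Inf, c(B, 2L * Lo, C))
  Xp[, seq_len(L), ] <- X
  A <- Xp[, seq(1L, 2L * Lo, by = 2L), , drop = FALSE]
  Bv <- Xp[, seq(2L, 2L * Lo, by = 2L), , drop = FALSE]
  mask <- A >= Bv  # ties keep the earlier sample
  list(Y = pmax(A, Bv), mask = mask, L_in = L)
}

maxpool_backward <- function(dY, mask, L_in) {
  d <- dim(dY)
  B <- d[1]; Lo <- d[2]; C <- d[3]
  dXp <- array(0, c(B, 2L * Lo, C))
  dXp[, seq(1L, 2L * Lo, by = 2L), ] <- dY * mask
  dXp[, seq(2L, 2L * Lo, by = 2L), ] <- dY * !mask
  dXp[, seq_len(L_in), , drop = FALSE]
}

# Forward pass. X: [B, L, C]. Returns embeddings, hidden, probabilities and
# (optionally) the caches needed for backprop.
sfe_forward <- function(model, X, cache = FALSE) {
  caches <- if (cache) vector("list", length(model$ops)) else NULL
  for (i in seq_along(model$ops)) {
    op <- model$ops[[i]]
    if (op$type == "conv") {
      cv <- model$convs[[op$id]]
      res <- conv1d_forward(X, cv$W, cv$b, model$config$kernel_len)
      if (cache) caches[[i]] <- list(M = res$M, dimX = dim(X))
      X <- res$Y
    } else if (op$type == "act") {
      if (cache) caches[[i]] <- list(mask = X > 0)
      X <- leaky_relu(X)
    } else {
      res <- maxpool_forward(X)
      if (cache) caches[[i]] <- list(mask = res$mask, L_in = res$L_in)
      X <- res$Y
    }
  }
  B <- dim(X)[1]
  E <- matrix(X, nrow = B)                     # B x embedding_dim
  Z1 <- sweep(E %*% model$fc1$W, 2, model$fc1$b, "+")
  H <- leaky_relu(Z1)
  logits <- sweep(H %*% model$fc2$W, 2, model$fc2$b, "+")
  P <- softmax_rows(logits)
  list(E = E, Z1 = Z1, H = H, P = P, caches = caches,
       final_dim = dim(X))
}

# Leaky rectifier (slope 0.1 on the negative side): keeps gradient alive
# through the deep plain conv stack.
leaky_relu <- function(x) pmax(x, 0) + 0.1 * pmin(x, 0)
leaky_grad <- function(mask) 0.1 + 0.9 * mask

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

# Backward pass. dlogits: gradient at the (pre-softmax) logits already scaled
# by the cross-entropy weight; dE_extra: gradient arriving directly at the
# embedding (triplet term, already scaled). Returns gradients for every
# parameter tensor, in the model's structure.
sfe_backward <- function(model, fw, dlogits, dE_extra = NULL) {
  dW2 <- crossprod(fw$H, dlogits)
  db2 <- colSums(dlogits)
  dH <- tcrossprod(dlogits, model$fc2$W)
  dZ1 <- dH * leaky_grad(fw$Z1 > 0)
  dW1 <- crossprod(fw$E, dZ1)
  db1 <- colSums(dZ1)
  dE <- tcrossprod(dZ1, model$fc1$W)
  if (!is.null(dE_extra)) dE <- dE + dE_extra
  dX <- array(dE, fw$final_dim)
  g_convs <- vector("list", length(model$convs))
  for (i in rev(seq_along(model$ops))) {
    op <- model$ops[[i]]
    cc <- fw$caches[[i]]
    if (op$type == "conv") {
      res <- conv1d_backward(dX, cc$M, model$convs[[op$id]]$W, cc$dimX,
                             model$config$kernel_len)
      g_convs[[op$id]] <- list(W = res$dW, b = res$db)
      dX <- res$dX
    } else if (op$type == "act") {
      dX <- dX * leaky_grad(cc$mask)
    } else {
      dX <- maxpool_backward(dX, cc$mask, cc$L_in)
    }
  }
  list(convs = g_convs,
       fc1 = list(W = dW1, b = db1),
       fc2 = list(W = dW2, b = db2))
}
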