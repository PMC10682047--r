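test_that("the layer census is 8 weight blocks, 62 processing, 2 classifying", {
  model <- build_sfe(sfe_config(n_classes = 13), seed = 1)
  cen <- layer_census(model)
  expect_equal(cen$n_weight_blocks, 8)
  expect_equal(cen$n_processing_layers, 62)
  expect_equal(cen$n_classifying_layers, 2)
  expect_equal(cen$n_conv + cen$n_pool + cen$n_act, 62)

  expect_error(sfe_config(n_classes = 13, n_processing_layers = 60),
               "Inconsistent layer accounting")
  expect_error(sfe_config(n_classes = 13, n_classifying_layers = 3),
               "2 fully connected")
})

test_that("forward passes give normalized probabilities and seeded init", {
  model <- build_sfe(sfe_config(n_classes = 5), seed = 3)
  pr <- predict(model, matrix(0, 4, 1000))
  expect_equal(sum(pr$probs), 1, tolerance = 1e-6)
  pr2 <- predict(model, array(rnorm(4 * 1000 * 3), c(4, 1000, 3)))
  expect_equal(rowSums(pr2$probs), rep(1, 3), tolerance = 1e-6)
  expect_length(pr2$class_id, 3)

  model2 <- build_sfe(sfe_config(n_classes = 5), seed = 3)
  expect_identical(model$convs, model2$convs)
  expect_identical(model$fc1, model2$fc1)

  expect_error(predict(model, matrix(0, 3, 1000)), "4 x 1000")
})

test_that("backpropagation matches numerical gradients on a tiny model", {
  cfg <- sfe_config(n_classes = 3, input_channels = 2, input_length = 32,
                    channels = rep(3, 8), kernel_len = 3, hidden_units = 5)
  model <- build_sfe(cfg, seed = 2)
  set.seed(1)
  X <- array(rnorm(4 * 32 * 2), c(4, 32, 2))
  Y <- one_hot(c(1, 2, 3, 1), 3)
  loss_of <- function(m) {
    fw <- sfe_forward(m, X)
    cross_entropy_loss(fw$P, Y)
  }
  fw <- sfe_forward(model, X, cache = TRUE)
  g <- sfe_backward(model, fw, (fw$P - Y) / 4)
  eps <- 1e-5
  for (probe in list(c(1, 2, 1), c(2, 1, 2))) {
    ci <- probe[1]
    m_plus <- m_minus <- model
    m_plus$convs[[ci]]$W[probe[2], probe[3]] <-
      m_plus$convs[[ci]]$W[probe[2], probe[3]] + eps
    m_minus$convs[[ci]]$W[probe[2], probe[3]] <-
      m_minus$convs[[ci]]$W[probe[2], probe[3]] - eps
    num <- (loss_of(m_plus) - loss_of(m_minus)) / (2 * eps)
    expect_equal(g$convs[[ci]]$W[probe[2], probe[3]], num, tolerance = 1e-5)
  }
  m_plus <- m_minus <- model
  m_plus$fc1$W[1, 1] <- m_plus$fc1$W[1, 1] + eps
  m_minus$fc1$W[1, 1] <- m_minus$fc1$W[1, 1] - eps
  num <- (loss_of(m_plus) - loss_of(m_minus)) / (2 * eps)
  expect_equal(g$fc1$W[1, 1], num, tolerance = 1e-5)
})

test_that("the learning-rate schedule matches its printed and annealed forms", {
  cfg <- lr_schedule_config(iLR = 1e-4, epochs = 100, mode = "as_printed")
  # cosine zero: x + pi/epochs = pi/2
  x0 <- pi / 2 - pi / 100
  expect_equal(lr_schedule(x0, cfg), 1 - 1e-4, tolerance = 1e-12)
  expect_equal(lr_schedule(0, cfg), (1 + 0.5 * cos(pi / 100)) * (1 - 1e-4),
               tolerance = 1e-12)
  expect_equal(round(lr_schedule(0, cfg), 4), 1.4996)

  ann <- lr_schedule_config(iLR = 1e-3, epochs = 50, mode = "cosine_annealing")
  expect_equal(lr_schedule(0, ann), 1e-3)
  expect_equal(lr_schedule(50, ann), 0, tolerance = 1e-18)
  expect_true(all(diff(lr_schedule(0:50, ann)) < 0))
})

test_that("the optimizer follows the attenuation-rate update rule", {
  st <- init_optimizer(0, adam_config())
  # first step, scalar gradient 1: bias-corrected ratio is 1/(eps + 1)
  out <- optimizer_step(st, 1, lr = 0.05, params = 0)
  expect_equal(out$deltas$par, 0.05 / (1e-8 + 1), tolerance = 1e-10)
  expect_equal(out$params$par, -0.05 / (1e-8 + 1), tolerance = 1e-10)
  expect_equal(out$state$AR, 0.9 - 0.05 / (1e-8 + 1), tolerance = 1e-10)

  # zero gradient: nothing moves, AR unchanged
  st0 <- init_optimizer(list(a = 1, b = 2))
  out0 <- optimizer_step(st0, list(a = 0, b = 0), lr = 0.1,
                         params = list(a = 1, b = 2))
  expect_equal(out0$params, list(a = 1, b = 2), ignore_attr = TRUE)
  expect_equal(out0$state$AR, 0.9)

  # repeated identical gradients: m_t approaches g monotonically
  st <- init_optimizer(0)
  ms <- numeric(20)
  for (i in 1:20) {
    out <- optimizer_step(st, 1, lr = 0.01, params = 0)
    st <- out$state
    ms[i] <- st$m$par
  }
  expect_true(all(diff(ms) > 0))
  expect_equal(ms, 1 - 0.9^(1:20), tolerance = 1e-12)

  expect_error(optimizer_step(init_optimizer(0), NaN, 0.1), "Non-finite")
})

test_that("the optimizer minimizes an analytic quadratic", {
  # f(x) = 0.5 * (x - 3)^2, gradient x - 3
  st <- init_optimizer(0)
  x <- 0
  for (i in 1:500) {
    out <- optimizer_step(st, x - 3, lr = 0.05, params = x)
    st <- out$state
    x <- out$params$par
    if (abs(x - 3) < 1e-3) break
  }
  expect_lt(abs(x - 3), 1e-3)
})

test_that("loss functions reproduce their closed forms", {
  expect_equal(triplet_loss(c(1, 2), c(1, 2), c(5, 5), margin = 1), 0)
  expect_equal(triplet_loss(c(1, 2), c(1, 2), c(1, 2), margin = 1), 1)
  expect_equal(triplet_loss(c(0, 0), c(1, 0), c(0, 3), margin = 1), 0)
  expect_equal(triplet_loss(c(0, 0), c(1, 0), c(0, 3), margin = 3), 1)
  expect_error(triplet_loss(c(0, 0), c(1, 0, 0), c(0, 3)), "dimensions")

  perfect <- one_hot(c(1, 2), 4)
  expect_lt(cross_entropy_loss(pmax(perfect, 1e-15), perfect), 1e-10)
  unif13 <- matrix(1 / 13, 2, 13)
  expect_equal(cross_entropy_loss(unif13, one_hot(c(4, 9), 13)), log(13),
               tolerance = 1e-12)
  unif4 <- matrix(1 / 4, 1, 4)
  expect_equal(cross_entropy_loss(unif4, one_hot(2, 4)), log(4),
               tolerance = 1e-12)
  expect_error(cross_entropy_loss(matrix(0.7, 1, 2), one_hot(1, 2)), "sum")
})
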