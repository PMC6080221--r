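# Numerical-gradient oracle: central finite differences.
numeric_gradient <- function(fn, theta, eps = 1e-5) {
  vapply(seq_along(theta), function(i) {
    e <- numeric(length(theta)); e[i] <- eps
    (fn(theta + e) - fn(theta - e)) / (2 * eps)
  }, numeric(1))
}

rel_err <- function(a, b) max(abs(a - b) / pmax(1, abs(a) + abs(b)))

test_that("autoencoder analytic gradients match finite differences", {
  set.seed(51)
  hyper <- sae_hyperparams(hidden_sizes = 4)
  x <- matrix(runif(7 * 5), 7, 5)
  theta <- rnorm(4 * 5 + 4 + 5 * 4 + 5, sd = 0.5)
  out <- sae_cost(theta, x, hyper, hidden = 4)
  num <- numeric_gradient(function(t) sae_cost(t, x, hyper, 4)$cost, theta)
  expect_lt(rel_err(out$grad, num), 1e-6)
})

test_that("softmax and full-network gradients match finite differences", {
  set.seed(52)
  hyper <- sae_hyperparams(hidden_sizes = c(4, 3))
  n <- 9
  h <- matrix(runif(n * 6), n, 6)
  y <- sample(1:4, n, replace = TRUE)
  theta <- rnorm(4 * 6 + 4, sd = 0.5)
  out <- myograsp:::softmax_cost(theta, h, y, 4, hyper$lambda_decay)
  num <- numeric_gradient(function(t)
    myograsp:::softmax_cost(t, h, y, 4, hyper$lambda_decay)$cost, theta)
  expect_lt(rel_err(out$grad, num), 1e-6)
  # end-to-end networks, both head kinds
  x <- matrix(runif(n * 5), n, 5)
  scaler <- list(lo = rep(0, 5), range = rep(1, 5))
  layers <- list(list(W = matrix(rnorm(4 * 5, sd = .5), 4, 5), b = rnorm(4)),
                 list(W = matrix(rnorm(3 * 4, sd = .5), 3, 4), b = rnorm(3)))
  cls <- myograsp:::new_sae_model(layers,
                                  list(W = matrix(rnorm(4 * 3, sd = .5), 4, 3),
                                       b = rnorm(4), k_classes = 4),
                                  "classifier", hyper, scaler)
  th <- myograsp:::sae_pack(cls)
  out <- myograsp:::sae_model_cost(th, cls, x, y)
  num <- numeric_gradient(function(t)
    myograsp:::sae_model_cost(t, cls, x, y)$cost, th)
  expect_lt(rel_err(out$grad, num), 1e-6)
  reg <- myograsp:::new_sae_model(layers,
                                  list(W = matrix(rnorm(3, sd = .5), 1, 3),
                                       b = 0.2),
                                  "regressor", hyper, scaler)
  thr <- myograsp:::sae_pack(reg)
  fr <- runif(n, 0, 40)
  out <- myograsp:::sae_model_cost(thr, reg, x, fr)
  num <- numeric_gradient(function(t)
    myograsp:::sae_model_cost(t, reg, x, fr)$cost, thr)
  expect_lt(rel_err(out$grad, num), 1e-6)
})

test_that("the sparsity penalty vanishes exactly at the target activation", {
  expect_identical(myograsp:::kl_bernoulli(0.1, rep(0.1, 20)), 0)
  expect_gt(myograsp:::kl_bernoulli(0.1, rep(0.3, 20)), 0)
  # clamping keeps the penalty finite at degenerate activations
  expect_true(is.finite(myograsp:::kl_bernoulli(0.1, c(0, 1))))
})

test_that("perfect reconstruction with no penalties costs zero", {
  hyper <- sae_hyperparams(hidden_sizes = 3, lambda_decay = 0,
                           beta_sparsity = 0)
  # W = 0 everywhere: hidden = 0.5; with decoder bias = logit(c) the
  # constant input c is reconstructed exactly
  cc <- 0.73
  x <- matrix(cc, 10, 4)
  theta <- c(rep(0, 3 * 4 + 3 + 4 * 3), rep(log(cc / (1 - cc)), 4))
  out <- sae_cost(theta, x, hyper, hidden = 3)
  expect_equal(out$cost, 0, tolerance = 1e-12)
})

test_that("pretraining reduces reconstruction cost deterministically", {
  set.seed(53)
  x <- matrix(runif(60 * 6, 0.2, 0.8), 60, 6)
  hyper <- sae_hyperparams(hidden_sizes = c(5, 4), pretrain_iters = 30)
  l1 <- train_autoencoder(x, 5, hyper, seed = 9)
  expect_lt(l1$cost_final, l1$cost_initial)
  stack1 <- pretrain_stack(x, hyper, seed = 2)
  stack2 <- pretrain_stack(x, hyper, seed = 2)
  expect_identical(stack1, stack2)
  stack3 <- pretrain_stack(x, hyper, seed = 3)
  expect_false(identical(stack1[[1]]$W, stack3[[1]]$W))
})

test_that("near-affine rank-1 inputs are captured by one hidden unit", {
  set.seed(54)
  t <- runif(80)
  direction <- c(0.2, -0.15, 0.1, 0.25)
  x <- 0.5 + outer(t - 0.5, direction)          # 1-D affine manifold
  hyper <- sae_hyperparams(hidden_sizes = 1, lambda_decay = 0,
                           beta_sparsity = 0, pretrain_iters = 400)
  l1 <- train_autoencoder(x, 1, hyper, seed = 6, maxit = 400)
  baseline <- sum(sweep(x, 2, colMeans(x))^2) / 2   # mean-only reconstruction
  expect_lt(l1$cost_final, 0.02 * baseline)
})

test_that("softmax head separates well-separated classes", {
  set.seed(55)
  n <- 200
  y <- rep(1:2, each = n / 2)
  h <- matrix(rnorm(n * 2, sd = 0.15), n, 2) + cbind(y == 1, y == 2)
  hyper <- sae_hyperparams(head_iters = 100)
  head <- train_softmax_head(h, y, hyper, k_classes = 2)
  z <- h %*% t(head$W) + matrix(head$b, n, 2, byrow = TRUE)
  expect_gte(mean(max.col(z) == y), 0.99)
  expect_warning(train_softmax_head(h, y, hyper, k_classes = 3),
                 "absent")
})

test_that("softmax probabilities are a proper distribution with lower-tie argmax", {
  hyper <- sae_hyperparams(hidden_sizes = c(4, 4))
  scaler <- list(lo = rep(0, 3), range = rep(1, 3))
  layers <- list(list(W = matrix(0, 4, 3), b = rep(0, 4)),
                 list(W = matrix(0, 4, 4), b = rep(0, 4)))
  m <- myograsp:::new_sae_model(layers,
                                list(W = matrix(0, 8, 4), b = rep(0, 8),
                                     k_classes = 8),
                                "classifier", hyper, scaler)
  out <- predict_level(m, matrix(runif(15), 5, 3))
  expect_equal(unname(rowSums(out$probs)), rep(1, 5))
  expect_true(all(out$probs >= 0))
  # all-equal logits: uniform probabilities, ties resolve to level 1
  expect_equal(max(abs(out$probs - 1 / 8)), 0, tolerance = 1e-12)
  expect_identical(out$level, rep(1L, 5))
  set.seed(56)
  m$head$W <- matrix(rnorm(32), 8, 4)
  out2 <- predict_level(m, matrix(runif(15), 5, 3))
  expect_equal(unname(rowSums(out2$probs)), rep(1, 5))
  expect_identical(out2$level,
                   vapply(1:5, function(i) which.max(out2$probs[i, ]),
                          integer(1)))
})

test_that("fine-tuning monitors descent and honors zero iterations", {
  set.seed(57)
  x <- matrix(runif(100 * 4), 100, 4)
  y <- 1L + (x[, 1] > 0.5) + 2L * (x[, 2] > 0.5)   # 4 separable classes
  hyper <- sae_hyperparams(hidden_sizes = c(6, 6), pretrain_iters = 30,
                           head_iters = 50, finetune_iters = 50)
  scaler <- myograsp:::fit_minmax(x)
  xs <- myograsp:::apply_minmax(scaler, x)
  stack <- pretrain_stack(xs, hyper, seed = 7)
  head <- train_softmax_head(myograsp:::encode_stack(xs, stack), y, hyper,
                             k_classes = 4)
  m0 <- myograsp:::new_sae_model(stack, head, "classifier", hyper, scaler)
  cost0 <- myograsp:::sae_model_cost(myograsp:::sae_pack(m0), m0, xs, y)$cost
  m1 <- finetune(m0, x, y)
  expect_lte(m1$cost_final, cost0)
  expect_gt(length(m1$trajectory), 0)
  expect_identical(finetune(m0, x, y, maxit = 0), m0)
  # fine-tuning helps (or at least never hurts) training accuracy here
  acc0 <- mean(predict_level(m0, x)$level == y)
  acc1 <- mean(predict_level(m1, x)$level == y)
  expect_gte(acc1, acc0)
  expect_gte(acc1, 0.97)
})

test_that("an 8-class separable problem is learned far above chance", {
  set.seed(58)
  n_per <- 40
  y <- rep(1:8, each = n_per)
  centers <- cbind(seq(0, 7), seq(7, 0))
  x <- centers[y, ] + matrix(rnorm(8 * n_per * 2, sd = 0.12), ncol = 2)
  test_idx <- unlist(lapply(0:7, function(k) k * n_per + 1:10))
  hyper <- sae_hyperparams(hidden_sizes = c(20, 20), pretrain_iters = 40,
                           head_iters = 80, finetune_iters = 80)
  fp <- train_force_predictor(x[-test_idx, ], y[-test_idx], hyper = hyper,
                              scheme = level_scheme(8, 0, 40), seed = 5,
                              train_regressors = FALSE)
  acc <- mean(predict_level(fp, x[test_idx, ])$level == y[test_idx])
  expect_gte(acc, 0.90)
})

test_that("training is reproducible and encoding is stable", {
  set.seed(59)
  x <- matrix(runif(90 * 3), 90, 3)
  y <- 1L + (x[, 1] > 0.5)
  hyper <- sae_hyperparams(hidden_sizes = c(5, 5), pretrain_iters = 20,
                           head_iters = 30, finetune_iters = 30)
  fp1 <- train_force_predictor(x, y, hyper = hyper,
                               scheme = level_scheme(2, 0, 10), seed = 21,
                               train_regressors = FALSE)
  fp2 <- train_force_predictor(x, y, hyper = hyper,
                               scheme = level_scheme(2, 0, 10), seed = 21,
                               train_regressors = FALSE)
  expect_identical(fp1, fp2)
  p1 <- predict_level(fp1, x)
  p2 <- predict_level(fp1, x)
  expect_identical(p1, p2)
})
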