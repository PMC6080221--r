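# Stacked sparse autoencoder, written out explicitly: sigmoid layers,
# squared-error reconstruction with weight decay and a KL sparsity
# penalty, greedy layer-wise pretraining, then supervised heads (softmax
# for level classification, linear for per-level force regression) and
# end-to-end fine-tuning by backpropagation. Optimization uses
# deterministic L-BFGS-B on the full batch; all initialization is seeded.

#' Hyperparameters of the stacked sparse autoencoder
#'
#' Defaults: two hidden layers of 200 units, desired average hidden
#' activation rho = 0.1, weight decay lambda = 3e-3, sparsity weight
#' beta = 1.
#'
#' @param hidden_sizes hidden layer widths.
#' @param rho desired average activation of hidden units, in (0, 1).
#' @param lambda_decay weight-decay coefficient (>= 0).
#' @param beta_sparsity sparsity-penalty weight (>= 0).
#' @param pretrain_iters L-BFGS iterations per layer-wise pretraining stage.
#' @param head_iters iterations for the head-only training stage.
#' @param finetune_iters iterations of end-to-end fine-tuning.
#' @param seed integer seed for weight initialization.
#' @return an object of class `sae_hyperparams`.
#' @export
sae_hyperparams <- function(hidden_sizes = c(200, 200), rho = 0.1,
                            lambda_decay = 3e-3, beta_sparsity = 1,
                            pretrain_iters = 100, head_iters = 100,
                            finetune_iters = 100, seed = 1L) {
  if (rho <= 0 || rho >= 1) stop_validation("rho must lie in (0, 1)")
  if (lambda_decay < 0 || beta_sparsity < 0)
    stop_validation("lambda_decay and beta_sparsity must be >= 0")
  if (length(hidden_sizes) < 1L || any(hidden_sizes < 1))
    stop_validation("hidden_sizes must be positive")
  structure(list(hidden_sizes = as.integer(hidden_sizes), rho = rho,
                 lambda_decay = lambda_decay, beta_sparsity = beta_sparsity,
                 pretrain_iters = as.integer(pretrain_iters),
                 head_iters = as.integer(head_iters),
                 finetune_iters = as.integer(finetune_iters),
                 seed = as.integer(seed)),
            class = "sae_hyperparams")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

add_bias <- function(z, b) z + matrix(b, nrow(z), length(b), byrow = TRUE)

# KL divergence between Bernoulli(rho) and Bernoulli(rho_hat), clamped
# away from 0/1 to avoid log(0).
kl_bernoulli <- function(rho, rho_hat) {
  rho_hat <- clamp(rho_hat, 1e-6, 1 - 1e-6)
  sum(rho * log(rho / rho_hat) + (1 - rho) * log((1 - rho) / (1 - rho_hat)))
}

# ---- min-max input scaling -------------------------------------------------

fit_minmax <- function(x) {
  lo <- apply(x, 2, min); hi <- apply(x, 2, max)
  rg <- hi - lo; rg[rg == 0] <- 1
  list(lo = lo, range = rg)
}

apply_minmax <- function(scaler, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  sweep(sweep(x, 2, scaler$lo), 2, scaler$range, "/")
}

# ---- parameter packing -----------------------------------------------------

# A shape spec is a list of (rows, cols) per weight matrix, with bias
# vectors interleaved: W1, b1, W2, b2, ...
pack_params <- function(mats) unlist(mats, use.names = FALSE)

unpack_params <- function(theta, shapes) {
  out <- vector("list", length(shapes))
  pos <- 0L
  for (i in seq_along(shapes)) {
    d <- shapes[[i]]
    len <- d[1] * d[2]
    out[[i]] <- if (d[2] == 1L && length(d) == 3L) theta[pos + seq_len(len)]
                else matrix(theta[pos + seq_len(len)], d[1], d[2])
    pos <- pos + len
  }
  out
}

shape_of <- function(mats) lapply(mats, function(m)
  if (is.matrix(m)) dim(m) else c(length(m), 1L, 1L))

# Seeded symmetric-uniform init scaled by fan-in/fan-out.
init_weights <- function(n_out, n_in) {
  r <- sqrt(6) / sqrt(n_in + n_out + 1)
  matrix(stats::runif(n_out * n_in, -r, r), n_out, n_in)
}

# ---- sparse autoencoder cost -----------------------------------------------

#' Cost and gradient of one sparse autoencoder
#'
#' cost = sum over rows of (1/2) squared reconstruction error
#'      + (lambda/2) * sum of squared weights
#'      + beta * sum_j KL(rho || rho_hat_j),
#' with rho_hat_j the mean activation of hidden unit j over the batch and
#' sigmoid transfer on both the hidden and the reconstruction layer.
#' The data term is summed (not averaged) over the batch: the weight
#' decay and sparsity coefficients are calibrated for that convention,
#' under which their defaults (3e-3 and 1) balance the three terms.
#' The gradient is computed by backpropagation.
#'
#' @param theta packed parameter vector `c(W1, b1, W2, b2)` with W1
#'   (hidden x d) and W2 (d x hidden).
#' @param x batch matrix (rows x d), values scaled to `[0, 1]`.
#' @param hyper an [sae_hyperparams()].
#' @param hidden hidden layer width.
#' @return list with `cost` (scalar) and `grad` (same length as `theta`).
#' @export
sae_cost <- function(theta, x, hyper, hidden) {
  n <- nrow(x); d <- ncol(x)
  if (n < 1L) stop_validation("empty batch")
  p <- unpack_params(theta, list(c(hidden, d), c(hidden, 1L, 1L),
                                 c(d, hidden), c(d, 1L, 1L)))
  W1 <- p[[1]]; b1 <- p[[2]]; W2 <- p[[3]]; b2 <- p[[4]]
  a1 <- sigmoid(add_bias(x %*% t(W1), b1))        # n x hidden
  a2 <- sigmoid(add_bias(a1 %*% t(W2), b2))       # n x d
  rho_hat <- clamp(colMeans(a1), 1e-6, 1 - 1e-6)
  rho <- hyper$rho; lam <- hyper$lambda_decay; beta <- hyper$beta_sparsity
  cost <- sum((a2 - x)^2) / 2 +
    lam / 2 * (sum(W1^2) + sum(W2^2)) +
    beta * kl_bernoulli(rho, rho_hat)
  d2 <- (a2 - x) * a2 * (1 - a2)                  # n x d
  sparse_grad <- beta * (-rho / rho_hat + (1 - rho) / (1 - rho_hat)) / n
  d1 <- (d2 %*% W2 + matrix(sparse_grad, n, hidden, byrow = TRUE)) *
    a1 * (1 - a1)
  grad <- pack_params(list(t(d1) %*% x + lam * W1, colSums(d1),
                           t(d2) %*% a1 + lam * W2, colSums(d2)))
  list(cost = cost, grad = grad)
}

# Deterministic batch optimizer: L-BFGS-B with a single cost+gradient
# evaluation per point (memoized between fn and gr calls).
optimize_cost <- function(theta0, cost_fun, maxit) {
  if (maxit < 1L) return(list(par = theta0, value = cost_fun(theta0)$cost,
                              trajectory = numeric(0)))
  cache <- new.env(parent = emptyenv())
  trajectory <- numeric(0)
  eval_at <- function(theta) {
    if (!is.null(cache$theta) && identical(theta, cache$theta))
      return(cache$out)
    out <- cost_fun(theta)
    if (!is.finite(out$cost))
      stop("non-finite training cost (", out$cost, "); aborting")
    cache$theta <- theta; cache$out <- out
    trajectory <<- c(trajectory, out$cost)
    out
  }
  res <- stats::optim(theta0, fn = function(t) eval_at(t)$cost,
                      gr = function(t) eval_at(t)$grad,
                      method = "L-BFGS-B",
                      control = list(maxit = maxit))
  list(par = res$par, value = res$value, trajectory = trajectory)
}

#' Train a single sparse autoencoder layer
#'
#' @param x input batch (rows x d), scaled to `[0, 1]`.
#' @param hidden hidden width.
#' @param hyper an [sae_hyperparams()].
#' @param seed seed for the weight initialization.
#' @param maxit L-BFGS iterations (default `hyper$pretrain_iters`).
#' @return list with encoder `W` (hidden x d), `b`, decoder weights, and
#'   the initial/final costs.
#' @export
train_autoencoder <- function(x, hidden, hyper, seed,
                              maxit = hyper$pretrain_iters) {
  d <- ncol(x)
  theta0 <- with_seed(seed, pack_params(list(
    init_weights(hidden, d), numeric(hidden),
    init_weights(d, hidden), numeric(d))))
  cost0 <- sae_cost(theta0, x, hyper, hidden)$cost
  fit <- optimize_cost(theta0, function(t) sae_cost(t, x, hyper, hidden),
                       maxit)
  p <- unpack_params(fit$par, list(c(hidden, d), c(hidden, 1L, 1L),
                                   c(d, hidden), c(d, 1L, 1L)))
  list(W = p[[1]], b = p[[2]], W_dec = p[[3]], b_dec = p[[4]],
       cost_initial = cost0, cost_final = fit$value)
}

encode_layer <- function(x, layer) sigmoid(add_bias(x %*% t(layer$W), layer$b))

# Encode rows through the full stack.
encode_stack <- function(x, layers) {
  for (l in layers) x <- encode_layer(x, l)
  x
}

#' Greedy layer-wise pretraining of the encoder stack
#'
#' Layer 1 is trained as a sparse autoencoder on the inputs; each further
#' layer is trained on the previous layer's hidden activations.
#'
#' @param x training rows (scaled to `[0, 1]`).
#' @param hyper an [sae_hyperparams()].
#' @param seed master seed; per-layer seeds derive via [split_seed()].
#' @return list of encoder layers (each with `W`, `b`, training costs).
#' @export
pretrain_stack <- function(x, hyper, seed = hyper$seed) {
  layers <- vector("list", length(hyper$hidden_sizes))
  a <- x
  for (i in seq_along(hyper$hidden_sizes)) {
    layers[[i]] <- train_autoencoder(a, hyper$hidden_sizes[i], hyper,
                                     seed = split_seed(seed, i))
    a <- encode_layer(a, layers[[i]])
  }
  layers
}

# ---- heads -----------------------------------------------------------------

# Softmax cross-entropy cost with weight decay; theta = c(W, b), W (K x h).
softmax_cost <- function(theta, h, y, k_classes, lambda) {
  n <- nrow(h)
  p <- unpack_params(theta, list(c(k_classes, ncol(h)), c(k_classes, 1L, 1L)))
  W <- p[[1]]; b <- p[[2]]
  z <- add_bias(h %*% t(W), b)
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  probs <- ez / rowSums(ez)
  idx <- cbind(seq_len(n), y)
  cost <- -sum(log(pmax(probs[idx], 1e-300))) + lambda / 2 * sum(W^2)
  dz <- probs
  dz[idx] <- dz[idx] - 1
  list(cost = cost,
       grad = pack_params(list(t(dz) %*% h + lambda * W, colSums(dz))),
       probs = probs)
}

#' Train the softmax classification head on encoded rows
#'
#' @param h encoded training rows (rows x hidden).
#' @param y integer labels in `1..k_classes`.
#' @param hyper an [sae_hyperparams()].
#' @param k_classes number of classes (default `max(y)`).
#' @return list with `W` (K x hidden), `b`, `k_classes`.
#' @export
train_softmax_head <- function(h, y, hyper, k_classes = max(y)) {
  y <- as.integer(y)
  missing_classes <- setdiff(seq_len(k_classes), unique(y))
  if (length(missing_classes))
    warning("classes absent from training data: ",
            paste(missing_classes, collapse = ", "))
  theta0 <- numeric(k_classes * ncol(h) + k_classes)  # convex: zero init
  fit <- optimize_cost(theta0,
                       function(t) softmax_cost(t, h, y, k_classes,
                                                hyper$lambda_decay),
                       hyper$head_iters)
  p <- unpack_params(fit$par, list(c(k_classes, ncol(h)),
                                   c(k_classes, 1L, 1L)))
  list(W = p[[1]], b = p[[2]], k_classes = k_classes)
}

# ---- full networks ---------------------------------------------------------

sae_shapes <- function(model) {
  c(unlist(lapply(model$layers, function(l)
      list(dim(l$W), c(length(l$b), 1L, 1L))), recursive = FALSE),
    list(dim(model$head$W), c(length(model$head$b), 1L, 1L)))
}

sae_pack <- function(model) {
  pack_params(c(unlist(lapply(model$layers, function(l) list(l$W, l$b)),
                       recursive = FALSE),
                list(model$head$W, model$head$b)))
}

sae_unpack <- function(model, theta) {
  p <- unpack_params(theta, sae_shapes(model))
  nl <- length(model$layers)
  for (i in seq_len(nl)) {
    model$layers[[i]]$W <- p[[2 * i - 1]]
    model$layers[[i]]$b <- p[[2 * i]]
  }
  model$head$W <- p[[2 * nl + 1]]
  model$head$b <- p[[2 * nl + 2]]
  model
}

# End-to-end cost of a full network (encoder stack + head).
# head_kind "classifier": softmax cross-entropy; "regressor": half mean
# squared error on the scalar linear output. Weight decay on all weights.
sae_model_cost <- function(theta, model, x, target) {
  m <- sae_unpack(model, theta)
  lam <- m$hyper$lambda_decay
  acts <- list(x)
  for (l in m$layers) acts[[length(acts) + 1L]] <- encode_layer(acts[[length(acts)]], l)
  h <- acts[[length(acts)]]
  n <- nrow(x)
  W <- m$head$W; b <- m$head$b
  if (m$head_kind == "classifier") {
    z <- add_bias(h %*% t(W), b)
    z <- z - apply(z, 1, max)
    ez <- exp(z)
    probs <- ez / rowSums(ez)
    idx <- cbind(seq_len(n), as.integer(target))
    cost <- -sum(log(pmax(probs[idx], 1e-300)))
    dz <- probs; dz[idx] <- dz[idx] - 1
  } else {
    pred <- as.numeric(h %*% t(W)) + b
    cost <- sum((pred - target)^2) / 2
    dz <- matrix(pred - target, ncol = 1)
  }
  decay <- sum(W^2) + sum(vapply(m$layers, function(l) sum(l$W^2), numeric(1)))
  cost <- cost + lam / 2 * decay
  gW_head <- t(dz) %*% h + lam * W
  gb_head <- colSums(dz)
  delta <- dz %*% W
  grads <- vector("list", 2 * length(m$layers))
  for (i in rev(seq_along(m$layers))) {
    a <- acts[[i + 1L]]
    delta <- delta * a * (1 - a)
    grads[[2 * i - 1]] <- t(delta) %*% acts[[i]] + lam * m$layers[[i]]$W
    grads[[2 * i]] <- colSums(delta)
    delta <- delta %*% m$layers[[i]]$W
  }
  list(cost = cost, grad = pack_params(c(grads, list(gW_head, gb_head))))
}

#' Fine-tune a full network end-to-end by backpropagation
#'
#' @param model an `sae_model` (classifier or regressor).
#' @param x training rows on the model's input scale (pre min-max scaling
#'   is applied internally via the model's stored scaler).
#' @param target integer labels (classifier) or force values in newtons
#'   (regressor).
#' @param maxit iterations (default `model$hyper$finetune_iters`); 0
#'   returns the model unchanged.
#' @return the fine-tuned `sae_model` with a `trajectory` of training
#'   costs recorded.
#' @export
finetune <- function(model, x, target, maxit = model$hyper$finetune_iters) {
  stopifnot(inherits(model, "sae_model"))
  if (maxit < 1L) return(model)
  xs <- apply_minmax(model$scaler, x)
  fit <- optimize_cost(sae_pack(model),
                       function(t) sae_model_cost(t, model, xs, target),
                       maxit)
  out <- sae_unpack(model, fit$par)
  out$trajectory <- fit$trajectory
  out$cost_final <- fit$value
  out
}

new_sae_model <- function(layers, head, head_kind, hyper, scaler) {
  structure(list(layers = layers, head = head, head_kind = head_kind,
                 hyper = hyper, scaler = scaler, trajectory = numeric(0)),
            class = "sae_model")
}

#' @export
print.sae_model <- function(x, ...) {
  cat(sprintf("<sae_model> %s: %s -> %s\n", x$head_kind,
              paste(vapply(x$layers, function(l) ncol(l$W), integer(1)),
                    collapse = " -> "),
              if (x$head_kind == "classifier") paste0(x$head$k_classes,
                                                      " classes") else "1"))
  invisible(x)
}

# Forward pass of a fitted model on unscaled rows.
sae_forward <- function(model, x) {
  h <- encode_stack(apply_minmax(model$scaler, x), model$layers)
  if (model$head_kind == "classifier") {
    z <- add_bias(h %*% t(model$head$W), model$head$b)
    z <- z - apply(z, 1, max)
    ez <- exp(z)
    ez / rowSums(ez)
  } else {
    as.numeric(h %*% t(model$head$W)) + model$head$b
  }
}
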