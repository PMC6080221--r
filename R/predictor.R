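# Classify-then-regress force prediction: one stacked-sparse-autoencoder
# classifier recognizes the grasp-force level; a per-level regressor of
# the same architecture (linear output head) predicts the force value in
# newtons, routed by the predicted level.

#' Train the grasp-force predictor (classifier + per-level regressors)
#'
#' Pretrains one encoder stack on the (min-max scaled) training rows,
#' then trains and fine-tunes a softmax classifier over the levels plus,
#' per level, a linear-head regressor initialized from the same
#' pretrained stack and fine-tuned on that level's rows.
#'
#' @param x training rows (rows x d), typically PCA-reduced feature rows.
#' @param levels integer level label per row.
#' @param forces force feature (N) per row; used by the regressors.
#' @param hyper an [sae_hyperparams()].
#' @param scheme a [level_scheme()] (routing and output clipping).
#' @param seed master seed (defaults to `hyper$seed`).
#' @param train_regressors set FALSE to skip the per-level regressors
#'   (classification-only experiments).
#' @return an object of class `force_predictor`.
#' @export
train_force_predictor <- function(x, levels, forces = NULL,
                                  hyper = sae_hyperparams(),
                                  scheme = level_scheme(),
                                  seed = hyper$seed,
                                  train_regressors = !is.null(forces)) {
  x <- as.matrix(x)
  levels <- as.integer(levels)
  stopifnot(nrow(x) == length(levels))
  if (train_regressors && (is.null(forces) || length(forces) != nrow(x)))
    stop_validation("forces must be given (one per row) to train regressors")
  scaler <- fit_minmax(x)
  xs <- apply_minmax(scaler, x)
  stack <- pretrain_stack(xs, hyper, seed = split_seed(seed, 101L))
  h <- encode_stack(xs, stack)
  head <- train_softmax_head(h, levels, hyper, k_classes = scheme$n_levels)
  classifier <- new_sae_model(stack, head, "classifier", hyper, scaler)
  classifier <- finetune(classifier, x, levels)
  regressors <- vector("list", scheme$n_levels)
  if (train_regressors) {
    for (lv in seq_len(scheme$n_levels)) {
      rows <- which(levels == lv)
      if (length(rows) == 0L) next
      reg <- new_sae_model(stack,
                           list(W = matrix(0, 1, ncol(h)), b = 0),
                           "regressor", hyper, scaler)
      regressors[[lv]] <- finetune(reg, x[rows, , drop = FALSE], forces[rows])
    }
  }
  structure(list(classifier = classifier, regressors = regressors,
                 scheme = scheme, hyper = hyper),
            class = "force_predictor")
}

#' @export
print.force_predictor <- function(x, ...) {
  nr <- sum(!vapply(x$regressors, is.null, logical(1)))
  cat(sprintf("<force_predictor> %d-level classifier + %d regressors\n",
              x$scheme$n_levels, nr))
  invisible(x)
}

#' Predict grasp-force levels
#'
#' @param predictor a `force_predictor` (or its classifier `sae_model`).
#' @param x rows to classify (vector of length d or rows x d matrix).
#' @return list with `level` (integer vector; softmax argmax, ties broken
#'   toward the lower level) and `probs` (rows x n_levels matrix).
#' @export
predict_level <- function(predictor, x) {
  model <- if (inherits(predictor, "force_predictor")) predictor$classifier
           else predictor
  stopifnot(inherits(model, "sae_model"), model$head_kind == "classifier")
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != ncol(model$layers[[1]]$W))
    stop_validation("input has ", ncol(x), " columns; model expects ",
                    ncol(model$layers[[1]]$W))
  probs <- sae_forward(model, x)
  # which.max returns the first maximum: ties resolve to the lower level
  list(level = vapply(seq_len(nrow(probs)),
                      function(i) which.max(probs[i, ]), integer(1)),
       probs = probs)
}

#' Predict grasp force in newtons
#'
#' Routes each row to the regressor of its predicted level and clips the
#' output to the level scheme's force range.
#'
#' @param predictor a `force_predictor` with trained regressors.
#' @param x rows (vector or matrix).
#' @return list with `force` (N, clipped to the scheme range), `level`
#'   and `probs` as in [predict_level()].
#' @export
predict_force <- function(predictor, x) {
  stopifnot(inherits(predictor, "force_predictor"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  cls <- predict_level(predictor, x)
  force <- numeric(nrow(x))
  for (lv in unique(cls$level)) {
    reg <- predictor$regressors[[lv]]
    if (is.null(reg))
      stop("no regressor trained for predicted level ", lv)
    rows <- which(cls$level == lv)
    force[rows] <- sae_forward(reg, x[rows, , drop = FALSE])
  }
  force <- clamp(force, predictor$scheme$force_min, predictor$scheme$force_max)
  list(force = force, level = cls$level, probs = cls$probs)
}
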