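# PCA dimension reduction of feature rows: 1 x n rows are mapped to 1 x k
# through the top-k eigenvectors of the (optionally standardized) feature
# covariance. Implemented as an explicit covariance eigendecomposition;
# the test suite cross-checks it against an independent SVD route.

#' Fit the PCA reduction matrix
#'
#' Centers (and by default z-scores) the feature columns, eigendecomposes
#' their covariance, and retains the top `k` axes as the n x k reduction
#' matrix U. Axes are oriented so each one's largest-magnitude loading is
#' positive, which makes serialized models reproducible.
#'
#' @param x numeric matrix (rows x n features) or a `feature_table`.
#' @param k reduced dimension, `1 <= k < n` (default 8).
#' @param standardize z-score each column before the decomposition
#'   (default TRUE; features such as WL and MAV live on different scales).
#'   Zero-variance columns get scale 1 and contribute nothing.
#' @return an object of class `pca_model` with fields `mean`, `scale`,
#'   `rotation` (n x k), `eigenvalues` (all n, descending), `n`, `k`,
#'   `standardize`.
#' @export
fit_pca <- function(x, k = 8, standardize = TRUE) {
  if (inherits(x, "feature_table")) x <- x$features
  x <- as.matrix(x)
  n <- ncol(x)
  if (k < 1 || k >= n) stop_validation("need 1 <= k < n (n = ", n, ")")
  if (nrow(x) < 2L) stop_validation("need at least 2 rows to fit PCA")
  if (nrow(x) < n)
    warning("fewer rows (", nrow(x), ") than feature columns (", n, ")")
  mu <- colMeans(x)
  sc <- if (standardize) apply(x, 2, stats::sd) else rep(1, n)
  sc[sc == 0] <- 1
  z <- sweep(sweep(x, 2, mu), 2, sc, "/")
  eg <- eigen(stats::cov(z), symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  U <- eg$vectors[, seq_len(k), drop = FALSE]
  # sign convention: largest-magnitude loading of each axis positive
  for (j in seq_len(k)) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  structure(list(mean = mu, scale = sc, rotation = U,
                 eigenvalues = vals, n = n, k = as.integer(k),
                 standardize = standardize),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d -> %d dims, retained variance %.1f%%\n",
              x$n, x$k,
              100 * sum(x$eigenvalues[seq_len(x$k)]) / sum(x$eigenvalues)))
  invisible(x)
}

#' Project feature rows through a fitted PCA model
#'
#' @param model a `pca_model`.
#' @param x numeric vector (one row of length n), matrix (rows x n), or a
#'   `feature_table`.
#' @return matrix rows x k (a single vector input returns a 1 x k matrix).
#' @export
pca_transform <- function(model, x) {
  stopifnot(inherits(model, "pca_model"))
  if (inherits(x, "feature_table")) x <- x$features
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$n)
    stop_validation("row length ", ncol(x), " does not match model n = ",
                    model$n)
  z <- sweep(sweep(x, 2, model$mean), 2, model$scale, "/")
  z %*% model$rotation
}

#' @export
predict.pca_model <- function(object, newdata, ...) pca_transform(object, newdata)
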