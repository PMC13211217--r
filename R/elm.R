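# Extreme learning machine -----------------------------------------------------
#
# Single hidden layer with fixed random input weights: H = tanh(Z W + 1 b'),
# where Z is the (internally standardized) input. Output weights are solved in
# closed form: alpha = 0 gives the minimum-norm least-squares solution via the
# SVD pseudo-inverse; alpha > 0 gives the Tikhonov-regularized solution
# beta = (H'H + alpha I)^{-1} H'y.

#' Fit an extreme learning machine
#'
#' Input weights `W` (d x n_hidden) and biases `b` are drawn once from
#' U(-1, 1) under `seed` and never updated. Inputs are z-scored with training
#' statistics stored in the model (a constant column gets scale 1), keeping
#' the tanh hidden layer out of saturation regardless of channel units.
#'
#' @param x numeric matrix (n x d) of inputs.
#' @param y numeric targets (for classification pass label codes, e.g. -1/+1).
#' @param n_hidden number of hidden tanh units.
#' @param alpha ridge penalty; 0 selects the pseudo-inverse solution.
#' @param seed integer seed for the random projection.
#' @return An `elm_model`.
#' @export
fit_elm <- function(x, y, n_hidden = 150, alpha = 0, seed = 1L) {
  x <- as.matrix(x)
  if (!all(is.finite(x)) || !all(is.finite(y))) abort("non-finite inputs to fit_elm")
  if (nrow(x) < 1 || n_hidden < 1) abort("need n >= 1 and n_hidden >= 1")
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  z <- sweep(sweep(x, 2, center), 2, scale, "/")
  d <- ncol(x)
  wb <- withr::with_seed(seed, list(
    W = matrix(runif(d * n_hidden, -1, 1), d, n_hidden),
    b = runif(n_hidden, -1, 1)))
  h <- tanh(z %*% wb$W + rep(1, nrow(z)) %o% wb$b)
  if (alpha == 0) {
    sv <- svd(h)
    tol <- max(dim(h)) * .Machine$double.eps * sv$d[1]
    dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
    beta <- sv$v %*% (dinv * crossprod(sv$u, y))
  } else {
    beta <- solve(crossprod(h) + diag(alpha, n_hidden), crossprod(h, y))
  }
  structure(list(W = wb$W, b = wb$b, beta = drop(beta), n_hidden = n_hidden,
                 alpha = alpha, seed = seed, center = center, scale = scale,
                 activation = "tanh"),
            class = "elm_model")
}

#' Raw ELM output
#'
#' @param model an `elm_model`.
#' @param x input matrix with the training feature dimension.
#' @return Numeric vector `h(x)' beta`.
#' @export
predict_elm <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(model$center)) abort("feature dimension mismatch")
  z <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  h <- tanh(z %*% model$W + rep(1, nrow(z)) %o% model$b)
  drop(h %*% model$beta)
}

#' ELM class-1 probability via the logistic map
#'
#' @inheritParams predict_elm
#' @return Probabilities `sigma(h(x)' beta)` in (0, 1).
#' @export
predict_elm_proba <- function(model, x) {
  stats::plogis(predict_elm(model, x))
}
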