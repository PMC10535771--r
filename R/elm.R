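#' Activation functions
#'
#' Look up one of the supported elementwise activations by name.
#' The logistic sigmoid is the package default for both the random feature
#' map and the autoencoder stack.
#'
#' @param name one of `"sigmoid"`, `"tanh"`, `"relu"`, `"identity"`.
#' @return a vectorized function of one numeric argument.
#' @export
get_activation <- function(name) {
  fns <- list(
    sigmoid = function(z) 1 / (1 + exp(-z)),
    tanh = base::tanh,
    relu = function(z) pmax(z, 0),
    identity = base::identity
  )
  if (!name %in% names(fns))
    stop(sprintf("unknown activation '%s'; valid names: %s",
                 name, paste(names(fns), collapse = ", ")))
  fns[[name]]
}

#' Construct a frozen random feature map
#'
#' The heart of the ELM: hidden-layer input weights and biases are drawn
#' i.i.d. uniform on `[-1, 1]` from the seeded stream and never updated by
#' training — only the output weights are learned.
#'
#' @param input_dim number of input features D (>= 1).
#' @param hidden_count number of hidden neurons L (>= 1).
#' @param activation activation name (see [get_activation()]).
#' @param seed integer seed; the same seed always yields the same map.
#' @return an object of class `elm_feature_map` with fields
#'   `input_weights` (L x D), `biases` (length L), `activation`, `seed`.
#' @export
make_feature_map <- function(input_dim, hidden_count,
                             activation = "sigmoid", seed = 1L) {
  stopifnot(input_dim >= 1L, hidden_count >= 1L)
  get_activation(activation) # validates the name
  with_seed(seed, {
    W <- matrix(stats::runif(hidden_count * input_dim, -1, 1),
                hidden_count, input_dim)
    b <- stats::runif(hidden_count, -1, 1)
    structure(list(input_weights = W, biases = b,
                   activation = activation, seed = as.integer(seed)),
              class = "elm_feature_map")
  })
}

#' Hidden-layer activation matrix
#'
#' Computes `H[i, j] = a(r_j . x_i + b_j)` for every sample `i` and hidden
#' neuron `j`, where `r_j` and `b_j` are the frozen random weights and biases
#' of the feature map and `a` its activation.
#'
#' @param X N x D feature matrix.
#' @param map an [make_feature_map()] object with `input_dim = D`.
#' @return the N x L activation matrix.
#' @export
activation_matrix <- function(X, map) {
  X <- as.matrix(X)
  D <- ncol(map$input_weights)
  if (ncol(X) != D)
    stop(sprintf("feature dimension mismatch: X has %d columns, map expects %d",
                 ncol(X), D))
  a <- get_activation(map$activation)
  Z <- tcrossprod(X, map$input_weights)
  Z <- sweep(Z, 2L, map$biases, "+")
  a(Z)
}

#' Solve for ELM output weights
#'
#' Minimizes the ridge-regularized least-squares cost
#' `||H b - Y||^2 + lambda ||b||^2`. For `lambda > 0` the unique minimizer
#' is computed from the regularized normal equations via a Cholesky
#' factorization of the symmetric positive-definite matrix `H'H + lambda I`.
#' For `lambda = 0` the minimum-norm least-squares solution is returned via
#' an SVD-based pseudo-inverse, which also covers rank-deficient `H`
#' (documented behavior, not an error) and sidesteps the instability of
#' inverting near-singular matrices from very large hidden layers.
#'
#' @param H N x L activation matrix (or any design matrix).
#' @param Y N x C target matrix (one-hot class indicators for classification).
#' @param ridge_lambda nonnegative ridge penalty (default `1e-3`).
#' @return an object of class `elm_output_weights` with fields `beta`
#'   (L x C) and `ridge_lambda`.
#' @export
solve_output_weights <- function(H, Y, ridge_lambda = 1e-3) {
  H <- as.matrix(H); Y <- as.matrix(Y)
  if (nrow(H) != nrow(Y))
    stop(sprintf("row mismatch: H has %d rows, Y has %d", nrow(H), nrow(Y)))
  if (!all(is.finite(H)) || !all(is.finite(Y)))
    stop("non-finite values in H or Y")
  stopifnot(ridge_lambda >= 0)
  beta <- ridge_solve(H, Y, ridge_lambda)
  structure(list(beta = beta, ridge_lambda = ridge_lambda),
            class = "elm_output_weights")
}

# argmin ||A b - T||^2 + lambda ||b||^2; lambda = 0 -> min-norm pinv solution
ridge_solve <- function(A, T_, lambda) {
  if (lambda > 0) {
    M <- crossprod(A)
    diag(M) <- diag(M) + lambda
    R <- chol(M)
    backsolve(R, backsolve(R, crossprod(A, T_), transpose = TRUE))
  } else {
    pinv_solve(A, T_)
  }
}

# minimum-norm least squares via SVD with a relative rank tolerance
pinv_solve <- function(A, T_) {
  s <- svd(A)
  tol <- max(dim(A)) * .Machine$double.eps * max(s$d, 0)
  keep <- s$d > tol
  if (!any(keep)) return(matrix(0, ncol(A), ncol(T_)))
  s$v[, keep, drop = FALSE] %*%
    ((crossprod(s$u[, keep, drop = FALSE], T_)) / s$d[keep])
}

#' Predict classes with a single-layer ELM
#'
#' Scores are `activation_matrix(X, map) %*% beta`; the predicted class is
#' the per-row argmax, with ties broken toward the lowest class index.
#'
#' @param X N x D feature matrix.
#' @param map an [make_feature_map()].
#' @param weights an [solve_output_weights()] result.
#' @return list with `class_index` (1-based integer vector) and `scores`
#'   (N x C matrix).
#' @export
elm_predict <- function(X, map, weights) {
  H <- activation_matrix(X, map)
  if (ncol(H) != nrow(weights$beta))
    stop(sprintf("hidden dimension mismatch: H has %d columns, beta %d rows",
                 ncol(H), nrow(weights$beta)))
  scores <- H %*% weights$beta
  list(class_index = max.col(scores, ties.method = "first"), scores = scores)
}

#' Train a single-layer ELM classifier
#'
#' The classic three-step procedure: draw the random hidden layer, compute
#' the activation matrix, solve the regularized pseudo-inverse problem for
#' the output weights.
#'
#' @param dataset a [labeled_dataset()].
#' @param hidden_count hidden neurons (default 1000).
#' @param activation activation name (default `"sigmoid"`).
#' @param ridge_lambda ridge penalty (default `1e-3`).
#' @param seed master seed.
#' @return an object of class `elm_model`.
#' @export
train_elm <- function(dataset, hidden_count = 1000L, activation = "sigmoid",
                      ridge_lambda = 1e-3, seed = 1L) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  map <- make_feature_map(ncol(dataset$X), hidden_count, activation,
                          derive_seed(seed, "elm/map"))
  H <- activation_matrix(dataset$X, map)
  weights <- solve_output_weights(H, dataset$Y, ridge_lambda)
  structure(list(map = map, weights = weights,
                 class_names = dataset$class_names, seed = as.integer(seed)),
            class = "elm_model")
}

#' @export
predict.elm_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "labeled_dataset")) newdata$X else as.matrix(newdata)
  p <- elm_predict(X, object$map, object$weights)
  p$label <- object$class_names[p$class_index]
  colnames(p$scores) <- object$class_names
  p
}
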