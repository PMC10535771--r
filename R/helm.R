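#' FISTA for l1-regularized least squares
#'
#' Solves `argmin_B 0.5 * ||A B - X||_F^2 + lambda * ||B||_1` with the fast
#' iterative shrinkage-thresholding algorithm, using the fixed step
#' `1 / L` where `L` is the Lipschitz constant of the smooth gradient (the
#' largest eigenvalue of `A'A`, obtained by power iteration). The monotone
#' variant is used: each accepted iterate is the best objective value seen,
#' so the recorded objective trace is non-increasing by construction while
#' the momentum sequence keeps the fast convergence rate.
#'
#' @param A N x L design matrix.
#' @param X N x D target matrix.
#' @param lambda nonnegative l1 weight.
#' @param iters number of iterations.
#' @return list with `B` (L x D solution) and `objective` (numeric vector of
#'   the penalized objective after each iteration, starting at the zero
#'   initializer's objective).
#' @export
fista_l1 <- function(A, X, lambda, iters) {
  stopifnot(lambda >= 0, iters >= 1)
  AtA <- crossprod(A)
  AtX <- crossprod(A, X)
  x_sq <- sum(X^2)
  L <- lipschitz_bound(AtA)
  step <- 1 / L
  # f(B) = 0.5||AB - X||^2 via traces, avoiding the N-dim product
  smooth_obj <- function(B, AtAB) 0.5 * (sum(B * AtAB) - 2 * sum(B * AtX) + x_sq)
  obj <- function(B, AtAB) smooth_obj(B, AtAB) + lambda * sum(abs(B))
  B <- matrix(0, ncol(A), ncol(X))
  Yk <- B
  tk <- 1
  best <- obj(B, AtA %*% B)
  trace <- numeric(iters + 1L)
  trace[1L] <- best
  for (k in seq_len(iters)) {
    grad <- AtA %*% Yk - AtX
    cand <- soft_threshold(Yk - step * grad, step * lambda)
    f_cand <- obj(cand, AtA %*% cand)
    t_next <- (1 + sqrt(1 + 4 * tk^2)) / 2
    if (f_cand <= best) {
      B_next <- cand
      best <- f_cand
    } else {
      B_next <- B # keep the incumbent; candidate still drives momentum
    }
    Yk <- B_next + (tk / t_next) * (cand - B_next) +
      ((tk - 1) / t_next) * (B_next - B)
    B <- B_next
    tk <- t_next
    trace[k + 1L] <- best
  }
  list(B = B, objective = trace)
}

# elementwise soft-thresholding operator, the prox of t*||.||_1
soft_threshold <- function(Z, t) sign(Z) * pmax(abs(Z) - t, 0)

# largest eigenvalue of a symmetric PSD matrix by deterministic power
# iteration, with a small safety margin
lipschitz_bound <- function(M) {
  v <- rep(1, nrow(M))
  v <- v / sqrt(sum(v^2))
  lam <- 1
  for (i in 1:50) {
    w <- M %*% v
    lam <- sqrt(sum(w^2))
    if (lam == 0) return(.Machine$double.eps)
    v <- as.vector(w) / lam
  }
  lam * 1.01
}

#' Train one ELM sparse-autoencoder layer
#'
#' Unsupervised feature extraction: the layer's input `H_prev` is projected
#' through a frozen random map (uniform `[-1, 1]` weights, rows
#' orthonormalized when `nodes <= input_dim` for a better-conditioned
#' projection), the projections are min-max normalized per hidden unit to
#' `[-1, 1]` — the standard conditioning step of ELM sparse autoencoders,
#' without which the regularized solve below is dominated by a constant
#' component — and passed through the activation, giving `A`. The projection
#' matrix `beta` then solves the sparse reconstruction problem
#' `argmin ||A beta - H_prev||^2 + l1_weight ||beta||_1` by FISTA. With
#' `l1_weight = 0` (the default) the closed-form ridge solution with penalty
#' `ridge_fallback` is used instead (`ridge_fallback = 0` gives the plain
#' minimum-norm least-squares solution).
#'
#' @param H_prev N x D_prev input features (the raw data for the first layer).
#' @param nodes hidden neurons of this layer.
#' @param l1_weight l1 penalty; 0 (default) selects the exact ridge solve.
#' @param fista_iters FISTA iterations (default 50; used when `l1_weight > 0`).
#' @param ridge_fallback ridge penalty used when `l1_weight = 0`.
#' @param activation activation name for the random projection.
#' @param seed integer seed for this layer's stream.
#' @return an object of class `ae_layer` with `beta` (nodes x D_prev; the
#'   forward pass maps `H_prev -> g(H_prev %*% t(beta))`), the frozen random
#'   map (`W`, `b`) with its normalization (`z_lo`, `z_span`), the training
#'   hyperparameters, and the FISTA objective trace when FISTA ran.
#' @export
train_autoencoder_layer <- function(H_prev, nodes, l1_weight = 0,
                                    fista_iters = 50L, ridge_fallback = 1e-3,
                                    activation = "sigmoid", seed = 1L) {
  H_prev <- as.matrix(H_prev)
  stopifnot(nrow(H_prev) >= 1L, nodes >= 1L)
  D <- ncol(H_prev)
  g <- get_activation(activation)
  rmap <- with_seed(seed, {
    W <- matrix(stats::runif(nodes * D, -1, 1), nodes, D)
    if (nodes <= D) W <- t(qr.Q(qr(t(W)))) # orthonormal rows
    b <- stats::runif(nodes, -1, 1)
    list(W = W, b = b)
  })
  Z <- sweep(tcrossprod(H_prev, rmap$W), 2L, rmap$b, "+")
  z_lo <- apply(Z, 2L, min)
  z_span <- pmax(apply(Z, 2L, max) - z_lo, .Machine$double.eps)
  A <- g(sweep(sweep(Z, 2L, z_lo, "-"), 2L, z_span / 2, "/") - 1)
  if (!all(is.finite(A))) stop("non-finite activations in autoencoder layer")
  # reconstruction weights B (nodes x D_prev) double as the forward
  # projection: H_next = g(H_prev %*% t(B))
  if (l1_weight > 0) {
    fit <- fista_l1(A, H_prev, l1_weight, fista_iters)
    beta <- fit$B
    objective <- fit$objective
  } else {
    beta <- ridge_solve(A, H_prev, ridge_fallback)
    objective <- NULL
  }
  structure(list(beta = beta, nodes = as.integer(nodes),
                 l1_weight = l1_weight, fista_iters = as.integer(fista_iters),
                 seed = as.integer(seed), objective = objective,
                 W = rmap$W, b = rmap$b, z_lo = z_lo, z_span = z_span),
            class = "ae_layer")
}

#' Forward pass through one autoencoder layer
#'
#' The layer connection `H_i = g(H_{i-1} %*% t(beta))`, elementwise
#' activation `g`.
#'
#' @param H_prev N x D_prev features.
#' @param layer an [train_autoencoder_layer()] result.
#' @param g activation function or name.
#' @return the N x nodes feature matrix of this layer.
#' @export
forward_layer <- function(H_prev, layer, g = "sigmoid") {
  if (is.character(g)) g <- get_activation(g)
  H_prev <- as.matrix(H_prev)
  if (ncol(H_prev) != ncol(layer$beta))
    stop(sprintf("layer dimension mismatch: input has %d features, layer expects %d",
                 ncol(H_prev), ncol(layer$beta)))
  g(tcrossprod(H_prev, layer$beta))
}

#' Training configuration for a hierarchical ELM
#'
#' @param n_layers number of unsupervised autoencoder feature layers K
#'   (default 4, the selected architecture: 4 feature layers plus the
#'   separate single-layer decision ELM).
#' @param nodes_per_layer hidden neurons per feature layer (default 1000).
#' @param l1_weight autoencoder l1 penalty; 0 (default) selects the exact
#'   ridge solve, any positive value the FISTA l1 solver.
#' @param fista_iters FISTA iterations per layer (default 50).
#' @param ridge_ae autoencoder ridge penalty used when `l1_weight = 0`.
#' @param ridge_lambda ridge penalty of the final decision ELM (default `1e-3`).
#' @param final_hidden hidden neurons of the decision ELM; defaults to
#'   `nodes_per_layer`.
#' @param activation activation name used throughout (default `"sigmoid"`).
#' @param scatter `"random"` (square uniform `[-1, 1]` matrix, the default)
#'   or `"identity"` to disable feature scattering.
#' @param rescale_layers if `TRUE` (default), min-max rescale each layer's
#'   output and the scattered features per column to `[-1, 1]`; without this
#'   the sigmoid feature stack degenerates toward constant columns.
#' @param train_fraction train share for experiment drivers (default 0.8).
#' @param image_side expected input image side (default 28).
#' @param seed master seed; all streams are derived from it.
#' @return an object of class `train_config`.
#' @export
train_config <- function(n_layers = 4L, nodes_per_layer = 1000L,
                         l1_weight = 0, fista_iters = 50L,
                         ridge_ae = 1e-3, ridge_lambda = 1e-3,
                         final_hidden = NULL, activation = "sigmoid",
                         scatter = c("random", "identity"),
                         rescale_layers = TRUE,
                         train_fraction = 0.8, image_side = 28L, seed = 1L) {
  scatter <- match.arg(scatter)
  if (is.null(final_hidden)) final_hidden <- nodes_per_layer
  stopifnot(n_layers >= 1L, nodes_per_layer >= 1L, final_hidden >= 1L,
            fista_iters >= 1L, l1_weight >= 0, ridge_ae >= 0, ridge_lambda >= 0,
            train_fraction > 0, train_fraction < 1, image_side >= 1L)
  get_activation(activation)
  structure(list(
    n_layers = as.integer(n_layers),
    nodes_per_layer = as.integer(nodes_per_layer),
    l1_weight = l1_weight, fista_iters = as.integer(fista_iters),
    ridge_ae = ridge_ae, ridge_lambda = ridge_lambda,
    final_hidden = as.integer(final_hidden), activation = activation,
    scatter = scatter, rescale_layers = isTRUE(rescale_layers),
    train_fraction = train_fraction, image_side = as.integer(image_side),
    seed = as.integer(seed)
  ), class = "train_config")
}

# min-max rescale columns of H to [-1, 1]; returns H and the ranges so the
# identical affine map can be replayed at prediction time
rescale_fit <- function(H) {
  lo <- apply(H, 2L, min)
  hi <- apply(H, 2L, max)
  span <- pmax(hi - lo, .Machine$double.eps)
  list(H = sweep(sweep(H, 2L, lo, "-"), 2L, span / 2, "/") - 1,
       lo = lo, span = span)
}

rescale_apply <- function(H, lo, span) {
  sweep(sweep(H, 2L, lo, "-"), 2L, span / 2, "/") - 1
}

#' Train a hierarchical ELM
#'
#' The five-step procedure: (1) take the training set with one-hot targets;
#' (2--4) train `K` ELM sparse-autoencoder layers sequentially, each on the
#' forward-propagated output of the previous layer, connecting layers by
#' `H_i = g(H_{i-1} %*% t(beta_i))`; then scatter the last layer's features
#' with a frozen random matrix; (5) make the final decision with an ordinary
#' single-layer ELM trained on the scattered features.
#'
#' @param dataset a [labeled_dataset()].
#' @param config a [train_config()].
#' @return an object of class `helm_model`; its `report` field records wall
#'   time, per-layer shapes, and the seed.
#' @export
train_helm <- function(dataset, config = train_config()) {
  stopifnot(inherits(dataset, "labeled_dataset"), inherits(config, "train_config"))
  t0 <- proc.time()[["elapsed"]]
  g <- get_activation(config$activation)
  H <- dataset$X
  if (stats::var(as.vector(H)) == 0)
    warning("degenerate input: all features identical; proceeding (solver handles rank deficiency)")
  layers <- vector("list", config$n_layers)
  shapes <- character(config$n_layers)
  for (i in seq_len(config$n_layers)) {
    layer <- train_autoencoder_layer(
      H, config$nodes_per_layer, config$l1_weight, config$fista_iters,
      config$ridge_ae, config$activation,
      seed = derive_seed(config$seed, paste0("ae", i)))
    H <- forward_layer(H, layer, g)
    if (config$rescale_layers) {
      sc <- rescale_fit(H)
      H <- sc$H
      layer$rescale <- list(lo = sc$lo, span = sc$span)
    }
    layers[[i]] <- layer
    shapes[i] <- sprintf("layer %d: %d x %d", i, nrow(H), ncol(H))
  }
  scatter <- if (config$scatter == "random") {
    n <- ncol(H)
    with_seed(derive_seed(config$seed, "scatter"),
              matrix(stats::runif(n * n, -1, 1), n, n))
  } else {
    diag(ncol(H))
  }
  Hs <- H %*% scatter
  scatter_rescale <- NULL
  if (config$rescale_layers) {
    sc <- rescale_fit(Hs)
    Hs <- sc$H
    scatter_rescale <- list(lo = sc$lo, span = sc$span)
  }
  final_map <- make_feature_map(ncol(Hs), config$final_hidden,
                                config$activation,
                                derive_seed(config$seed, "final/map"))
  Hf <- activation_matrix(Hs, final_map)
  final_weights <- solve_output_weights(Hf, dataset$Y, config$ridge_lambda)
  elapsed <- proc.time()[["elapsed"]] - t0
  structure(list(
    layers = layers, scatter = scatter, scatter_rescale = scatter_rescale,
    final_map = final_map,
    final_weights = final_weights, activation = config$activation,
    class_names = dataset$class_names, input_dim = ncol(dataset$X),
    config = config,
    report = list(train_seconds = elapsed, layer_shapes = shapes,
                  n_train = nrow(dataset$X), seed = config$seed)
  ), class = "helm_model")
}

#' Predict with a hierarchical ELM
#'
#' Forward pass through every autoencoder layer, the scattering matrix, and
#' the final decision ELM; argmax per row with ties toward the lowest class
#' index.
#'
#' @param model a [train_helm()] result.
#' @param X N x D feature matrix (D must equal the model's input dimension).
#' @return list with `class_index`, `label`, and the N x C `scores` matrix.
#' @export
helm_predict <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$input_dim)
    stop(sprintf("feature dimension mismatch: X has %d columns, model expects %d",
                 ncol(X), model$input_dim))
  g <- get_activation(model$activation)
  H <- X
  for (layer in model$layers) {
    H <- forward_layer(H, layer, g)
    if (!is.null(layer$rescale))
      H <- rescale_apply(H, layer$rescale$lo, layer$rescale$span)
  }
  Hs <- H %*% model$scatter
  if (!is.null(model$scatter_rescale))
    Hs <- rescale_apply(Hs, model$scatter_rescale$lo, model$scatter_rescale$span)
  p <- elm_predict(Hs, model$final_map, model$final_weights)
  p$label <- model$class_names[p$class_index]
  colnames(p$scores) <- model$class_names
  p
}

#' @export
predict.helm_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "labeled_dataset")) newdata$X else as.matrix(newdata)
  helm_predict(object, X)
}

#' @export
print.helm_model <- function(x, ...) {
  cat(sprintf("<helm_model> %d autoencoder layers x %d nodes + final ELM (%d hidden), activation %s\n",
              length(x$layers), x$config$nodes_per_layer,
              x$config$final_hidden, x$activation))
  cat(sprintf("  input dim %d, classes: %s\n", x$input_dim,
              paste(x$class_names, collapse = ", ")))
  invisible(x)
}
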