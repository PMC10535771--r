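test_that("FISTA with identity design returns the closed-form soft threshold", {
  set.seed(5)
  X <- matrix(rnorm(12, sd = 2), 4, 3)
  lam <- 0.7
  fit <- fista_l1(diag(4), X, lam, 25L)
  expect_equal(fit$B, sign(X) * pmax(abs(X) - lam, 0), tolerance = 1e-6)
})

test_that("the FISTA objective trace is non-increasing", {
  set.seed(17)
  A <- matrix(rnorm(200), 20, 10)
  X <- matrix(rnorm(60), 20, 3)
  fit <- fista_l1(A, X, 0.3, 60L)
  expect_true(all(diff(fit$objective) <= 1e-10))
  # the recorded trace is the true objective of the accepted iterate
  expect_equal(fit$objective[length(fit$objective)],
               oracle_l1_objective(A, X, fit$B, 0.3), tolerance = 1e-8)
})

test_that("zero l1 weight reduces the autoencoder solve to least squares", {
  set.seed(23)
  H_prev <- matrix(rnorm(48), 8, 6)
  layer <- train_autoencoder_layer(H_prev, nodes = 5L, l1_weight = 0,
                                   ridge_fallback = 0, seed = 2L)
  # rebuild the layer's internal design matrix from its stored random map
  Z <- sweep(tcrossprod(H_prev, layer$W), 2, layer$b, "+")
  A <- 1 / (1 + exp(-(sweep(sweep(Z, 2, layer$z_lo, "-"), 2, layer$z_span / 2, "/") - 1)))
  expect_equal(layer$beta, oracle_pinv(A, H_prev), tolerance = 1e-6)
  # and the FISTA route converges to the same solution as lambda -> 0
  fit <- fista_l1(A, H_prev, 1e-12, 4000L)
  expect_equal(fit$B, oracle_pinv(A, H_prev), tolerance = 1e-4)
})

test_that("autoencoder layers are deterministic and correctly shaped", {
  H_prev <- matrix(rbinom(120, 1, 0.4), 12, 10)
  l1 <- train_autoencoder_layer(H_prev, nodes = 6L, seed = 31L)
  l2 <- train_autoencoder_layer(H_prev, nodes = 6L, seed = 31L)
  expect_identical(l1$beta, l2$beta)
  expect_equal(dim(l1$beta), c(6L, 10L))
  # orthonormal rows of the random map when nodes <= input dim
  expect_equal(l1$W %*% t(l1$W), diag(6), tolerance = 1e-10)
})

test_that("layer forwarding equals its elementwise definition", {
  layer <- structure(list(beta = diag(3)), class = "ae_layer")
  H <- matrix(rnorm(9), 3, 3)
  expect_equal(forward_layer(H, layer, "identity"), H)
  layer0 <- structure(list(beta = matrix(0, 4, 3)), class = "ae_layer")
  expect_true(all(forward_layer(H, layer0, "sigmoid") == 0.5))
  lh <- structure(list(beta = matrix(c(0.5, -1, 2, 0.25), 2, 2)), class = "ae_layer")
  H2 <- matrix(c(1, -0.5, 0.2, 3), 2, 2)
  out <- forward_layer(H2, lh, "tanh")
  for (i in 1:2) for (j in 1:2)
    expect_equal(out[i, j], tanh(sum(H2[i, ] * lh$beta[j, ])))
  expect_error(forward_layer(matrix(0, 2, 5), lh, "tanh"), "mismatch")
})

test_that("trivial single-layer config reduces to a hand-built ELM pipeline", {
  ds <- generate_dataset(synth_spec(n_per_class = 8L, seed = 6L))
  cfg <- train_config(n_layers = 1L, nodes_per_layer = 20L, final_hidden = 15L,
                      l1_weight = 0, activation = "identity",
                      scatter = "identity", rescale_layers = FALSE, seed = 44L)
  model <- train_helm(ds, cfg)
  # the same pipeline assembled by hand from the primitives
  layer <- train_autoencoder_layer(ds$X, 20L, l1_weight = 0, ridge_fallback = cfg$ridge_ae,
                                   activation = "identity",
                                   seed = derive_seed(44L, "ae1"))
  F1 <- forward_layer(ds$X, layer, "identity")
  fmap <- make_feature_map(20L, 15L, "identity", derive_seed(44L, "final/map"))
  w <- solve_output_weights(activation_matrix(F1, fmap), ds$Y, cfg$ridge_lambda)
  manual <- elm_predict(F1, fmap, w)
  auto <- helm_predict(model, ds$X)
  expect_equal(auto$scores, manual$scores, ignore_attr = TRUE)
  expect_identical(auto$class_index, manual$class_index)
})

test_that("the default architecture trains and interpolates a small training set", {
  ds <- generate_dataset(synth_spec(n_per_class = 20L, seed = 7L)) # n = 60
  model <- train_helm(ds, train_config(seed = 3L))
  p <- helm_predict(model, ds$X)
  expect_gte(mean(p$label == ds$labels), 0.99)
  expect_equal(ncol(p$scores), 3L)
  expect_identical(colnames(p$scores), ds$class_names)
  # row permutation permutes predictions identically
  perm <- sample(nrow(ds$X))
  expect_identical(helm_predict(model, ds$X[perm, ])$class_index,
                   p$class_index[perm])
})

test_that("identical seeds give byte-identical serialized models", {
  ds <- generate_dataset(synth_spec(n_per_class = 6L, seed = 8L))
  cfg <- train_config(n_layers = 2L, nodes_per_layer = 30L, seed = 12L)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  save_model(train_helm(ds, cfg), f1)
  save_model(train_helm(ds, cfg), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("hierarchical models survive a serialization round trip", {
  ds <- generate_dataset(synth_spec(n_per_class = 6L, seed = 9L))
  model <- train_helm(ds, train_config(n_layers = 2L, nodes_per_layer = 25L,
                                       seed = 5L))
  path <- withr::local_tempfile(fileext = ".txt")
  save_model(model, path)
  m2 <- load_model(path)
  p1 <- helm_predict(model, ds$X)
  p2 <- helm_predict(m2, ds$X)
  expect_equal(p2$scores, p1$scores, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(p2$label, p1$label)
})

test_that("degenerate all-identical features train with a warning, not an error", {
  X <- matrix(1L, 9, 16)
  ds <- labeled_dataset(X, rep(c("benign", "malignant", "normal"), each = 3L))
  expect_warning(model <- train_helm(ds, train_config(n_layers = 1L,
                                                      nodes_per_layer = 8L,
                                                      seed = 1L)),
                 "degenerate")
  expect_length(helm_predict(model, X)$class_index, 9L)
})
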