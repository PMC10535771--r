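#' Split a dataset into train and test sets
#'
#' Stratified by default: each class is shuffled with the seeded stream and
#' the first `floor(train_fraction * n_class)` samples go to training, so
#' per-class proportions are preserved to within one sample. Unstratified
#' splitting permutes all rows and takes the first
#' `floor(train_fraction * N)`.
#'
#' @param dataset a [labeled_dataset()].
#' @param train_fraction fraction of samples used for training, in (0, 1).
#' @param seed integer seed.
#' @param stratified stratify by class (default `TRUE`).
#' @return list with `train`, `test` ([labeled_dataset()]s) and the index
#'   vectors `train_idx`, `test_idx`.
#' @export
split_dataset <- function(dataset, train_fraction = 0.8, seed = 1L,
                          stratified = TRUE) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            train_fraction > 0, train_fraction < 1)
  n <- nrow(dataset$X)
  if (stratified) {
    counts <- table(dataset$labels)
    if (any(counts < 2L))
      stop("stratified split needs at least 2 samples per class; got: ",
           paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
    train_idx <- integer(0)
    for (cl in dataset$class_names) {
      idx <- which(dataset$labels == cl)
      if (length(idx) == 0L) next
      idx <- with_seed(derive_seed(seed, paste0("split/", cl)),
                       idx[sample.int(length(idx))])
      train_idx <- c(train_idx, idx[seq_len(floor(train_fraction * length(idx)))])
    }
    train_idx <- sort(train_idx)
  } else {
    perm <- with_seed(derive_seed(seed, "split/all"), sample.int(n))
    train_idx <- sort(perm[seq_len(floor(train_fraction * n))])
  }
  test_idx <- setdiff(seq_len(n), train_idx)
  list(train = subset_dataset(dataset, train_idx),
       test = subset_dataset(dataset, test_idx),
       train_idx = train_idx, test_idx = test_idx)
}

#' Evaluate a classifier on a test set
#'
#' @param model an `elm_model` or `helm_model`.
#' @param test a [labeled_dataset()].
#' @param train_seconds optional training wall time to record in the report.
#' @param config optional configuration snapshot to record.
#' @return an `eval_report`: `accuracy`, `confusion` (C x C count matrix,
#'   rows = true class, cols = predicted), `n_test`, and metadata.
#' @export
evaluate <- function(model, test, train_seconds = NA_real_, config = NULL) {
  stopifnot(inherits(test, "labeled_dataset"), nrow(test$X) >= 1L)
  pred <- predict(model, test)
  cn <- test$class_names
  confusion <- table(factor(test$labels, levels = cn),
                     factor(pred$label, levels = cn))
  confusion <- matrix(as.integer(confusion), length(cn), length(cn),
                      dimnames = list(true = cn, predicted = cn))
  acc <- sum(diag(confusion)) / nrow(test$X)
  structure(list(accuracy = acc, confusion = confusion,
                 n_test = nrow(test$X),
                 n_train = if (!is.null(config)) config$n_train else NA_integer_,
                 train_seconds = train_seconds, config = config),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.4f on %d test samples", x$accuracy, x$n_test))
  if (is.finite(x$train_seconds))
    cat(sprintf(" (trained in %.2f s)", x$train_seconds))
  cat("\nconfusion matrix (rows = true, cols = predicted):\n")
  print(x$confusion)
  invisible(x)
}

#' Write an evaluation report as JSON (plus a TSV confusion matrix)
#'
#' @param report an [evaluate()] result.
#' @param path JSON output path; the confusion matrix goes to
#'   `<path without .json>_confusion.tsv`.
#' @export
write_eval_report <- function(report, path) {
  out <- list(accuracy = report$accuracy,
              n_test = report$n_test, n_train = report$n_train,
              train_seconds = report$train_seconds,
              confusion = report$confusion,
              classes = colnames(report$confusion))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  tsv <- sub("\\.json$", "", path)
  utils::write.table(report$confusion, paste0(tsv, "_confusion.tsv"),
                     sep = "\t", quote = FALSE)
  invisible(path)
}

#' Run one train/evaluate experiment
#'
#' Splits the dataset (stratified, per the configuration's
#' `train_fraction` and `seed`), trains a hierarchical ELM on the training
#' part, and evaluates on the held-out part.
#'
#' @param dataset a [labeled_dataset()].
#' @param config a [train_config()].
#' @return list with `model`, `report` (an `eval_report`), and `split`.
#' @export
run_experiment <- function(dataset, config = train_config()) {
  sp <- split_dataset(dataset, config$train_fraction, config$seed,
                      stratified = TRUE)
  model <- train_helm(sp$train, config)
  report <- evaluate(model, sp$test,
                     train_seconds = model$report$train_seconds)
  report$n_train <- nrow(sp$train$X)
  list(model = model, report = report, split = sp)
}

#' Sweep over layer counts and hidden-node counts
#'
#' Re-runs the train/evaluate experiment for every combination in the grid,
#' `repeats` times each with distinct derived seeds, collecting accuracy and
#' training time per cell. Failures in individual cells are recorded
#' (accuracy `NA`) and the sweep continues.
#'
#' @param dataset a [labeled_dataset()].
#' @param layer_counts integer vector of autoencoder layer counts K.
#' @param node_counts integer vector of per-layer hidden-node counts.
#' @param repeats runs per cell (default 1).
#' @param base_config a [train_config()] supplying all other settings;
#'   its `seed` is the sweep's master seed.
#' @param out_tsv optional path: write the results table as TSV.
#' @return data frame with columns `layers`, `nodes`, `rep`, `seed`,
#'   `accuracy`, `train_seconds`, `best` (logical flag on the top-accuracy
#'   row).
#' @export
run_sweep <- function(dataset, layer_counts, node_counts, repeats = 1L,
                      base_config = train_config(), out_tsv = NULL) {
  stopifnot(length(layer_counts) >= 1L, length(node_counts) >= 1L, repeats >= 1L)
  rows <- list()
  for (K in layer_counts) for (nodes in node_counts) for (r in seq_len(repeats)) {
    seed <- derive_seed(base_config$seed, sprintf("sweep/K%d/n%d/r%d", K, nodes, r))
    cfg <- base_config
    cfg$n_layers <- as.integer(K)
    cfg$nodes_per_layer <- as.integer(nodes)
    cfg$final_hidden <- as.integer(nodes)
    cfg$seed <- seed
    res <- tryCatch({
      ex <- run_experiment(dataset, cfg)
      c(ex$report$accuracy, ex$report$train_seconds)
    }, error = function(e) {
      message(sprintf("sweep cell K=%d nodes=%d rep=%d failed: %s",
                      K, nodes, r, conditionMessage(e)))
      c(NA_real_, NA_real_)
    })
    rows[[length(rows) + 1L]] <- data.frame(
      layers = K, nodes = nodes, rep = r, seed = seed,
      accuracy = res[1], train_seconds = res[2])
  }
  out <- do.call(rbind, rows)
  out$best <- FALSE
  if (any(is.finite(out$accuracy)))
    out$best[which.max(out$accuracy)] <- TRUE
  if (!is.null(out_tsv))
    utils::write.table(out, out_tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  out
}

#' Classify a single image file with a saved model
#'
#' Runs the preprocessing chain (mask union, center crop, block downsample
#' to the model's image side) and the forward pass of the loaded model.
#'
#' @param model_path path to a model saved by [save_model()].
#' @param image_path path to the grayscale PNG.
#' @param mask_paths character vector of mask PNG paths (empty = no lesion
#'   mask, the normal-image case).
#' @param image_side side the model was trained at (default 28).
#' @return list with `label` and named `scores`.
#' @export
predict_image <- function(model_path, image_path, mask_paths = character(),
                          image_side = 28L) {
  model <- load_model(model_path)
  if (!is.null(model$input_dim) && model$input_dim != image_side^2)
    stop(sprintf("image side %d (-> %d features) does not match the model's input dimension %d",
                 image_side, image_side^2, model$input_dim))
  rec <- list(image_path = image_path, mask_paths = mask_paths,
              class_label = "normal")
  x <- preprocess_record(rec, image_side)
  p <- predict(model, matrix(x, 1L))
  list(label = p$label, scores = drop(p$scores))
}

#' Read a training configuration from a flat YAML file
#'
#' Keys mirror the arguments of [train_config()]; unknown keys are an error.
#'
#' @param path YAML file.
#' @return a [train_config()].
#' @export
read_train_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(train_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(train_config, vals)
}
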