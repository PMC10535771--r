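#' Labeled dataset container
#'
#' Holds the flattened feature matrix `X` (one image per row, row-major
#' pixel order) together with a one-hot label matrix `Y` and the ordered
#' class names that define the column order of `Y`.
#'
#' @param X numeric matrix, N x D.
#' @param labels character vector of length N with class labels, or an
#'   N x C one-hot matrix.
#' @param class_names ordered class labels defining the columns of `Y`;
#'   defaults to the sorted unique labels.
#' @return an object of class `labeled_dataset` with fields `X`, `Y`,
#'   `labels`, `class_names`.
#' @export
labeled_dataset <- function(X, labels, class_names = NULL) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 1L, ncol(X) >= 1L)
  if (is.matrix(labels)) {
    Y <- labels
    if (is.null(class_names)) class_names <- colnames(Y)
    stopifnot(!is.null(class_names), ncol(Y) == length(class_names))
    labels <- class_names[max.col(Y, ties.method = "first")]
  } else {
    labels <- as.character(labels)
    stopifnot(length(labels) == nrow(X))
    if (is.null(class_names)) class_names <- sort(unique(labels))
    if (!all(labels %in% class_names))
      stop("labels contain classes not listed in class_names: ",
           paste(setdiff(labels, class_names), collapse = ", "))
    Y <- matrix(0, nrow(X), length(class_names),
                dimnames = list(NULL, class_names))
    Y[cbind(seq_along(labels), match(labels, class_names))] <- 1
  }
  bad <- rowSums(Y == 1) != 1L | rowSums(Y != 0 & Y != 1) > 0L
  if (any(bad)) stop("Y must be one-hot: each row exactly one 1, rest 0")
  structure(list(X = X, Y = Y, labels = labels, class_names = class_names),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d samples x %d features, %d classes\n",
              nrow(x$X), ncol(x$X), length(x$class_names)))
  print(table(factor(x$labels, levels = x$class_names)))
  invisible(x)
}

# take a row subset, preserving class structure
subset_dataset <- function(ds, idx) {
  out <- labeled_dataset(ds$X[idx, , drop = FALSE], ds$labels[idx],
                         class_names = ds$class_names)
  out
}
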