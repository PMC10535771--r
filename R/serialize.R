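#' Save a model as a single plain-text container
#'
#' Writes a self-describing text file: a metadata header of `key: value`
#' lines (format version, activation, class names, configuration), followed
#' by named numeric matrix sections introduced by `@matrix <name> <rows>
#' <cols>` with one whitespace-separated row per line, printed at full
#' double precision (`%.17g`) so a reload reproduces the model exactly and
#' two same-seed models serialize byte-identically.
#'
#' @param model an `elm_model` or `helm_model`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
save_model <- function(model, path) {
  con <- file(path, "wb") # binary mode: fixed "\n" endings on every platform
  on.exit(close(con))
  wline <- function(...) writeLines(sprintf(...), con, sep = "\n")
  wmat <- function(name, m) {
    m <- as.matrix(m)
    wline("@matrix %s %d %d", name, nrow(m), ncol(m))
    writeLines(apply(m, 1L, function(r)
      paste(sprintf("%.17g", r), collapse = " ")), con, sep = "\n")
  }
  if (inherits(model, "helm_model")) {
    wline("helmus-model 1 helm")
    wline("activation: %s", model$activation)
    wline("classes: %s", paste(model$class_names, collapse = ","))
    wline("input_dim: %d", model$input_dim)
    wline("n_layers: %d", length(model$layers))
    cfg <- model$config
    wline("config: %s", paste(sprintf("%s=%s", names(unclass(cfg)),
      vapply(unclass(cfg), function(v) as.character(v)[1], "")), collapse = ";"))
    wline("scatter_kind: %s", cfg$scatter)
    wline("ridge_lambda: %.17g", model$final_weights$ridge_lambda)
    for (i in seq_along(model$layers)) {
      wmat(sprintf("layer%d_beta", i), model$layers[[i]]$beta)
      rs <- model$layers[[i]]$rescale
      if (!is.null(rs)) {
        wmat(sprintf("layer%d_rescale_lo", i), matrix(rs$lo, 1L))
        wmat(sprintf("layer%d_rescale_span", i), matrix(rs$span, 1L))
      }
    }
    wmat("scatter", model$scatter)
    if (!is.null(model$scatter_rescale)) {
      wmat("scatter_rescale_lo", matrix(model$scatter_rescale$lo, 1L))
      wmat("scatter_rescale_span", matrix(model$scatter_rescale$span, 1L))
    }
    wmat("final_input_weights", model$final_map$input_weights)
    wmat("final_biases", matrix(model$final_map$biases, 1L))
    wmat("final_beta", model$final_weights$beta)
  } else if (inherits(model, "elm_model")) {
    wline("helmus-model 1 elm")
    wline("activation: %s", model$map$activation)
    wline("classes: %s", paste(model$class_names, collapse = ","))
    wline("input_dim: %d", ncol(model$map$input_weights))
    wline("ridge_lambda: %.17g", model$weights$ridge_lambda)
    wmat("input_weights", model$map$input_weights)
    wmat("biases", matrix(model$map$biases, 1L))
    wmat("beta", model$weights$beta)
  } else {
    stop("save_model supports elm_model and helm_model objects")
  }
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path path to the text container.
#' @return the reconstructed `elm_model` or `helm_model`.
#' @export
load_model <- function(path) {
  lines <- readLines(path)
  if (!grepl("^helmus-model 1 ", lines[1]))
    stop("not a helmus model file (or unsupported format version): ", path)
  kind <- sub("^helmus-model 1 ", "", lines[1])
  header <- list()
  i <- 2L
  while (i <= length(lines) && !startsWith(lines[i], "@matrix")) {
    kv <- regmatches(lines[i], regexec("^([^:]+): ?(.*)$", lines[i]))[[1]]
    if (length(kv) == 3L) header[[kv[2]]] <- kv[3]
    i <- i + 1L
  }
  mats <- list()
  while (i <= length(lines)) {
    hdr <- strsplit(lines[i], " ", fixed = TRUE)[[1]]
    stopifnot(hdr[1] == "@matrix")
    nr <- as.integer(hdr[3]); nc <- as.integer(hdr[4])
    block <- lines[(i + 1L):(i + nr)]
    vals <- scan(text = block, quiet = TRUE)
    mats[[hdr[2]]] <- matrix(vals, nr, nc, byrow = TRUE)
    i <- i + nr + 1L
  }
  classes <- strsplit(header$classes, ",", fixed = TRUE)[[1]]
  activation <- header$activation
  if (kind == "elm") {
    map <- structure(list(input_weights = mats$input_weights,
                          biases = as.vector(mats$biases),
                          activation = activation, seed = NA_integer_),
                     class = "elm_feature_map")
    weights <- structure(list(beta = mats$beta,
                              ridge_lambda = as.numeric(header$ridge_lambda)),
                         class = "elm_output_weights")
    return(structure(list(map = map, weights = weights, class_names = classes,
                          seed = NA_integer_), class = "elm_model"))
  }
  n_layers <- as.integer(header$n_layers)
  layers <- vector("list", n_layers)
  for (k in seq_len(n_layers)) {
    layer <- structure(list(beta = mats[[sprintf("layer%d_beta", k)]],
                            nodes = nrow(mats[[sprintf("layer%d_beta", k)]])),
                       class = "ae_layer")
    lo <- mats[[sprintf("layer%d_rescale_lo", k)]]
    if (!is.null(lo))
      layer$rescale <- list(lo = as.vector(lo),
                            span = as.vector(mats[[sprintf("layer%d_rescale_span", k)]]))
    layers[[k]] <- layer
  }
  final_map <- structure(list(input_weights = mats$final_input_weights,
                              biases = as.vector(mats$final_biases),
                              activation = activation, seed = NA_integer_),
                         class = "elm_feature_map")
  final_weights <- structure(list(beta = mats$final_beta,
                                  ridge_lambda = as.numeric(header$ridge_lambda)),
                             class = "elm_output_weights")
  scatter_rescale <- NULL
  if (!is.null(mats$scatter_rescale_lo))
    scatter_rescale <- list(lo = as.vector(mats$scatter_rescale_lo),
                            span = as.vector(mats$scatter_rescale_span))
  structure(list(layers = layers, scatter = mats$scatter,
                 scatter_rescale = scatter_rescale,
                 final_map = final_map, final_weights = final_weights,
                 activation = activation, class_names = classes,
                 input_dim = as.integer(header$input_dim), config = NULL,
                 report = NULL),
            class = "helm_model")
}
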