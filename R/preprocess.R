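#' Read an 8-bit grayscale PNG as an intensity matrix
#'
#' RGB(A) inputs are converted to grayscale by rounding the Rec.601 luminance
#' (0.299 R + 0.587 G + 0.114 B); the alpha channel, if present, is dropped.
#'
#' @param path path to a PNG file.
#' @return an integer matrix of intensities in `[0, 255]`.
#' @export
read_gray_png <- function(path) {
  if (!file.exists(path)) stop("image not readable: ", path)
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3]
    if (nc >= 3L) {
      arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr <- arr[, , 1]
    }
  }
  if (length(arr) == 0L) stop("image has no readable pixels: ", path)
  matrix(as.integer(round(arr * 255)), nrow(arr), ncol(arr))
}

#' Scan a BUSI-style directory tree into sample records
#'
#' Expects class subfolders `benign/`, `malignant/`, `normal/` containing
#' image files like `benign (1).png` with companion masks
#' `benign (1)_mask.png` (and optional `benign (1)_mask_1.png`, ... extras).
#' Every non-mask PNG becomes one record; all files whose stem extends the
#' image stem with `_mask` or `_mask_<k>` are attached as its masks. Records
#' are returned in deterministic lexicographic order (by class folder, then
#' filename). Subfolders with unknown names are skipped with a warning.
#'
#' @param root_dir dataset root containing the class subfolders.
#' @return a list of `sample_record` objects, each with fields
#'   `image_path`, `mask_paths`, `class_label`.
#' @export
scan_dataset <- function(root_dir) {
  if (!dir.exists(root_dir)) stop("dataset root not found: ", root_dir)
  subdirs <- sort(list.dirs(root_dir, recursive = FALSE, full.names = FALSE))
  unknown <- setdiff(subdirs, helmus_classes())
  if (length(unknown) > 0)
    warning("skipping unknown class folders: ", paste(unknown, collapse = ", "))
  records <- list()
  for (cl in intersect(sort(helmus_classes()), subdirs)) {
    files <- sort(list.files(file.path(root_dir, cl), pattern = "\\.png$",
                             ignore.case = TRUE))
    stems <- sub("\\.png$", "", files, ignore.case = TRUE)
    is_mask <- grepl("_mask(_[0-9]+)?$", stems)
    for (k in which(!is_mask)) {
      mask_re <- paste0("^", escape_regex(stems[k]), "_mask(_[0-9]+)?$")
      masks <- files[is_mask][grepl(mask_re, stems[is_mask])]
      records[[length(records) + 1L]] <- structure(list(
        image_path = file.path(root_dir, cl, files[k]),
        mask_paths = file.path(root_dir, cl, masks),
        class_label = cl
      ), class = "sample_record")
    }
  }
  records
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Merge ground-truth masks by pixelwise union
#'
#' Images with several lesion masks are merged with a logical OR, so any
#' pixel marked in any mask is foreground. An empty mask list yields the
#' all-zero raster of the given shape (the normal-class case).
#'
#' @param masks list of binary matrices sharing one shape.
#' @param shape integer `c(rows, cols)` used when `masks` is empty.
#' @return a binary integer matrix.
#' @export
merge_masks <- function(masks, shape = NULL) {
  if (length(masks) == 0L) {
    if (is.null(shape)) stop("empty mask list needs an explicit shape")
    return(matrix(0L, shape[1], shape[2]))
  }
  ref <- dim(masks[[1]])
  out <- matrix(0L, ref[1], ref[2])
  for (m in masks) {
    if (!identical(dim(m), ref))
      stop(sprintf("mask shape mismatch: %dx%d vs %dx%d",
                   dim(m)[1], dim(m)[2], ref[1], ref[2]))
    out[m != 0] <- 1L
  }
  out
}

#' Cut or pad a raster to a square
#'
#' `center_crop` removes equal margins from the longer axis, taking the extra
#' pixel from the trailing edge when the total margin is odd; `pad` adds
#' zero margins symmetrically, with the extra pixel on the trailing edge.
#'
#' @param x numeric or integer matrix.
#' @param policy `"center_crop"` or `"pad"`.
#' @return a square matrix.
#' @export
to_square <- function(x, policy = c("center_crop", "pad")) {
  policy <- match.arg(policy)
  nr <- nrow(x); nc <- ncol(x)
  stopifnot(nr >= 1L, nc >= 1L)
  if (nr == nc) return(x)
  if (policy == "center_crop") {
    side <- min(nr, nc)
    lead_r <- (nr - side) %/% 2L
    lead_c <- (nc - side) %/% 2L
    x[lead_r + seq_len(side), lead_c + seq_len(side), drop = FALSE]
  } else {
    side <- max(nr, nc)
    out <- matrix(0, side, side)
    lead_r <- (side - nr) %/% 2L
    lead_c <- (side - nc) %/% 2L
    out[lead_r + seq_len(nr), lead_c + seq_len(nc)] <- x
    if (is.integer(x)) storage.mode(out) <- "integer"
    out
  }
}

# fractional-overlap averaging weights mapping `from` cells onto `to` cells;
# rows sum to 1, entry (i, r) = overlap of output cell i with input cell r
# divided by the output cell width from/to (both in cell units)
block_weights <- function(from, to) {
  w <- matrix(0, to, from)
  scale <- from / to
  for (i in seq_len(to)) {
    lo <- (i - 1) * scale
    hi <- i * scale
    r0 <- floor(lo)
    r1 <- ceiling(hi) - 1
    for (r in r0:r1) {
      ov <- min(hi, r + 1) - max(lo, r)
      if (ov > 0) w[i, r + 1] <- ov / scale
    }
  }
  w
}

#' Binarize and block-downsample a square raster
#'
#' Grayscale input is first thresholded to {0, 1} (`intensity > gray_threshold`
#' is foreground; a no-op for already-binary input), then reduced to
#' `target_side` by area averaging — each output pixel is the overlap-weighted
#' mean of the input pixels its footprint covers, so fractional blocks are
#' handled exactly — and finally re-thresholded: block mean `>= 0.5` maps
#' to 1 (ties are foreground).
#'
#' @param x square numeric matrix with values in {0, 1} or `[0, 255]`.
#' @param target_side output side in pixels; must not exceed the input side.
#' @param gray_threshold grayscale binarization cut (default 127, the
#'   midpoint of the 8-bit range).
#' @return a `target_side` x `target_side` integer matrix in {0, 1}.
#' @export
binarize_downsample <- function(x, target_side, gray_threshold = 127) {
  stopifnot(nrow(x) == ncol(x))
  side <- nrow(x)
  if (target_side > side)
    stop(sprintf("target side %d larger than input side %d: upsampling unsupported",
                 target_side, side))
  b <- if (max(x) > 1) (x > gray_threshold) * 1 else (x != 0) * 1
  w <- block_weights(side, target_side)
  means <- w %*% b %*% t(w)
  out <- matrix(0L, target_side, target_side)
  out[means >= 0.5] <- 1L
  out
}

#' Preprocess one sample record into a binary feature vector
#'
#' The full chain: read the image (for its shape and validity), read and
#' binarize the ground-truth masks, merge them by union, center-crop to a
#' square, block-downsample to `target_side`, and flatten row-major.
#' Records without masks (the normal class) yield the all-zero vector.
#'
#' @param record a `sample_record` from [scan_dataset()], or any list with
#'   `image_path`, `mask_paths`, `class_label`.
#' @param target_side output image side (default 28).
#' @param gray_threshold mask binarization cut (default 127).
#' @return integer vector of length `target_side^2` with values in {0, 1}.
#' @export
preprocess_record <- function(record, target_side = 28L, gray_threshold = 127) {
  img <- read_gray_png(record$image_path)
  masks <- lapply(record$mask_paths, read_gray_png)
  masks <- lapply(masks, function(m) (m > gray_threshold) * 1L)
  merged <- merge_masks(masks, shape = dim(img))
  sq <- to_square(merged, "center_crop")
  small <- binarize_downsample(sq, target_side)
  flatten_image(small)
}

#' Preprocess a list of records into a labeled dataset
#'
#' @param records list of sample records from [scan_dataset()].
#' @param target_side output image side (default 28).
#' @return a [labeled_dataset()] over the package's three classes.
#' @export
preprocess_dataset <- function(records, target_side = 28L) {
  stopifnot(length(records) > 0L)
  X <- matrix(0L, length(records), target_side^2)
  labels <- character(length(records))
  for (i in seq_along(records)) {
    X[i, ] <- preprocess_record(records[[i]], target_side)
    labels[i] <- records[[i]]$class_label
  }
  labeled_dataset(X, labels, class_names = helmus_classes())
}

#' Write a feature matrix with labels as TSV
#'
#' One row per sample: `label` column followed by pixel columns `p1..pD`.
#'
#' @param ds a [labeled_dataset()].
#' @param path output file.
#' @export
write_feature_tsv <- function(ds, path) {
  df <- data.frame(label = ds$labels, ds$X, check.names = FALSE)
  names(df) <- c("label", paste0("p", seq_len(ncol(ds$X))))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
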