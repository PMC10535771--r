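#' Specification for the synthetic lesion-silhouette generator
#'
#' Describes a three-class benchmark of square binary images emulating the
#' silhouettes that the mask-guided preprocessing chain produces from breast
#' ultrasound images: `normal` is an empty field (an empty ground-truth mask
#' yields an all-zero silhouette), `benign` is a smooth filled ellipse, and
#' `malignant` is a star-convex blob with a noisy boundary and radial
#' spicules. Shape parameters are expressed as fractions of the image side so
#' the generator scales with `image_side`.
#'
#' @param n_per_class number of images per class (>= 1).
#' @param image_side side of the square image in pixels (>= 8, default 28).
#' @param benign_radius_range range of ellipse semi-axes, as a fraction of
#'   the image side. Also used for the malignant base ellipse.
#' @param malignant_irregularity range of the boundary-noise amplitude, as a
#'   fraction of the local base radius.
#' @param spicule_count_range integer range of radial spikes added to
#'   malignant blobs.
#' @param speckle salt-noise probability added per background pixel
#'   (default 0 = off); a harder-benchmark option, the standard benchmark
#'   keeps normal images exactly empty.
#' @param seed master seed for the whole dataset.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(n_per_class = 200L,
                       image_side = 28L,
                       benign_radius_range = c(0.15, 0.35),
                       malignant_irregularity = c(0.2, 0.6),
                       spicule_count_range = c(4L, 10L),
                       speckle = 0,
                       seed = 1L) {
  stopifnot(n_per_class >= 1L, image_side >= 8L)
  check_range <- function(r, name) {
    if (length(r) != 2L || !all(is.finite(r)) || r[1] > r[2])
      stop(sprintf("'%s' must be a nonempty range c(low, high) with low <= high", name))
  }
  check_range(benign_radius_range, "benign_radius_range")
  check_range(malignant_irregularity, "malignant_irregularity")
  check_range(spicule_count_range, "spicule_count_range")
  stopifnot(speckle >= 0, speckle < 1)
  structure(list(
    n_per_class = as.integer(n_per_class),
    image_side = as.integer(image_side),
    benign_radius_range = as.numeric(benign_radius_range),
    malignant_irregularity = as.numeric(malignant_irregularity),
    spicule_count_range = as.integer(spicule_count_range),
    speckle = as.numeric(speckle),
    seed = as.integer(seed)
  ), class = "synth_spec")
}

#' Class labels used throughout the package
#'
#' Lexicographic order, matching the dataset directory scan.
#' @export
helmus_classes <- function() c("benign", "malignant", "normal")

# polar radius of a rotated ellipse about its center
ellipse_radius <- function(theta, a, b, phi) {
  a * b / sqrt((b * cos(theta - phi))^2 + (a * sin(theta - phi))^2)
}

# rasterize a star-convex region: pixel is foreground iff its center
# (col - 0.5, row - 0.5) lies inside {d <= r(theta)} around (cx, cy)
rasterize_star <- function(side, cx, cy, radius_fun) {
  xs <- seq_len(side) - 0.5
  dx <- matrix(xs, side, side, byrow = TRUE) - cx
  dy <- matrix(xs, side, side, byrow = FALSE) - cy
  d <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  out <- matrix(0L, side, side)
  out[d <= radius_fun(theta)] <- 1L
  out
}

#' Generate one synthetic lesion silhouette
#'
#' Draws shape parameters from the seeded stream and rasterizes the analytic
#' shape with the center-in-shape rule: a pixel is foreground iff its center
#' lies inside the shape. Normal images are all-zero (plus optional salt
#' noise when `spec$speckle > 0`).
#'
#' @param spec a [synth_spec()].
#' @param class_label one of `"normal"`, `"benign"`, `"malignant"`.
#' @param seed integer seed for this sample's stream.
#' @return an `image_side` x `image_side` integer matrix with values in {0, 1}.
#' @export
generate_sample <- function(spec, class_label, seed) {
  stopifnot(inherits(spec, "synth_spec"))
  if (!class_label %in% c("normal", "benign", "malignant"))
    stop(sprintf("unknown class label '%s'; expected normal, benign or malignant", class_label))
  side <- spec$image_side
  with_seed(seed, {
    img <- switch(class_label,
      normal = matrix(0L, side, side),
      benign = {
        ax <- stats::runif(2, spec$benign_radius_range[1], spec$benign_radius_range[2]) * side
        phi <- stats::runif(1, 0, pi)
        rmax <- max(ax)
        cx <- stats::runif(1, rmax, side - rmax)
        cy <- stats::runif(1, rmax, side - rmax)
        rasterize_star(side, cx, cy, function(theta)
          ellipse_radius(theta, ax[1], ax[2], phi))
      },
      malignant = {
        ax <- stats::runif(2, spec$benign_radius_range[1], spec$benign_radius_range[2]) * side
        phi <- stats::runif(1, 0, pi)
        amp <- stats::runif(1, spec$malignant_irregularity[1], spec$malignant_irregularity[2])
        # smooth boundary noise: low-order random harmonics, peak-normalized
        h <- 2:5
        ch <- stats::runif(length(h), -1, 1)
        ph <- stats::runif(length(h), 0, 2 * pi)
        nspike <- sample(seq(spec$spicule_count_range[1], spec$spicule_count_range[2]), 1)
        sp_theta <- stats::runif(nspike, -pi, pi)
        # spike height is its own scale, not tied to the boundary-noise
        # amplitude; width is chosen so spicules stay resolvable after
        # rasterization at the default 28-pixel side
        sp_amp <- stats::runif(nspike, 0.3, 0.7)
        sp_width <- 0.25 # radians
        grid <- seq(-pi, pi, length.out = 721)
        raw_wave <- function(theta) {
          w <- numeric(length(theta))
          for (k in seq_along(h)) w <- w + ch[k] * cos(h[k] * theta + ph[k])
          w
        }
        wnorm <- max(abs(raw_wave(grid)), 1e-9)
        wave_at <- function(theta) raw_wave(theta) / wnorm
        radius_at <- function(theta) {
          base <- ellipse_radius(theta, ax[1], ax[2], phi)
          r <- base * (1 + amp * wave_at(theta))
          for (s in seq_len(nspike)) {
            d <- (theta - sp_theta[s] + pi) %% (2 * pi) - pi
            r <- r + base * sp_amp[s] * exp(-d^2 / (2 * sp_width^2))
          }
          pmax(r, 0.03 * side)
        }
        rmax <- max(radius_at(grid))
        rmax <- min(rmax, side / 2 - 0.5)
        cx <- stats::runif(1, rmax, side - rmax)
        cy <- stats::runif(1, rmax, side - rmax)
        rasterize_star(side, cx, cy, function(theta) pmin(radius_at(theta), rmax))
      }
    )
    if (spec$speckle > 0) {
      salt <- matrix(stats::runif(side * side) < spec$speckle, side, side)
      img[salt] <- 1L
    }
    img
  })
}

#' Generate a labeled synthetic dataset
#'
#' Produces `3 * n_per_class` silhouettes, balanced across the three classes,
#' shuffled by a seeded permutation. Images are flattened row-major into
#' feature vectors in {0, 1}; a manifest records each row's class.
#'
#' @param spec a [synth_spec()].
#' @return a [labeled_dataset()] with an extra `manifest` data frame
#'   (columns `index`, `class`) and the generating `spec` attached.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  classes <- helmus_classes()
  n <- spec$n_per_class
  side <- spec$image_side
  total <- 3L * n
  X <- matrix(0L, total, side * side)
  labels <- character(total)
  row <- 1L
  for (cl in classes) {
    for (i in seq_len(n)) {
      img <- generate_sample(spec, cl, derive_seed(spec$seed, paste0("sample/", cl, "/", i)))
      X[row, ] <- flatten_image(img)
      labels[row] <- cl
      row <- row + 1L
    }
  }
  perm <- with_seed(derive_seed(spec$seed, "shuffle"), sample.int(total))
  X <- X[perm, , drop = FALSE]
  labels <- labels[perm]
  ds <- labeled_dataset(X, labels, class_names = classes)
  ds$manifest <- data.frame(index = seq_len(total), class = labels,
                            stringsAsFactors = FALSE)
  ds$spec <- spec
  ds
}

#' Boundary-roughness statistic of a binary image
#'
#' Perimeter-squared over area, the classic dimensionless shape-compactness
#' index (4*pi for an ideal disk, larger for rougher boundaries). Perimeter
#' is counted as the number of foreground pixels with at least one 4-neighbor
#' outside the foreground (image border counts as background).
#'
#' @param img binary matrix in {0, 1}.
#' @return `perimeter^2 / area`, or `NA` for an empty image.
#' @export
shape_roughness <- function(img) {
  area <- sum(img)
  if (area == 0) return(NA_real_)
  padded <- matrix(0L, nrow(img) + 2L, ncol(img) + 2L)
  padded[2:(nrow(img) + 1L), 2:(ncol(img) + 1L)] <- img
  core <- padded[2:(nrow(img) + 1L), 2:(ncol(img) + 1L)]
  nb_min <- pmin(
    padded[1:nrow(img), 2:(ncol(img) + 1L)],
    padded[3:(nrow(img) + 2L), 2:(ncol(img) + 1L)],
    padded[2:(nrow(img) + 1L), 1:ncol(img)],
    padded[2:(nrow(img) + 1L), 3:(ncol(img) + 2L)]
  )
  perim <- sum(core == 1L & nb_min == 0L)
  perim^2 / area
}

#' Write a synthetic dataset to disk in the BUSI directory convention
#'
#' Creates `benign/`, `malignant/` and `normal/` subfolders with files named
#' `<class> (<i>).png` plus `<class> (<i>)_mask.png` (the silhouette doubles
#' as its own ground-truth mask), and a `manifest.tsv` with columns
#' `filename`, `class`, so the preprocessing scanner can round-trip it.
#'
#' @param spec a [synth_spec()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, the manifest data frame.
#' @export
write_synth_busi <- function(spec, out_dir) {
  stopifnot(inherits(spec, "synth_spec"))
  rows <- list()
  for (cl in helmus_classes()) {
    dir.create(file.path(out_dir, cl), recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(spec$n_per_class)) {
      img <- generate_sample(spec, cl, derive_seed(spec$seed, paste0("sample/", cl, "/", i)))
      stem <- sprintf("%s (%d)", cl, i)
      png::writePNG(img * 1.0, file.path(out_dir, cl, paste0(stem, ".png")))
      png::writePNG(img * 1.0, file.path(out_dir, cl, paste0(stem, "_mask.png")))
      rows[[length(rows) + 1L]] <- data.frame(
        filename = file.path(cl, paste0(stem, ".png")), class = cl,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

# row-major flatten: R matrices are column-major, so transpose first
flatten_image <- function(img) as.integer(t(img))
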