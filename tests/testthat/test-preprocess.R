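test_that("mask union counts, empty-list shape, and error reporting", {
  m1 <- matrix(0L, 4, 4); m1[1, 1] <- 1L
  m2 <- matrix(0L, 4, 4); m2[3, 2] <- 1L
  expect_equal(sum(merge_masks(list(m1, m2))), 2L)
  expect_identical(merge_masks(list(), shape = c(4L, 4L)), matrix(0L, 4, 4))
  expect_error(merge_masks(list(m1, matrix(0L, 3, 4))), "4x4")
})

test_that("mask union is commutative, associative, and idempotent", {
  set.seed(7)
  for (i in 1:20) {
    ms <- replicate(3, matrix(rbinom(25, 1, 0.3), 5, 5), simplify = FALSE)
    ab <- merge_masks(ms[1:2])
    ba <- merge_masks(ms[2:1])
    expect_identical(ab, ba)
    expect_identical(merge_masks(list(ab, ms[[3]])),
                     merge_masks(list(ms[[1]], merge_masks(ms[2:3]))))
    expect_identical(merge_masks(list(ms[[1]], ms[[1]])),
                     merge_masks(ms[1]))
  }
})

test_that("square sizing follows the stated margin rules", {
  x64 <- matrix(seq_len(24), 6, 4)
  expect_identical(to_square(x64, "center_crop"), x64[2:5, ])
  x54 <- matrix(seq_len(20), 5, 4)
  expect_identical(to_square(x54, "center_crop"), x54[1:4, ]) # odd margin: trailing edge
  sq <- matrix(1:9, 3, 3)
  expect_identical(to_square(sq, "center_crop"), sq)
  expect_identical(to_square(sq, "pad"), sq)
  # padding puts the extra zero row/col on the trailing edge
  p <- to_square(matrix(1, 2, 3), "pad")
  expect_equal(dim(p), c(3L, 3L))
  expect_equal(p[1, ], c(1, 1, 1))
  expect_equal(p[3, ], c(0, 0, 0))
  # wide input crops columns
  x46 <- matrix(seq_len(24), 4, 6)
  expect_identical(to_square(x46, "center_crop"), x46[, 2:5])
})

test_that("block downsampling is exact on homogeneous-block cases", {
  expect_identical(binarize_downsample(matrix(1L, 56, 56), 28L),
                   matrix(1L, 28, 28))
  quad <- matrix(0L, 56, 56)
  quad[1:28, 1:28] <- 1L
  expected <- matrix(0L, 28, 28)
  expected[1:14, 1:14] <- 1L
  expect_identical(binarize_downsample(quad, 28L), expected)
})

test_that("fractional-overlap downsampling matches brute-force integration", {
  set.seed(12)
  x <- matrix(rbinom(900, 1, 0.5), 30, 30)
  expect_identical(binarize_downsample(x, 28L), oracle_downsample(x, 28L))
  x2 <- matrix(rbinom(49, 1, 0.4), 7, 7)
  expect_identical(binarize_downsample(x2, 5L), oracle_downsample(x2, 5L))
  expect_identical(binarize_downsample(x2, 3L), oracle_downsample(x2, 3L))
})

test_that("upsampling is refused and grayscale is thresholded at the midpoint", {
  expect_error(binarize_downsample(matrix(0L, 10, 10), 20L), "unsupport")
  gray <- matrix(c(0, 100, 127, 128, 200, 255, 30, 250, 90), 3, 3)
  out <- binarize_downsample(gray, 3L)
  expect_identical(out, matrix(as.integer(gray > 127), 3, 3))
})

test_that("large downsampling preserves disk area fractions", {
  side <- 600L
  for (s in 1:10) {
    set.seed(s)
    r <- 0.3 * side
    cx <- runif(1, r + 1, side - r - 1)
    cy <- runif(1, r + 1, side - r - 1)
    xs <- seq_len(side) - 0.5
    disk <- 1L * (outer((xs - cy)^2, (xs - cx)^2, "+") <= r^2)
    small <- binarize_downsample(disk, 28L)
    frac <- sum(small) / length(small)
    expect_gt(frac, pi * 0.3^2 * 0.8)
    expect_lt(frac, pi * 0.3^2 * 1.2)
  }
})

test_that("scanner attaches multi-mask files and skips unknown folders", {
  root <- withr::local_tempdir()
  dir.create(file.path(root, "benign"))
  dir.create(file.path(root, "mystery"))
  img <- matrix(0.5, 8, 8)
  png::writePNG(img, file.path(root, "benign", "benign (1).png"))
  png::writePNG(img, file.path(root, "benign", "benign (1)_mask.png"))
  png::writePNG(img, file.path(root, "benign", "benign (1)_mask_1.png"))
  png::writePNG(img, file.path(root, "benign", "benign (2).png"))
  expect_warning(records <- scan_dataset(root), "mystery")
  expect_length(records, 2L)
  expect_length(records[[1]]$mask_paths, 2L)
  expect_length(records[[2]]$mask_paths, 0L)
  empty <- withr::local_tempdir()
  expect_length(scan_dataset(empty), 0L)
})

test_that("record preprocessing yields correct-length binary vectors", {
  root <- withr::local_tempdir()
  dir.create(file.path(root, "normal"))
  dir.create(file.path(root, "malignant"))
  png::writePNG(matrix(0.3, 60, 40), file.path(root, "normal", "normal (1).png"))
  png::writePNG(matrix(0.3, 60, 40), file.path(root, "malignant", "malignant (1).png"))
  png::writePNG(matrix(1, 60, 40), file.path(root, "malignant", "malignant (1)_mask.png"))
  records <- scan_dataset(root)
  vecs <- lapply(records, preprocess_record, target_side = 28L)
  labs <- vapply(records, `[[`, "", "class_label")
  expect_true(all(lengths(vecs) == 784L))
  # no masks -> all-zero vector; all-ones mask -> all-one vector
  expect_identical(vecs[[which(labs == "normal")]], rep(0L, 784L))
  expect_identical(vecs[[which(labs == "malignant")]], rep(1L, 784L))
  # byte-identical across runs
  expect_identical(vecs, lapply(records, preprocess_record, target_side = 28L))
})

test_that("a synthetic tree preprocesses into the dataset it was written from", {
  spec <- synth_spec(n_per_class = 2L, image_side = 28L, seed = 9L)
  root <- withr::local_tempdir()
  write_synth_busi(spec, root)
  ds <- preprocess_dataset(scan_dataset(root), 28L)
  expect_equal(nrow(ds$X), 6L)
  expect_true(all(ds$X %in% c(0L, 1L)))
  # 28x28 inputs pass through the chain unchanged
  img <- generate_sample(spec, "benign", derive_seed(9L, "sample/benign/1"))
  expect_equal(ds$X[which(ds$labels == "benign")[1], ], as.integer(t(img)))
})
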