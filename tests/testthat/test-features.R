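test_that("grayscale conversion uses the 601 luma weights exactly", {
  expect_equal(to_grayscale(array(100, c(4, 4, 3))),
               matrix(100, 4, 4))
  red <- array(0, c(3, 3, 3)); red[, , 1] <- 255
  expect_equal(to_grayscale(red), matrix(0.299 * 255, 3, 3))
  expect_equal(to_grayscale(array(255, c(2, 2, 3))), matrix(255, 2, 2))
})

test_that("brightness and contrast match hand-derived values", {
  expect_equal(brightness(array(100, c(4, 4, 3))), 100)
  half <- gray_image(rbind(matrix(0, 2, 4), matrix(255, 2, 4)))
  expect_equal(brightness(half), 127.5)
  expect_equal(contrast(array(42, c(5, 5, 3))), 0)
  two <- gray_image(matrix(c(0, 255), 2, 1))
  expect_equal(contrast(two), 127.5, tolerance = 1e-12)
  board <- gray_image(255 * (outer(1:8, 1:8, "+") %% 2))
  expect_equal(contrast(board), 127.5, tolerance = 1e-12)
})

test_that("Laplacian sharpness matches hand convolution with zero padding", {
  expect_equal(sharpness(array(0, c(5, 5, 3))), 0)
  m <- matrix(0, 3, 3); m[2, 2] <- 255
  expect_equal(sharpness(gray_image(m)), (1020 + 4 * 255) / 9,
               tolerance = 1e-12)
  # interior uniform region contributes zero response
  big <- matrix(7, 9, 9)
  resp_interior <- sharpness(gray_image(big)) * 81 -
    (sum(abs(c(rep(-2 * 7, 4), rep(-7, 4 * 7)))))  # corners + edges only
  expect_equal(resp_interior, 0, tolerance = 1e-9)
  expect_error(sharpness(array(1, c(2, 2, 3))), "3 x 3")
})

test_that("saturation follows (max-min)/max with the zero-max convention", {
  expect_equal(saturation(array(123, c(4, 4, 3))), 0)
  red <- array(0, c(4, 4, 3)); red[, , 1] <- 255
  expect_equal(saturation(red), 1)
  mixed <- array(100, c(2, 2, 3))
  mixed[1, , 1] <- 255; mixed[1, , 2] <- 0; mixed[1, , 3] <- 0
  expect_equal(saturation(mixed), 0.5)
  expect_equal(saturation(array(0, c(3, 3, 3))), 0)
})

test_that("colorfulness matches the opponent-component closed forms", {
  expect_equal(colorfulness(gray_image(matrix(runif(16, 0, 255), 4, 4))), 0)
  two <- array(0, c(2, 1, 3))
  two[1, 1, ] <- c(255, 0, 0); two[2, 1, ] <- c(0, 255, 0)
  expect_equal(colorfulness(two), 255 + 0.3 * 127.5, tolerance = 1e-12)
  const_red <- array(0, c(4, 4, 3)); const_red[, , 1] <- 255
  expect_equal(colorfulness(const_red),
               0.3 * sqrt(255^2 + 127.5^2), tolerance = 1e-12)
})

test_that("quadtree decomposition obeys the split rule and leaf geometry", {
  p <- quadtree_params(variance_threshold = 10, min_block_size = 2,
                       max_depth = 8)
  const <- matrix(5, 16, 16)
  qt <- quadtree_decompose(const, p)
  expect_true(qt$root$leaf)
  expect_identical(qt$leaf_count, 1L)
  # infinite threshold never splits
  board <- 255 * (outer(1:16, 1:16, "+") %% 2)
  expect_identical(quadtree_decompose(board,
                                      quadtree_params(Inf, 2, 8))$leaf_count,
                   1L)
  # leaves tile the image exactly
  qt2 <- quadtree_decompose(board, p)
  area <- function(node) {
    if (node$leaf) return(node$height * node$width)
    sum(vapply(node$children, area, numeric(1)))
  }
  expect_equal(area(qt2$root), 16 * 16)
  expect_error(quadtree_decompose(matrix(1, 4, 4),
                                  quadtree_params(10, 8, 6)),
               "configuration error")
})

test_that("complexity equals an independent brute-force oracle", {
  p <- quadtree_params(variance_threshold = 10, min_block_size = 2,
                       max_depth = 8)
  for (seed in 1:30) {
    dims <- withr::with_seed(seed + 500, sample(5:32, 2))
    m <- random_gray_matrix(dims[1], dims[2], seed,
                            levels = if (seed %% 2) NULL else c(0, 255))
    expect_identical(quadtree_decompose(m, p)$leaf_count,
                     oracle_leaf_count(m, 10, 2, 8),
                     info = paste("seed", seed))
  }
})

test_that("adding texture to a quadrant never decreases complexity", {
  base <- matrix(10, 32, 32)
  p <- quadtree_params(variance_threshold = 5, min_block_size = 4,
                       max_depth = 5)
  c0 <- complexity(gray_image(base), p)
  withtex <- base
  withtex[1:8, 1:8] <- withr::with_seed(9, matrix(runif(64, 0, 255), 8, 8))
  expect_gte(complexity(gray_image(withtex), p), c0)
})

test_that("symmetry is 100 for mirror-symmetric images and matches the count formula", {
  p <- quadtree_params(variance_threshold = 10, min_block_size = 2,
                       max_depth = 6)
  half <- random_gray_matrix(16, 8, 3)
  mirrored <- cbind(half, half[, 8:1])
  expect_equal(symmetry(gray_image(mirrored), "vertical", p), 100)
  expect_equal(symmetry(gray_image(matrix(7, 12, 12)), "vertical", p), 100)
  # asymmetric: constant left half, textured right half
  img <- cbind(matrix(0, 16, 8), random_gray_matrix(16, 8, 4))
  t1 <- oracle_leaf_count(img[, 1:8], 10, 2, 6)
  t2 <- oracle_leaf_count(img[, 9:16], 10, 2, 6)
  expect_equal(symmetry(gray_image(img), "vertical", p),
               100 * (1 - abs(t1 - t2) / max(t1, t2)))
  expect_lt(symmetry(gray_image(img), "vertical", p), 100)
})

test_that("pixel-permutation invariance holds for multiset statistics only", {
  img <- random_image(8, 8, 11)
  perm <- withr::with_seed(12, sample(64))
  pimg <- array(0, dim(img))
  for (k in 1:3) pimg[, , k] <- matrix(as.numeric(img[, , k])[perm], 8, 8)
  expect_equal(brightness(pimg), brightness(img), tolerance = 1e-12)
  expect_equal(contrast(pimg), contrast(img), tolerance = 1e-12)
  expect_equal(saturation(pimg), saturation(img), tolerance = 1e-12)
  expect_equal(colorfulness(pimg), colorfulness(img), tolerance = 1e-12)
  # spatial statistics are not permutation invariant on a generic image
  expect_false(isTRUE(all.equal(sharpness(pimg), sharpness(img))))
})

test_that("storage-order invariance: transposed images give the same multiset statistics", {
  img <- random_image(6, 9, 21)
  timg <- array(0, c(9, 6, 3))
  for (k in 1:3) timg[, , k] <- t(img[, , k])
  expect_equal(brightness(timg), brightness(img))
  expect_equal(contrast(timg), contrast(img))
  expect_equal(colorfulness(timg), colorfulness(img))
})

test_that("feature extraction composes the operators deterministically", {
  g <- array(90, c(16, 16, 3))
  f <- extract_features(g)
  expect_equal(unname(f[c("contrast", "saturation", "colorfulness")]),
               c(0, 0, 0))
  expect_equal(unname(f["complexity"]), 1)
  expect_equal(unname(f["symmetry"]), 100)
  img <- random_image(16, 16, 31)
  expect_identical(extract_features(img), extract_features(img))
})

test_that("standardization reaches its defining moments and is idempotent", {
  cfg <- tiny_cfg(n_categories = 4L)
  seqs <- generate_dataset(cfg)
  tbl <- extract_feature_table(seqs)
  z <- standardize_features(tbl, "zscore", "global")
  for (f in c("brightness", "contrast", "colorfulness")) {
    expect_equal(mean(z[[f]]), 0, tolerance = 1e-9)
    expect_equal(sd(z[[f]]), 1, tolerance = 1e-9)
  }
  z2 <- standardize_features(z, "zscore", "global")
  expect_equal(z2$brightness, z$brightness, tolerance = 1e-9)
  mm <- standardize_features(tbl, "minmax", "global")
  expect_equal(min(mm$brightness), 0)
  expect_equal(max(mm$brightness), 1)
  flat <- tbl; flat$symmetry <- 50
  expect_warning(standardize_features(flat, "zscore", "global"),
                 "zero spread")
})
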