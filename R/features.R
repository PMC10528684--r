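#' Convert an RGB image to grayscale luma
#'
#' Uses the ITU-R 601 weights `L = 0.299 R + 0.587 G + 0.114 B`, the common
#' default of mainstream imaging libraries.  Values are kept real-valued
#' (no rounding) so downstream statistics are exact.
#'
#' @param img an `H x W x 3` array with values in `[0, 255]`
#' @return an `H x W` matrix of luma values in `[0, 255]`
#' @export
#' @examples
#' img <- array(100, c(4, 4, 3))
#' range(to_grayscale(img))  # 100 100
to_grayscale <- function(img) {
  assert_image(img)
  luma_matrix(img)
}

#' Mean brightness of an image
#'
#' The mean of the grayscale (luma) pixel values; high for bright images.
#'
#' @inheritParams to_grayscale
#' @return scalar in `[0, 255]`
#' @export
brightness <- function(img) {
  mean(to_grayscale(img))
}

#' RMS contrast of an image
#'
#' The population standard deviation of the grayscale pixel values; zero
#' for constant images.
#'
#' @inheritParams to_grayscale
#' @return nonnegative scalar
#' @export
contrast <- function(img) {
  sd_pop(to_grayscale(img))
}

#' Laplacian sharpness of an image
#'
#' The mean absolute response of the grayscale image to the 3x3
#' four-neighbour Laplacian kernel `[[0,1,0],[1,-4,1],[0,1,0]]` under zero
#' padding.  The absolute value is required for a meaningful mean: signed
#' responses cancel over any closed region.
#'
#' @inheritParams to_grayscale
#' @return nonnegative scalar; 0 for an all-zero image
#' @export
sharpness <- function(img) {
  g <- to_grayscale(img)
  nr <- nrow(g); nc <- ncol(g)
  if (nr < 3L || nc < 3L)
    stop("image must be at least 3 x 3 for the Laplacian filter", call. = FALSE)
  p <- matrix(0, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- g
  resp <- p[1:nr, 2:(nc + 1L)] + p[3:(nr + 2L), 2:(nc + 1L)] +
    p[2:(nr + 1L), 1:nc] + p[2:(nr + 1L), 3:(nc + 2L)] - 4 * g
  mean(abs(resp))
}

#' Mean HSV saturation of an image
#'
#' Per pixel `S = (max - min) / max` over the three channels (0 when
#' `max = 0`), averaged over the image.  Grayscale pixels have S = 0.
#'
#' @inheritParams to_grayscale
#' @return scalar in `[0, 1]`
#' @export
saturation <- function(img) {
  assert_image(img)
  mx <- pmax(img[, , 1L], img[, , 2L], img[, , 3L])
  mn <- pmin(img[, , 1L], img[, , 2L], img[, , 3L])
  s <- ifelse(mx == 0, 0, (mx - mn) / mx)
  mean(s)
}

#' Hasler-Suesstrunk colorfulness of an image
#'
#' With opponent components `rg = R - G` and `yb = (R + G)/2 - B` computed
#' per pixel, returns
#' `sqrt(sd(rg)^2 + sd(yb)^2) + 0.3 * sqrt(mean(rg)^2 + mean(yb)^2)`
#' using population standard deviations.  Zero for any image with
#' `R = G = B` everywhere.
#'
#' @inheritParams to_grayscale
#' @return nonnegative scalar
#' @export
colorfulness <- function(img) {
  assert_image(img)
  rg <- img[, , 1L] - img[, , 2L]
  yb <- (img[, , 1L] + img[, , 2L]) / 2 - img[, , 3L]
  sqrt(sd_pop(rg)^2 + sd_pop(yb)^2) + 0.3 * sqrt(mean(rg)^2 + mean(yb)^2)
}

#' Quadtree decomposition parameters
#'
#' A block is split into four quadrants when its population SD exceeds
#' `variance_threshold`, both halved dimensions stay at least
#' `min_block_size`, and the depth is below `max_depth`.  Defaults are
#' tuned so 64-256 px images give informative leaf counts.
#'
#' @param variance_threshold nonnegative; split when block SD exceeds it
#' @param min_block_size integer, at least 2
#' @param max_depth integer, maximum recursion depth (root is depth 0)
#' @return a `quadtree_params` list
#' @export
quadtree_params <- function(variance_threshold = 25,
                            min_block_size = 8L,
                            max_depth = 6L) {
  stopifnot(variance_threshold >= 0, min_block_size >= 2, max_depth >= 0)
  structure(list(variance_threshold = variance_threshold,
                 min_block_size = as.integer(min_block_size),
                 max_depth = as.integer(max_depth)),
            class = "quadtree_params")
}

quadtree_node <- function(gray, top, left, h, w, depth, params) {
  block <- gray[top:(top + h - 1L), left:(left + w - 1L), drop = FALSE]
  h1 <- h %/% 2L; w1 <- w %/% 2L
  split <- depth < params$max_depth &&
    h1 >= params$min_block_size && w1 >= params$min_block_size &&
    sd_pop(block) > params$variance_threshold
  node <- list(top = top, left = left, height = h, width = w,
               leaf = !split, children = NULL)
  if (split) {
    # odd dimensions split as floor/ceil halves
    h2 <- h - h1; w2 <- w - w1
    node$children <- list(
      quadtree_node(gray, top,       left,       h1, w1, depth + 1L, params),
      quadtree_node(gray, top,       left + w1,  h1, w2, depth + 1L, params),
      quadtree_node(gray, top + h1,  left,       h2, w1, depth + 1L, params),
      quadtree_node(gray, top + h1,  left + w1,  h2, w2, depth + 1L, params))
  }
  node
}

count_leaves <- function(node) {
  if (node$leaf) return(1L)
  sum(vapply(node$children, count_leaves, integer(1L)))
}

#' Quadtree decomposition of a grayscale image
#'
#' Recursively splits the image into four quadrants wherever local pixel
#' variation (population SD) exceeds the threshold.  The leaf count of the
#' resulting tree is the visual-complexity statistic.
#'
#' @param gray an `H x W` numeric matrix of values in `[0, 255]`
#' @param params a [quadtree_params()] object
#' @return a `quadtree` list with elements `root` (nested nodes, each with
#'   `top`, `left`, `height`, `width`, `leaf`, `children`) and `leaf_count`
#' @export
quadtree_decompose <- function(gray, params = quadtree_params()) {
  stopifnot(is.matrix(gray), is.numeric(gray))
  if (min(dim(gray)) < params$min_block_size)
    stop("configuration error: min_block_size exceeds an image dimension",
         call. = FALSE)
  root <- quadtree_node(gray, 1L, 1L, nrow(gray), ncol(gray), 0L, params)
  structure(list(root = root, leaf_count = count_leaves(root)),
            class = "quadtree")
}

#' Visual complexity of an image
#'
#' The number of leaves of the quadtree decomposition of the grayscale
#' image; 1 for a constant image, growing with local pixel variation.
#'
#' @inheritParams to_grayscale
#' @param params a [quadtree_params()] object
#' @return integer, at least 1
#' @export
complexity <- function(img, params = quadtree_params()) {
  quadtree_decompose(to_grayscale(img), params)$leaf_count
}

#' Quadtree symmetry of an image
#'
#' Decomposes the two halves of the image about the chosen axis separately
#' and compares their leaf counts `T1`, `T2`:
#' `100 * (1 - |T1 - T2| / max(T1, T2))`.  Mirror-symmetric images score
#' 100.  For odd dimensions the centre row/column is dropped so the halves
#' are congruent.
#'
#' @inheritParams complexity
#' @param axis `"vertical"` compares left vs right halves (default),
#'   `"horizontal"` compares top vs bottom
#' @return scalar in `[0, 100]`
#' @export
symmetry <- function(img, axis = c("vertical", "horizontal"),
                     params = quadtree_params()) {
  axis <- match.arg(axis)
  g <- to_grayscale(img)
  if (axis == "vertical") {
    half <- ncol(g) %/% 2L
    a <- g[, seq_len(half), drop = FALSE]
    b <- g[, seq.int(ncol(g) - half + 1L, ncol(g)), drop = FALSE]
  } else {
    half <- nrow(g) %/% 2L
    a <- g[seq_len(half), , drop = FALSE]
    b <- g[seq.int(nrow(g) - half + 1L, nrow(g)), , drop = FALSE]
  }
  t1 <- quadtree_decompose(a, params)$leaf_count
  t2 <- quadtree_decompose(b, params)$leaf_count
  100 * (1 - abs(t1 - t2) / max(t1, t2))
}

#' Extract the seven image features
#'
#' Applies the low-level operators (brightness, contrast, sharpness,
#' saturation) and the mid-level operators (colorfulness, quadtree
#' complexity and symmetry) to one image.  Deterministic.
#'
#' @inheritParams complexity
#' @return named numeric vector with elements `brightness`, `contrast`,
#'   `sharpness`, `saturation`, `colorfulness`, `complexity`, `symmetry`
#' @export
extract_features <- function(img, params = quadtree_params()) {
  assert_image(img)
  c(brightness = brightness(img),
    contrast = contrast(img),
    sharpness = sharpness(img),
    saturation = saturation(img),
    colorfulness = colorfulness(img),
    complexity = as.numeric(complexity(img, params)),
    symmetry = symmetry(img, params = params))
}

#' Extract features for every image of one or more sequences
#'
#' @param sequences an `image_sequence` or list of them
#' @param params a [quadtree_params()] object
#' @return data frame with columns `category_id`, `alpha`,
#'   `aesthetic_score` and the seven feature columns, one row per image
#' @export
extract_feature_table <- function(sequences, params = quadtree_params()) {
  if (inherits(sequences, "image_sequence")) sequences <- list(sequences)
  rows <- lapply(sequences, function(s) {
    fv <- t(vapply(s$images, extract_features, numeric(7L), params = params))
    data.frame(category_id = s$category_id, alpha = s$alpha_levels,
               aesthetic_score = s$aesthetic_scores, fv,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Standardize feature columns of a feature table
#'
#' Centres and scales each feature column, either to z-scores (mean 0,
#' SD 1) or to the `[0, 1]` range, globally or within each category.
#' A feature with zero spread in a group is set to 0 with a warning, which
#' signals a degenerate generator configuration.
#'
#' @param tbl data frame with `category_id` and feature columns
#' @param mode `"zscore"` (default) or `"minmax"`
#' @param scope `"global"` (default) or `"within_category"`
#' @param features character vector of columns to standardize
#' @return `tbl` with the named columns standardized
#' @export
standardize_features <- function(tbl, mode = c("zscore", "minmax"),
                                 scope = c("global", "within_category"),
                                 features = .FEATURE_NAMES) {
  mode <- match.arg(mode)
  scope <- match.arg(scope)
  stopifnot(all(features %in% names(tbl)))
  std1 <- function(x, feat) {
    if (mode == "zscore") {
      s <- stats::sd(x)
      if (length(x) < 2L || !is.finite(s) || s == 0) {
        warning(sprintf("feature '%s' has zero spread; set to 0", feat),
                call. = FALSE)
        return(rep(0, length(x)))
      }
      (x - mean(x)) / s
    } else {
      r <- range(x)
      if (r[1L] == r[2L]) {
        warning(sprintf("feature '%s' has zero spread; set to 0", feat),
                call. = FALSE)
        return(rep(0, length(x)))
      }
      (x - r[1L]) / (r[2L] - r[1L])
    }
  }
  for (f in features) {
    if (scope == "global") {
      tbl[[f]] <- std1(tbl[[f]], f)
    } else {
      for (id in unique(tbl$category_id)) {
        i <- tbl$category_id == id
        tbl[[f]][i] <- std1(tbl[[f]][i], f)
      }
    }
  }
  tbl
}
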