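# deterministic random image fixtures and an independent quadtree oracle

random_image <- function(h, w, seed) {
  withr::with_seed(seed, array(runif(h * w * 3, 0, 255), c(h, w, 3)))
}

random_gray_matrix <- function(h, w, seed, levels = NULL) {
  withr::with_seed(seed, {
    if (is.null(levels)) matrix(runif(h * w, 0, 255), h, w)
    else matrix(sample(levels, h * w, replace = TRUE), h, w)
  })
}

gray_image <- function(m) {
  array(rep(m, 3L), c(dim(m), 3L))
}

# Brute-force quadtree leaf counter, written independently of the package
# implementation: iterative worklist instead of recursion, SD computed from
# raw sums.
oracle_leaf_count <- function(gray, threshold, min_block, max_depth) {
  work <- list(c(1L, 1L, nrow(gray), ncol(gray), 0L))
  leaves <- 0L
  while (length(work)) {
    blk <- work[[length(work)]]
    work[[length(work)]] <- NULL
    top <- blk[1L]; left <- blk[2L]; h <- blk[3L]; w <- blk[4L]; d <- blk[5L]
    v <- as.numeric(gray[top:(top + h - 1L), left:(left + w - 1L)])
    n <- length(v)
    sd_p <- sqrt(sum(v^2) / n - (sum(v) / n)^2)
    h1 <- h %/% 2L; w1 <- w %/% 2L
    if (d < max_depth && h1 >= min_block && w1 >= min_block &&
        sd_p > threshold + 1e-12 * max(1, threshold)) {
      work <- c(work, list(
        c(top, left, h1, w1, d + 1L),
        c(top, left + w1, h1, w - w1, d + 1L),
        c(top + h1, left, h - h1, w1, d + 1L),
        c(top + h1, left + w1, h - h1, w - w1, d + 1L)))
    } else {
      leaves <- leaves + 1L
    }
  }
  leaves
}

# small standard observer used across behavioral tests
default_truth <- function() {
  observer_model(threshold_mu = 0, slope_s = 0.05,
                 guess_gamma = 0.07, lapse_lambda = 0.17)
}

tiny_cfg <- function(n_categories = 6L, image_size = 32L, ...) {
  generator_config(n_categories = n_categories, image_size = image_size, ...)
}
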