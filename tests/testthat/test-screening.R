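test_that("histogram counts are exact and conserve the pixel count", {
  cfg <- tiny_cfg(n_categories = 2L, image_size = 16L)
  s <- generate_sequence("cat0001", cfg)
  h <- rgb_histograms(s)
  sums <- tapply(h$count, paste(h$alpha, h$channel), sum)
  expect_true(all(sums == 16 * 16))
  # constant image: one nonzero bin per channel at its level
  s2 <- s
  s2$alpha_levels <- 0
  img <- array(0, c(8, 8, 3))
  img[, , 1] <- 10; img[, , 2] <- 20; img[, , 3] <- 30
  s2$images <- list(img)
  s2$aesthetic_scores <- 0.5
  h2 <- rgb_histograms(s2)
  nz <- h2[h2$count > 0, ]
  expect_identical(nrow(nz), 3L)
  expect_identical(nz$intensity, c(10L, 20L, 30L))
  expect_true(all(nz$count == 64))
})

screen_feature_table <- function(n, seed = 1L, zero_ids = character()) {
  # synthetic standardized feature table with controlled per-category change
  ids <- sprintf("cat%04d", seq_len(n))
  withr::with_seed(seed, {
    rows <- lapply(ids, function(id) {
      delta <- if (id %in% zero_ids) 0 else runif(1, 0.5, 2)
      data.frame(category_id = id, alpha = c(-0.25, 0.25),
                 aesthetic_score = c(0.3, 0.7),
                 brightness = c(0, delta), contrast = c(0, delta / 2),
                 sharpness = c(0, delta / 3), saturation = c(0, delta / 4),
                 colorfulness = c(0, delta), complexity = c(1, 1),
                 symmetry = c(50, 50))
    })
    do.call(rbind, rows)
  })
}

test_that("the stability screen selects the flattest 5% with exact size", {
  tbl <- screen_feature_table(100L, zero_ids = "cat0042")
  res <- stable_feature_sequences(tbl)
  expect_identical(res$n_selected, 5L)
  expect_length(res$selected, 5L)
  expect_true("cat0042" %in% res$selected)
  # selected statistics are the smallest ones
  stat <- res$statistic_per_category
  expect_lte(max(stat[res$selected]), min(stat[setdiff(names(stat),
                                                       res$selected)]))
})

test_that("screens break ties deterministically by category id", {
  tbl <- screen_feature_table(40L)
  for (f in c("brightness", "contrast", "sharpness", "saturation"))
    tbl[[f]] <- rep(c(0, 1), 40L)  # all categories identical change
  res <- stable_feature_sequences(tbl)
  expect_identical(res$selected, sprintf("cat%04d", 1:2))
  expect_identical(res$n_selected, as.integer(ceiling(0.05 * 40)))
  # permutation of input rows does not change the selection
  perm <- withr::with_seed(2, sample(nrow(tbl)))
  expect_identical(stable_feature_sequences(tbl[perm, ])$selected,
                   res$selected)
})

test_that("categories missing an extreme level are skipped with a warning", {
  tbl <- screen_feature_table(20L)
  tbl <- tbl[!(tbl$category_id == "cat0003" & tbl$alpha == 0.25), ]
  expect_warning(res <- stable_feature_sequences(tbl), "skipped")
  expect_false("cat0003" %in% names(res$statistic_per_category))
})

test_that("the downturn screen recovers planted downturn categories exactly", {
  cfg <- generator_config(n_categories = 40L, image_size = 16L,
                          noise_sd = 0, downturn_fraction = 0.05)
  seqs <- generate_dataset(cfg)
  planted <- names(seqs)[vapply(seqs, `[[`, logical(1), "downturn")]
  res <- aesthetic_downturn_sequences(seqs)
  expect_identical(res$n_selected, as.integer(ceiling(0.05 * 40)))
  expect_setequal(res$selected, planted)
})

test_that("the downturn screen applies its definition when all scores increase", {
  cfg <- generator_config(n_categories = 40L, image_size = 16L,
                          noise_sd = 0, downturn_fraction = 0)
  seqs <- generate_dataset(cfg)
  res <- aesthetic_downturn_sequences(seqs)
  expect_length(res$selected, 2L)
  expect_true(all(res$statistic_per_category < 0))
})

test_that("gaussian summaries use population moments", {
  s <- gaussian_summary_of(matrix(c(0, 2), ncol = 1))
  expect_equal(unname(s$mean), 1)
  expect_equal(unname(s$cov[1, 1]), 1)  # population variance of {0, 2}
  imgs <- list(array(100, c(16, 16, 3)), array(100, c(16, 16, 3)))
  g <- embed_images(imgs)
  expect_equal(max(abs(g$cov)), 0)
  expect_equal(max(abs(g$cov - t(g$cov))), 0, tolerance = 1e-12)
  expect_error(embed_images(imgs[1]), "at least 2")
})

test_that("the Frechet distance matches the 1-D closed form", {
  expect_equal(frechet_distance(
    gaussian_summary_of(matrix(c(-1, 1), ncol = 1)),
    gaussian_summary_of(matrix(c(0, 2), ncol = 1))), 1, tolerance = 1e-10)
  withr::with_seed(77, {
    for (i in 1:200) {
      mu <- rnorm(2); sdv <- runif(2, 0.1, 3)
      a <- list(mean = mu[1], cov = matrix(sdv[1]^2, 1, 1))
      b <- list(mean = mu[2], cov = matrix(sdv[2]^2, 1, 1))
      expect_equal(frechet_distance(a, b),
                   (mu[1] - mu[2])^2 + (sdv[1] - sdv[2])^2,
                   tolerance = 1e-8)
    }
  })
})

test_that("the Frechet distance is symmetric, nonnegative and zero at identity", {
  withr::with_seed(78, {
    for (i in 1:20) {
      x <- matrix(rnorm(40), 10, 4)
      y <- matrix(rnorm(40, 1), 10, 4)
      a <- gaussian_summary_of(x); b <- gaussian_summary_of(y)
      dab <- frechet_distance(a, b)
      expect_gte(dab, 0)
      expect_equal(dab, frechet_distance(b, a), tolerance = 1e-8)
      expect_equal(frechet_distance(a, a), 0, tolerance = 1e-8)
    }
  })
  a <- gaussian_summary_of(matrix(rnorm(20), 10, 2))
  b <- gaussian_summary_of(matrix(rnorm(30), 10, 3))
  expect_error(frechet_distance(a, b), "dimension mismatch")
})

test_that("the Frechet profile is zero at the reference level", {
  cfg <- generator_config(n_categories = 4L, image_size = 16L)
  seqs <- generate_dataset(cfg)
  prof <- frechet_profile(seqs, reference_alpha = 0.25)
  expect_equal(prof$frechet[prof$alpha == 0.25], 0, tolerance = 1e-6)
  expect_true(all(prof$frechet >= 0))
})
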