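feature_fixture <- function(n = 400L, seed = 1L, noise_sd = 0.3) {
  beta <- c(brightness = 0.6, contrast = 0.4, sharpness = 0.5,
            saturation = 0.4, colorfulness = 0.6, complexity = -0.2,
            symmetry = 0)
  simulate_feature_scores(n, beta, intercept = -0.2, rho = 0.4,
                          noise_sd = noise_sd, seed = seed)
}

test_that("profiles average z-scored features per alpha and centre at zero", {
  cfg <- tiny_cfg(n_categories = 5L)
  tbl <- standardize_features(extract_feature_table(generate_dataset(cfg)),
                              "zscore", "global")
  prof <- feature_alpha_profiles(tbl)
  expect_identical(prof$alpha, sort(unique(tbl$alpha)))
  # grand mean of each profile, weighted by cell counts, is the z-score mean
  for (f in c("brightness", "contrast", "colorfulness"))
    expect_equal(sum(prof[[f]] * prof$n) / sum(prof$n), 0, tolerance = 1e-9)
  # positive-slope features give non-decreasing profiles
  for (f in c("brightness", "saturation", "colorfulness"))
    expect_true(all(diff(prof[[f]]) >= -1e-9), info = f)
})

test_that("noiseless linear targets are recovered exactly", {
  tbl <- feature_fixture(noise_sd = 0)
  fit <- suppressWarnings(fit_feature_regression(tbl, "aesthetic_score"))
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  b <- setNames(fit$terms$b, fit$terms$name)
  expect_equal(unname(b["brightness"]), 0.6, tolerance = 1e-9)
  expect_equal(unname(b["symmetry"]), 0, tolerance = 1e-9)
})

test_that("coefficient CIs cover the generating values in most replicates", {
  truth <- c(-0.2, 0.6, 0.4, 0.5, 0.4, 0.6, -0.2, 0)
  hits <- 0L; total <- 0L
  for (rep in 1:40) {
    tbl <- feature_fixture(n = 300L, seed = rep + 100L)
    fit <- fit_feature_regression(tbl, "aesthetic_score")
    ci <- confint(fit$fit, level = 0.95)
    inside <- truth >= ci[, 1] & truth <= ci[, 2]
    hits <- hits + sum(inside); total <- total + length(inside)
  }
  expect_gte(hits / total, 0.90)
})

test_that("rank-deficient designs fail with the collinear features named", {
  tbl <- feature_fixture()
  tbl$symmetry <- 2 * tbl$complexity
  expect_error(fit_feature_regression(tbl, "aesthetic_score"),
               "complexity|symmetry")
})

test_that("ridge at lambda zero equals OLS on the training split", {
  tbl <- feature_fixture()
  rr <- fit_ridge(tbl, "aesthetic_score", split_seed = 11,
                  lambda_grid = 0)
  train <- rr$train_index
  x <- as.matrix(tbl[train, names(rr$coefficients)[-1]])
  x <- scale(x, center = TRUE, scale = apply(x, 2, sd))
  d <- data.frame(y = tbl$aesthetic_score[train], x)
  ols <- lm(y ~ ., data = d)
  expect_equal(unname(rr$coefficients[-1]), unname(coef(ols)[-1]),
               tolerance = 1e-8)
  expect_equal(unname(rr$coefficients[1]), unname(coef(ols)[1]),
               tolerance = 1e-8)
})

test_that("a huge penalty shrinks every slope to zero", {
  tbl <- feature_fixture()
  rr <- fit_ridge(tbl, "aesthetic_score", split_seed = 3,
                  lambda_grid = 1e12)
  expect_equal(max(abs(rr$coefficients[-1])), 0, tolerance = 1e-4)
  train_mean <- mean(tbl$aesthetic_score[rr$train_index])
  expect_equal(unname(rr$coefficients[1]), train_mean, tolerance = 1e-4)
})

test_that("the split is seeded, disjoint and exactly 80/20 by row count", {
  tbl <- feature_fixture(n = 401L)
  r1 <- fit_ridge(tbl, "aesthetic_score", split_seed = 7)
  r2 <- fit_ridge(tbl, "aesthetic_score", split_seed = 7)
  expect_identical(r1$train_index, r2$train_index)
  expect_identical(length(r1$train_index), as.integer(floor(0.8 * 401)))
  r3 <- fit_ridge(tbl, "aesthetic_score", split_seed = 8)
  expect_false(identical(r1$train_index, r3$train_index))
  expect_error(fit_ridge(tbl, "aesthetic_score", lambda_grid = -1),
               "configuration error")
})

test_that("cross-validated ridge does not lose to OLS under collinearity", {
  beta <- c(brightness = 0.5, contrast = 0.5, sharpness = 0.5,
            saturation = 0.5, colorfulness = 0.5, complexity = 0.5,
            symmetry = 0.5)
  tbl <- simulate_feature_scores(80L, beta, rho = 0.8, noise_sd = 1.5,
                                 seed = 5L)
  rr <- fit_ridge(tbl, "aesthetic_score", split_seed = 2)
  rr0 <- fit_ridge(tbl, "aesthetic_score", split_seed = 2, lambda_grid = 0)
  expect_lte(rr$test_rmse, rr0$test_rmse + 1e-9)
})

test_that("single-feature r2 never exceeds the full-model r2", {
  tbl <- feature_fixture(seed = 9L)
  for (f in c("brightness", "colorfulness", "symmetry")) {
    vc <- variance_contribution(tbl, f, "aesthetic_score")
    expect_lte(vc$single_r2, vc$full_r2 + 1e-12)
    expect_gte(vc$delta, -1e-12)
  }
  # target generated from one feature alone
  beta1 <- c(brightness = 0, contrast = 0, sharpness = 0, saturation = 0,
             colorfulness = 1, complexity = 0, symmetry = 0)
  tbl1 <- simulate_feature_scores(200L, beta1, noise_sd = 0, seed = 2L)
  vc1 <- suppressWarnings(
    variance_contribution(tbl1, "colorfulness", "aesthetic_score"))
  expect_equal(vc1$single_r2, 1, tolerance = 1e-9)
  expect_equal(vc1$full_r2, 1, tolerance = 1e-9)
  expect_error(variance_contribution(tbl, "glow", "aesthetic_score"),
               "unknown feature")
})

test_that("in-sample r2 is monotone in the predictor set", {
  tbl <- feature_fixture(seed = 12L)
  sets <- list(c("brightness"),
               c("brightness", "contrast"),
               c("brightness", "contrast", "colorfulness"),
               c("brightness", "contrast", "colorfulness", "sharpness"))
  r2s <- vapply(sets, function(s)
    fit_feature_regression(tbl, "aesthetic_score", features = s)$r2,
    numeric(1))
  expect_true(all(diff(r2s) >= -1e-12))
})
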