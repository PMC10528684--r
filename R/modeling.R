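#' Per-alpha mean standardized feature profiles
#'
#' For a z-scored feature table, averages each feature over categories at
#' every alpha level, giving the feature-by-alpha profile curves.
#'
#' @param tbl feature table with `alpha` and the seven feature columns
#'   (z-scored; see [standardize_features()])
#' @param features columns to profile
#' @return data frame with columns `alpha`, one column per feature
#'   (mean z-score), and `n` (categories per level), ordered by alpha
#' @export
feature_alpha_profiles <- function(tbl, features = .FEATURE_NAMES) {
  stopifnot(all(c("alpha", features) %in% names(tbl)))
  a <- sort(unique(tbl$alpha))
  out <- do.call(rbind, lapply(a, function(al) {
    i <- tbl$alpha == al
    row <- as.data.frame(as.list(colMeans(tbl[i, features, drop = FALSE])))
    cbind(data.frame(alpha = al), row, data.frame(n = sum(i)))
  }))
  rownames(out) <- NULL
  out
}

feature_design <- function(tbl, features) {
  x <- as.matrix(tbl[, features, drop = FALSE])
  if (qr(cbind(1, x))$rank < ncol(x) + 1L) {
    # name the offending columns for the error message
    bad <- character()
    for (j in seq_along(features)) {
      if (qr(cbind(1, x[, -j, drop = FALSE]))$rank == qr(cbind(1, x))$rank)
        bad <- c(bad, features[j])
    }
    stop("rank-deficient design; collinear features: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  x
}

#' Multiple linear regression of a target on the image features
#'
#' Ordinary least squares of the aesthetic score (or of alpha) on all
#' seven features, with intercept.  Reports unstandardized weights,
#' standard errors, t and p values, multiple and adjusted R-squared,
#' residual SE, and squared semi-partial correlations per feature.
#'
#' @param tbl feature table with `aesthetic_score`, `alpha` and feature
#'   columns
#' @param target `"aesthetic_score"` (default) or `"alpha"`
#' @param features predictor columns (default all seven)
#' @return a `regression_result` list with elements `terms` (data frame:
#'   `name`, `b`, `se`, `t`, `p`, `sr2`), `r2`, `adj_r2`, `residual_se`,
#'   `dof`, `fstat`, `fit`
#' @export
fit_feature_regression <- function(tbl, target = c("aesthetic_score", "alpha"),
                                   features = .FEATURE_NAMES) {
  target <- match.arg(target)
  stopifnot(all(c(target, features) %in% names(tbl)))
  if (nrow(tbl) < 10L * length(features))
    warning("fewer than 10 rows per predictor; estimates will be unstable",
            call. = FALSE)
  x <- feature_design(tbl, features)
  y <- tbl[[target]]
  d <- data.frame(.y = y, x)
  form <- stats::as.formula(paste(".y ~", paste(features, collapse = " + ")))
  environment(form) <- baseenv()
  fit <- stats::lm(form, data = d)
  sm <- summary(fit)
  co <- sm$coefficients
  r2_full <- sm$r.squared
  sr2 <- c(NA_real_, vapply(features, function(f) {
    rest <- setdiff(features, f)
    rhs <- if (length(rest)) paste(rest, collapse = " + ") else "1"
    f2 <- stats::as.formula(paste(".y ~", rhs))
    environment(f2) <- baseenv()
    r2_full - summary(stats::lm(f2, data = d))$r.squared
  }, numeric(1L)))
  structure(list(
    terms = data.frame(name = rownames(co),
                       b = unname(co[, 1L]), se = unname(co[, 2L]),
                       t = unname(co[, 3L]), p = unname(co[, 4L]),
                       sr2 = unname(sr2), stringsAsFactors = FALSE),
    r2 = r2_full, adj_r2 = sm$adj.r.squared,
    residual_se = sm$sigma, dof = fit$df.residual,
    fstat = unname(sm$fstatistic[1L]),
    target = target, fit = fit), class = "regression_result")
}

ridge_solve <- function(x, y, lambda) {
  # centred closed form; penalty excludes the intercept
  xm <- colMeans(x); ym <- mean(y)
  xc <- sweep(x, 2L, xm)
  yc <- y - ym
  a <- crossprod(xc) + diag(lambda, ncol(x))
  beta <- solve(a, crossprod(xc, yc))
  c(intercept = ym - sum(xm * beta), stats::setNames(drop(beta),
                                                     colnames(x)))
}

ridge_predict <- function(coefs, x) {
  coefs[1L] + drop(x %*% coefs[-1L])
}

#' Ridge regression with an 80-20 train-test split
#'
#' Splits the rows 80/20 (seeded; train size `floor(0.8 n)`), z-scores
#' the predictors using training-set statistics, picks the ridge penalty
#' on a grid by seeded k-fold cross-validation within the training set,
#' and reports train/test R-squared and RMSE.  With `lambda = 0` the
#' coefficients equal the unpenalized least-squares fit on the same
#' split.
#'
#' @inheritParams fit_feature_regression
#' @param split_seed integer seed for the split and the CV folds
#' @param lambda_grid nonnegative penalties (default logarithmic
#'   `1e-4 ... 1e2`, 25 points)
#' @param nfolds cross-validation folds within the training set
#' @return a `ridge_result` list: `lambda_ridge`, `coefficients` (on the
#'   standardized-predictor scale), `train_r2`, `test_r2`, `train_rmse`,
#'   `test_rmse`, `split_seed`, `cv_rmse` (per grid point)
#' @export
fit_ridge <- function(tbl, target = c("aesthetic_score", "alpha"),
                      split_seed = 11L,
                      lambda_grid = 10^seq(-4, 2, length.out = 25L),
                      nfolds = 5L, features = .FEATURE_NAMES) {
  target <- match.arg(target)
  if (!length(lambda_grid) || any(lambda_grid < 0))
    stop("configuration error: lambda_grid must be nonnegative and nonempty",
         call. = FALSE)
  x <- feature_design(tbl, features)
  y <- tbl[[target]]
  n <- nrow(x)
  n_train <- floor(0.8 * n)
  withr::with_seed(as.integer(split_seed), {
    train <- sort(sample.int(n, n_train))
    folds <- sample(rep_len(seq_len(nfolds), n_train))
  })
  test <- setdiff(seq_len(n), train)
  mu <- colMeans(x[train, , drop = FALSE])
  sdv <- apply(x[train, , drop = FALSE], 2L, stats::sd)
  if (any(sdv == 0)) stop("zero-variance feature in the training split",
                          call. = FALSE)
  z <- sweep(sweep(x, 2L, mu), 2L, sdv, "/")
  xtr <- z[train, , drop = FALSE]; ytr <- y[train]
  xte <- z[test, , drop = FALSE]; yte <- y[test]
  cv_rmse <- vapply(lambda_grid, function(l) {
    errs <- vapply(seq_len(nfolds), function(f) {
      i <- folds == f
      cf <- ridge_solve(xtr[!i, , drop = FALSE], ytr[!i], l)
      sqrt(mean((ytr[i] - ridge_predict(cf, xtr[i, , drop = FALSE]))^2))
    }, numeric(1L))
    mean(errs)
  }, numeric(1L))
  lambda <- lambda_grid[which.min(cv_rmse)]
  coefs <- ridge_solve(xtr, ytr, lambda)
  rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))
  r2 <- function(obs, pred) 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  ptr <- ridge_predict(coefs, xtr); pte <- ridge_predict(coefs, xte)
  structure(list(lambda_ridge = lambda, coefficients = coefs,
                 train_r2 = r2(ytr, ptr), test_r2 = r2(yte, pte),
                 train_rmse = rmse(ytr, ptr), test_rmse = rmse(yte, pte),
                 split_seed = as.integer(split_seed),
                 lambda_grid = lambda_grid, cv_rmse = cv_rmse,
                 train_index = train, target = target),
            class = "ridge_result")
}

#' Variance explained by a single feature versus the full model
#'
#' Compares the R-squared of the one-predictor fit with the full
#' seven-feature fit for the chosen target; `delta = full - single` is
#' nonnegative by model nesting.
#'
#' @inheritParams fit_feature_regression
#' @param feature one feature name
#' @return list with `single_r2`, `full_r2`, `delta`
#' @export
variance_contribution <- function(tbl, feature,
                                  target = c("aesthetic_score", "alpha"),
                                  features = .FEATURE_NAMES) {
  target <- match.arg(target)
  if (!feature %in% features)
    stop("unknown feature name: ", feature, call. = FALSE)
  single <- fit_feature_regression(tbl, target, features = feature)
  full <- fit_feature_regression(tbl, target, features = features)
  list(single_r2 = single$r2, full_r2 = full$r2,
       delta = full$r2 - single$r2)
}
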