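poly_terms <- function(degree) {
  c("abs_alpha", "I(abs_alpha^2)", "I(abs_alpha^3)")[seq_len(degree)]
}

weighted_tss <- function(y, w) sum(w * (y - sum(w * y) / sum(w))^2)

fit_poly_lm <- function(folded, degree, weighted) {
  rhs <- c(poly_terms(degree), "positive")
  folded$.w <- if (weighted && "n_trials" %in% names(folded))
    folded$n_trials else rep(1, nrow(folded))
  form <- stats::as.formula(paste("agreement ~", paste(rhs, collapse = " + ")))
  environment(form) <- baseenv()
  stats::lm(form, data = folded, weights = .w)
}

# semi-partial r^2 per term: drop in R^2 when that term is removed
poly_sr2 <- function(folded, degree, weighted) {
  rhs <- c(poly_terms(degree), "positive")
  folded$.w <- if (weighted && "n_trials" %in% names(folded))
    folded$n_trials else rep(1, nrow(folded))
  if (weighted_tss(folded$agreement, folded$.w) < 1e-20)
    return(stats::setNames(rep(0, length(rhs)), rhs))
  r2_of <- function(terms) {
    form <- stats::as.formula(paste("agreement ~",
                                    paste(terms, collapse = " + ")))
    environment(form) <- baseenv()
    summary(stats::lm(form, data = folded, weights = .w))$r.squared
  }
  r2_full <- r2_of(rhs)
  stats::setNames(vapply(rhs, function(tm) r2_full - r2_of(setdiff(rhs, tm)),
                         numeric(1L)), rhs)
}

poly_result <- function(folded, degree, weighted, n_boot, boot_seed) {
  fit <- fit_poly_lm(folded, degree, weighted)
  sm <- summary(fit)
  # a constant response has (numerically) zero total SS; report r2 = 0
  w <- if (weighted && "n_trials" %in% names(folded)) folded$n_trials
       else rep(1, nrow(folded))
  if (is.nan(sm$r.squared) || weighted_tss(folded$agreement, w) < 1e-20)
    sm$r.squared <- sm$adj.r.squared <- 0
  co <- sm$coefficients
  ci <- stats::confint(fit, level = 0.95)
  terms <- rownames(co)
  sr2 <- c(NA_real_, poly_sr2(folded, degree, weighted))
  sr2_ci <- matrix(NA_real_, length(terms), 2L)
  if (n_boot > 0L) {
    bs <- withr::with_seed(as.integer(boot_seed), {
      t(vapply(seq_len(n_boot), function(b) {
        i <- sample.int(nrow(folded), replace = TRUE)
        tryCatch(poly_sr2(folded[i, , drop = FALSE], degree, weighted),
                 error = function(e) rep(NA_real_, length(terms) - 1L))
      }, numeric(length(terms) - 1L)))
    })
    sr2_ci[-1L, ] <- t(apply(bs, 2L, stats::quantile,
                             probs = c(0.025, 0.975), na.rm = TRUE))
  }
  structure(list(
    terms = data.frame(name = terms,
                       b = unname(co[, 1L]),
                       b_ci_lower = unname(ci[, 1L]),
                       b_ci_upper = unname(ci[, 2L]),
                       sr2 = unname(sr2),
                       sr2_ci_lower = sr2_ci[, 1L],
                       sr2_ci_upper = sr2_ci[, 2L],
                       p = unname(co[, 4L]),
                       stringsAsFactors = FALSE),
    r2 = sm$r.squared,
    adj_r2 = sm$adj.r.squared,
    residual_se = sm$sigma,
    dof = fit$df.residual,
    weighted = weighted,
    fit = fit), class = "regression_result")
}

#' Polynomial regressions of folded agreement on |alpha|
#'
#' Fits agreement on `{|alpha|, |alpha|^2, positive}` (quadratic) and on
#' `{|alpha|, |alpha|^2, |alpha|^3, positive}` (cubic) by least squares,
#' where `positive` is a dummy for the sign of alpha.  Rows are weighted
#' by trial count by default (configurable).  Reports unstandardized
#' weights with 95% CIs, squared semi-partial correlations (the R-squared
#' drop when the term is removed) with case-bootstrap CIs, the model
#' R-squared, and a nested-model F-test for adding the cubic term.
#'
#' @param folded data frame with columns `abs_alpha`, `positive` (0/1),
#'   `agreement`, and optionally `n_trials` (see [aggregate_agreement()])
#' @param weighted weight rows by `n_trials` (default `TRUE`)
#' @param n_boot case-bootstrap resamples for the sr2 CIs (0 skips)
#' @param boot_seed integer seed
#' @return list with `quadratic` and `cubic` regression results and
#'   `delta_r2_test` (`delta_r2`, `f`, `p`)
#' @export
fit_polynomial_agreement <- function(folded, weighted = TRUE, n_boot = 0L,
                                     boot_seed = 1L) {
  stopifnot(all(c("abs_alpha", "positive", "agreement") %in% names(folded)))
  if (nrow(folded) < 6L)
    stop("need at least 6 folded rows", call. = FALSE)
  if (length(unique(folded$positive)) < 2L)
    stop("both alpha signs must be represented", call. = FALSE)
  if (length(unique(folded$abs_alpha)) < 4L)
    stop("collinear design: need at least 4 distinct |alpha| values",
         call. = FALSE)
  quad <- poly_result(folded, 2L, weighted, n_boot, boot_seed)
  cub <- poly_result(folded, 3L, weighted, n_boot, boot_seed + 1L)
  an <- stats::anova(quad$fit, cub$fit)
  list(quadratic = quad, cubic = cub,
       delta_r2_test = list(delta_r2 = cub$r2 - quad$r2,
                            f = an$F[2L], p = an$`Pr(>F)`[2L]))
}

#' Two-way ANOVA for stimulus confounds
#'
#' Tests whether per-cell agreement depends on the broad content group of
#' the category or on the screen position of the nonneutral image.
#' Agreement is aggregated per (category, position) cell and analysed
#' with a two-way ANOVA without interaction.
#'
#' @param trials a trial table
#' @param broad_category character vector mapping each trial to a broad
#'   group label (same length as `trials` has rows)
#' @return data frame with one row per term (plus residuals): `term`,
#'   `df`, `sum_sq`, `f`, `p`
#' @export
anova_confounds <- function(trials, broad_category) {
  stopifnot(nrow(trials) > 0L, length(broad_category) == nrow(trials))
  d <- data.frame(
    agreement = as.numeric(agreement_flag(trials$alpha,
                                          trials$chose_nonneutral)),
    group = broad_category,
    position = trials$nonneutral_position,
    category = trials$category_id,
    stringsAsFactors = FALSE)
  cells <- stats::aggregate(agreement ~ category + group + position, d, mean)
  keep <- c("group", "position")
  for (f in c("group", "position")) {
    if (length(unique(cells[[f]])) < 2L) {
      warning(sprintf("factor '%s' has fewer than 2 observed levels; dropped",
                      f), call. = FALSE)
      keep <- setdiff(keep, f)
    }
  }
  if (!length(keep)) stop("no factor with 2+ levels", call. = FALSE)
  form <- stats::as.formula(paste("agreement ~", paste(keep, collapse = " + ")))
  environment(form) <- baseenv()
  av <- summary(stats::aov(form, data = cells))[[1L]]
  data.frame(term = trimws(rownames(av)),
             df = av$Df, sum_sq = av$`Sum Sq`,
             f = av$`F value`, p = av$`Pr(>F)`,
             stringsAsFactors = FALSE, row.names = NULL)
}
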