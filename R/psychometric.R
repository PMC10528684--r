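psy_fun <- function(alpha, mu, s, gamma, lambda) {
  gamma + (1 - gamma - lambda) * stats::pnorm((alpha - mu) / s)
}

psy_counts <- function(data) {
  if (all(c("alpha", "n", "k") %in% names(data))) {
    data.frame(alpha = data$alpha, n = data$n, k = data$k)
  } else if (all(c("alpha", "chose_nonneutral") %in% names(data))) {
    a <- sort(unique(data$alpha))
    do.call(rbind, lapply(a, function(al) {
      i <- data$alpha == al
      data.frame(alpha = al, n = sum(i), k = sum(data$chose_nonneutral[i]))
    }))
  } else {
    stop("data must have columns (alpha, n, k) or (alpha, chose_nonneutral)",
         call. = FALSE)
  }
}

psy_negloglik <- function(par, cnt) {
  p <- psy_fun(cnt$alpha, par[1L], exp(par[2L]), par[3L], par[4L])
  p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  -sum(cnt$k * log(p) + (cnt$n - cnt$k) * log(1 - p))
}

psy_mle <- function(cnt) {
  rng <- range(cnt$alpha)
  starts <- list(c(0, log(diff(rng) / 6), 0.05, 0.05),
                 c(mean(rng), log(diff(rng) / 3), 0.02, 0.02),
                 c(0, log(diff(rng) / 12), 0.15, 0.15))
  lower <- c(rng[1L] - diff(rng), log(1e-5), 0, 0)
  upper <- c(rng[2L] + diff(rng), log(10 * diff(rng)), 0.5, 0.5)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, psy_negloglik, cnt = cnt, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500L)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best))
    stop("psychometric fit failed to converge from every start", call. = FALSE)
  best
}

#' Fit a psychometric function with free guess and lapse rates
#'
#' Maximizes the binomial log-likelihood of the nonneutral-choice counts
#' under `psi(alpha) = gamma + (1 - gamma - lambda) * Phi((alpha - mu) /
#' s)`, with `gamma` and `lambda` bounded in `[0, 0.5]`.  Confidence
#' intervals are obtained by parametric bootstrap: counts are resampled
#' from the fitted curve and refitted, and percentile intervals are
#' reported at `ci_level`.
#'
#' @param data either a trial table (columns `alpha`,
#'   `chose_nonneutral`) or an aggregated table (columns `alpha`, `n`,
#'   `k`)
#' @param n_boot bootstrap resamples for the CIs (0 skips CIs)
#' @param ci_level confidence level (default 0.99)
#' @param boot_seed integer seed for the bootstrap
#' @return a `psychometric_fit` list with `threshold_mu`, `slope_s`,
#'   `guess_gamma`, `lapse_lambda`, a `ci` matrix (if bootstrapped),
#'   `loglik`, `n_trials`, `converged`
#' @export
fit_psychometric <- function(data, n_boot = 999L, ci_level = 0.99,
                             boot_seed = 1L) {
  cnt <- psy_counts(data)
  if (nrow(cnt) < 4L)
    stop("need at least 4 distinct alpha levels", call. = FALSE)
  if (all(cnt$alpha >= 0) || all(cnt$alpha <= 0))
    stop("alpha levels must span both signs", call. = FALSE)
  best <- psy_mle(cnt)
  est <- c(threshold_mu = best$par[1L], slope_s = exp(best$par[2L]),
           guess_gamma = best$par[3L], lapse_lambda = best$par[4L])
  ci <- NULL
  if (n_boot > 0L) {
    boot <- withr::with_seed(as.integer(boot_seed), {
      p_hat <- psy_fun(cnt$alpha, est[1L], est[2L], est[3L], est[4L])
      t(vapply(seq_len(n_boot), function(b) {
        cb <- cnt
        cb$k <- stats::rbinom(nrow(cnt), cnt$n, p_hat)
        fb <- psy_mle(cb)
        c(fb$par[1L], exp(fb$par[2L]), fb$par[3L], fb$par[4L])
      }, numeric(4L)))
    })
    qs <- c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2)
    ci <- t(apply(boot, 2L, stats::quantile, probs = qs))
    dimnames(ci) <- list(names(est), c("lower", "upper"))
  }
  structure(list(threshold_mu = unname(est[1L]), slope_s = unname(est[2L]),
                 guess_gamma = unname(est[3L]),
                 lapse_lambda = unname(est[4L]),
                 ci = ci, ci_level = if (is.null(ci)) NULL else ci_level,
                 loglik = -best$value, n_trials = sum(cnt$n),
                 converged = best$convergence == 0L),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat("Psychometric fit (cumulative Gaussian, free guess/lapse)\n")
  cat(sprintf("  PSE (mu)     %8.4f\n", x$threshold_mu))
  cat(sprintf("  slope (s)    %8.4f\n", x$slope_s))
  cat(sprintf("  guess rate   %8.4f\n", x$guess_gamma))
  cat(sprintf("  lapse rate   %8.4f\n", x$lapse_lambda))
  if (!is.null(x$ci)) {
    cat(sprintf("  %.0f%% bootstrap CIs:\n", 100 * x$ci_level))
    for (nm in rownames(x$ci))
      cat(sprintf("    %-12s [%.4f, %.4f]\n", nm, x$ci[nm, 1L], x$ci[nm, 2L]))
  }
  cat(sprintf("  log-likelihood %.2f on %d trials\n", x$loglik, x$n_trials))
  invisible(x)
}
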