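#' Simulated 2AFC observer
#'
#' An observer whose probability of choosing the nonneutral image follows
#' a cumulative-Gaussian psychometric function with guess rate `gamma`
#' (lower asymptote) and lapse rate `lambda` (upper asymptote `1 -
#' lambda`).  Defaults correspond to a typical aesthetic-preference
#' observer: point of subjective equality at alpha = 0, guess rate 0.07,
#' lapse rate 0.17.
#'
#' @param threshold_mu point of subjective equality on the alpha axis
#' @param slope_s positive spread of the inner cumulative Gaussian
#' @param guess_gamma lower asymptote, in `[0, 0.5)`
#' @param lapse_lambda one minus the upper asymptote, in `[0, 0.5)`
#' @return an `observer_model` list
#' @export
observer_model <- function(threshold_mu = 0, slope_s = 0.05,
                           guess_gamma = 0.07, lapse_lambda = 0.17) {
  stopifnot(slope_s > 0,
            guess_gamma >= 0, guess_gamma < 0.5,
            lapse_lambda >= 0, lapse_lambda < 0.5,
            guess_gamma + lapse_lambda < 1)
  structure(list(threshold_mu = threshold_mu, slope_s = slope_s,
                 guess_gamma = guess_gamma, lapse_lambda = lapse_lambda),
            class = "observer_model")
}

#' Psychometric choice probability
#'
#' `psi(alpha) = gamma + (1 - gamma - lambda) * Phi((alpha - mu) / s)`
#' with `Phi` the cumulative unit Gaussian; strictly increasing in alpha
#' and bounded in `[gamma, 1 - lambda]`.
#'
#' @param model an [observer_model()]
#' @param alpha numeric vector of alpha values
#' @return choice probabilities, same length as `alpha`
#' @export
#' @examples
#' observer_prob(observer_model(0, 0.05, 0, 0), 0)  # 0.5
observer_prob <- function(model, alpha) {
  model$guess_gamma + (1 - model$guess_gamma - model$lapse_lambda) *
    stats::pnorm((alpha - model$threshold_mu) / model$slope_s)
}

#' Simulate binomial choice counts on a fixed alpha grid
#'
#' Draws `n_per_level` Bernoulli choices at every alpha level from one
#' observer.  The aggregated form used for psychometric parameter
#' recovery.
#'
#' @param model an [observer_model()]
#' @param alpha_levels numeric grid
#' @param n_per_level trials per level
#' @param seed integer seed
#' @return data frame with columns `alpha`, `n`, `k` (nonneutral choices)
#' @export
simulate_choices <- function(model, alpha_levels, n_per_level, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    k <- stats::rbinom(length(alpha_levels), n_per_level,
                       observer_prob(model, alpha_levels))
    data.frame(alpha = alpha_levels, n = n_per_level, k = k)
  })
}

rt_lognormal <- function(n, median_ms, sdlog) {
  stats::rlnorm(n, meanlog = log(median_ms), sdlog = sdlog)
}

trial_columns <- c("participant_id", "trial_index", "category_id", "alpha",
                   "nonneutral_position", "chosen_position",
                   "chose_nonneutral", "rt_ms")

make_trials <- function(participant_id, cat_ids, alpha, nonneutral_position,
                        chose_nonneutral, rt_ms) {
  data.frame(participant_id = participant_id,
             trial_index = seq_along(cat_ids),
             category_id = cat_ids,
             alpha = alpha,
             nonneutral_position = nonneutral_position,
             chosen_position = ifelse(chose_nonneutral, nonneutral_position,
                                      ifelse(nonneutral_position == "left",
                                             "right", "left")),
             chose_nonneutral = chose_nonneutral,
             rt_ms = rt_ms,
             stringsAsFactors = FALSE)
}

# Planted rule violators.  Each is engineered to break exactly one
# cleaning rule: positions/choices are constructed deterministically so
# the other three rules cannot fire.  The trick throughout: fix the
# desired chosen_position pattern (alternating, or all-left for the bias
# violator) and derive nonneutral_position from it, which pins the side
# proportion exactly.
planted_participant <- function(kind, participant_id, cat_pool, alphas,
                                n_trials, cfg) {
  cats <- cat_pool[seq_len(n_trials)]
  alpha <- rep_len(alphas, n_trials)
  rt <- rt_lognormal(n_trials, cfg$rt_median_ms, cfg$rt_sdlog)
  alt <- rep_len(c("left", "right"), n_trials)
  if (kind == "bias") {
    # every choice lands left; agreement irrelevant (bias rule is first)
    chose_nn <- rep_len(c(TRUE, FALSE), n_trials)
    chosen <- rep("left", n_trials)
  } else if (kind == "chance") {
    # per alpha level, agree on exactly floor(n/2) trials -> max
    # per-level agreement <= 0.5
    agree <- logical(n_trials)
    for (a in unique(alpha)) {
      i <- which(alpha == a)
      agree[i] <- seq_along(i) %% 2L == 0L
    }
    chose_nn <- ifelse(alpha > 0, agree, !agree)
    chosen <- alt
  } else if (kind == "fast_rt") {
    chose_nn <- alpha > 0          # perfect agreement
    chosen <- alt
    rt <- rt_lognormal(n_trials, 300, 0.2)
  } else if (kind == "few_trials") {
    chose_nn <- alpha > 0
    chosen <- alt
  } else stop("unknown planted violation: ", kind, call. = FALSE)
  nn_pos <- ifelse(chose_nn, chosen,
                   ifelse(chosen == "left", "right", "left"))
  make_trials(participant_id, cats, alpha, nn_pos, chose_nn, rt)
}

#' Simulate a 2AFC preference experiment
#'
#' Each participant (one per observer model) completes
#' `trials_per_participant` trials.  Per trial a category is drawn without
#' replacement (no category repeats within a participant), the nonneutral
#' image's alpha is drawn approximately uniformly from the nonzero levels,
#' its screen position is an independent fair coin, and the choice is a
#' Bernoulli draw with probability [observer_prob()].  Response times are
#' log-normal with configurable median.
#'
#' Planted violators are appended as extra participants, each engineered
#' to break exactly one cleaning rule: `bias` (all choices on one side),
#' `chance` (per-level agreement pinned at or below 0.5), `fast_rt`
#' (median RT near 300 ms), `few_trials` (40 trials).
#'
#' @param models list of [observer_model()] objects
#' @param cfg a [generator_config()]
#' @param trials_per_participant at most `cfg$n_categories`
#' @param planted_violations named integer vector with any of the names
#'   `bias`, `chance`, `fast_rt`, `few_trials`
#' @param rng_seed integer seed
#' @return data frame of trials with columns `participant_id`,
#'   `trial_index`, `category_id`, `alpha`, `nonneutral_position`,
#'   `chosen_position`, `chose_nonneutral`, `rt_ms`
#' @export
simulate_experiment <- function(models, cfg, trials_per_participant,
                                planted_violations = integer(),
                                rng_seed = cfg$rng_seed) {
  if (trials_per_participant > cfg$n_categories)
    stop("design error: trials_per_participant exceeds the number of ",
         "categories, so the category no-repeat rule is unsatisfiable",
         call. = FALSE)
  if (length(planted_violations)) {
    bad <- setdiff(names(planted_violations),
                   c("bias", "chance", "fast_rt", "few_trials"))
    if (length(bad))
      stop("unknown planted violation(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  ids <- category_ids(cfg$n_categories)
  alphas <- setdiff(cfg$alpha_levels, 0)
  withr::with_seed(as.integer(rng_seed), {
    tabs <- list()
    for (p in seq_along(models)) {
      m <- models[[p]]
      cats <- sample(ids, trials_per_participant)
      alpha <- sample(alphas, trials_per_participant, replace = TRUE)
      nn_pos <- sample(c("left", "right"), trials_per_participant,
                       replace = TRUE)
      chose_nn <- stats::runif(trials_per_participant) <
        observer_prob(m, alpha)
      rt <- rt_lognormal(trials_per_participant, cfg$rt_median_ms,
                         cfg$rt_sdlog)
      tabs[[length(tabs) + 1L]] <-
        make_trials(sprintf("obs%03d", p), cats, alpha, nn_pos, chose_nn, rt)
    }
    for (kind in names(planted_violations)) {
      for (j in seq_len(planted_violations[[kind]])) {
        n_tr <- if (kind == "few_trials") min(40L, trials_per_participant)
                else trials_per_participant
        tabs[[length(tabs) + 1L]] <- planted_participant(
          kind, sprintf("planted_%s_%02d", kind, j),
          sample(ids, n_tr), sample(rep_len(alphas, n_tr)), n_tr, cfg)
      }
    }
    if (!length(tabs)) {
      empty <- make_trials(character(), character(), numeric(), character(),
                           logical(), numeric())
      return(empty)
    }
    do.call(rbind, tabs)
  })
}
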