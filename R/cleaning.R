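#' Participant cleaning thresholds
#'
#' Thresholds for the four exclusion rules applied to 2AFC trial tables:
#' side bias (deviation of the left-choice proportion from 0.5 greater
#' than `max_side_bias`), near-chance performance (the participant's
#' maximum per-alpha agreement below `min_agreement`), implausibly fast
#' responding (median RT below `min_median_rt_ms`), and too few trials.
#'
#' @param max_side_bias proportion deviation from 0.5 (default 0.25, i.e.
#'   removal when the side proportion falls outside `[0.25, 0.75]`)
#' @param min_agreement proportion (default 0.55)
#' @param min_median_rt_ms milliseconds (default 500)
#' @param min_trials integer (default 50)
#' @return a `cleaning_thresholds` list
#' @export
cleaning_thresholds <- function(max_side_bias = 0.25, min_agreement = 0.55,
                                min_median_rt_ms = 500, min_trials = 50L) {
  stopifnot(max_side_bias >= 0, max_side_bias <= 0.5,
            min_agreement >= 0, min_agreement <= 1,
            min_median_rt_ms >= 0, min_trials >= 0)
  structure(list(max_side_bias = max_side_bias,
                 min_agreement = min_agreement,
                 min_median_rt_ms = min_median_rt_ms,
                 min_trials = as.integer(min_trials)),
            class = "cleaning_thresholds")
}

agreement_flag <- function(alpha, chose_nonneutral) {
  ifelse(alpha > 0, chose_nonneutral, !chose_nonneutral)
}

#' Remove participants violating the cleaning rules
#'
#' A participant is removed iff any rule fires; the report attributes each
#' removal to the first violated rule in the order side bias, near-chance
#' agreement, fast RT, too few trials.  Surviving trials are returned
#' unchanged.  Cleaning depends only on per-participant summaries, so it
#' is invariant to row order.
#'
#' @param trials a trial table as produced by [simulate_experiment()]
#' @param thr a [cleaning_thresholds()] object
#' @return list with `trials` (kept rows) and `report`, a list holding
#'   `kept` (ids), `removed` (named character: id -> first violated rule)
#'   and `counts_per_rule`
#' @export
clean_participants <- function(trials, thr = cleaning_thresholds()) {
  if (!nrow(trials)) stop("empty trial table", call. = FALSE)
  rules <- c("bias", "chance", "fast_rt", "few_trials")
  ids <- sort(unique(trials$participant_id))
  first_rule <- vapply(ids, function(id) {
    t1 <- trials[trials$participant_id == id, ]
    side <- mean(t1$chosen_position == "left")
    agree <- agreement_flag(t1$alpha, t1$chose_nonneutral)
    max_agree <- max(tapply(agree, t1$alpha, mean))
    viol <- c(bias = abs(side - 0.5) > thr$max_side_bias,
              chance = max_agree < thr$min_agreement,
              fast_rt = stats::median(t1$rt_ms) < thr$min_median_rt_ms,
              few_trials = nrow(t1) < thr$min_trials)
    if (any(viol)) rules[which(viol)[1L]] else NA_character_
  }, character(1L))
  removed <- first_rule[!is.na(first_rule)]
  kept <- ids[is.na(first_rule)]
  counts <- table(factor(removed, levels = rules))
  list(trials = trials[trials$participant_id %in% kept, , drop = FALSE],
       report = list(kept = kept,
                     removed = removed,
                     counts_per_rule = stats::setNames(as.integer(counts),
                                                       rules)))
}

#' Aggregate choices and agreement per alpha level
#'
#' Produces the two standard views of a cleaned trial table: the
#' psychometric view (per alpha, proportion of trials on which the
#' nonneutral image was chosen) and the folded agreement view (per
#' `|alpha|` and sign, the proportion of trials agreeing with the
#' generator: choosing the nonneutral image when alpha is positive, the
#' neutral one when negative).
#'
#' @param trials a trial table
#' @return list with data frames `psychometric` (`alpha`, `n_trials`,
#'   `prop_chose_nonneutral`) and `folded` (`abs_alpha`, `positive`,
#'   `n_trials`, `agreement`)
#' @export
aggregate_agreement <- function(trials) {
  if (!nrow(trials)) stop("empty trial table", call. = FALSE)
  a <- sort(unique(trials$alpha))
  psy <- do.call(rbind, lapply(a, function(al) {
    t1 <- trials[trials$alpha == al, ]
    data.frame(alpha = al, n_trials = nrow(t1),
               prop_chose_nonneutral = mean(t1$chose_nonneutral))
  }))
  agree <- agreement_flag(trials$alpha, trials$chose_nonneutral)
  key <- paste(abs(trials$alpha), trials$alpha > 0)
  folded <- do.call(rbind, lapply(unique(key), function(k) {
    i <- key == k
    data.frame(abs_alpha = abs(trials$alpha[i][1L]),
               positive = as.integer(trials$alpha[i][1L] > 0),
               n_trials = sum(i), agreement = mean(agree[i]))
  }))
  folded <- folded[order(folded$abs_alpha, folded$positive), ]
  rownames(folded) <- NULL
  list(psychometric = psy, folded = folded)
}
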