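# Simulated Wisconsin Card Sorting Test.
#
# Four decks differ along three categories (color, shape, number); deck d
# carries the d-th attribute of every category. Each trial a stimulus card
# is drawn, the agent picks a deck, and feedback reports whether the pick
# matches the stimulus on the active sorting rule. The rule changes after
# 10 consecutive correct matches (a completed category), always to a
# different rule; the test ends after nine completed categories or when
# 128 cards have been drawn.

wcst_rules <- c("color", "shape", "number")

#' Simulate a WCST session with a parameterized agent
#'
#' The agent chooses, in order of precedence: a random deck with probability
#' `distraction_rate` (a lapse); the deck prescribed by the previous rule
#' with probability `perseveration_rate` once at least one rule shift has
#' occurred; otherwise the deck prescribed by the active rule with
#' probability `skill`, falling back to a uniformly random incorrect deck.
#' `skill = 1` with zero rates is the oracle agent: 9 categories in exactly
#' 90 trials with no errors.
#'
#' @param skill Probability in \[0, 1\] of sorting by the active rule on a
#'   non-lapse trial.
#' @param perseveration_rate Probability in \[0, 1\] of answering by the
#'   pre-shift rule.
#' @param distraction_rate Probability in \[0, 1\] of a random lapse.
#' @param seed RNG seed.
#' @param max_trials Card limit (128 in the standard test).
#' @param n_categories Categories required to finish (9 in the standard
#'   test).
#' @return A trial-log data.frame with columns `trial`, `rule`, `choice`,
#'   `matched_categories` (pipe-separated), `feedback`.
#' @export
simulate_wcst_agent <- function(skill, perseveration_rate = 0,
                                distraction_rate = 0, seed = 1L,
                                max_trials = 128L, n_categories = 9L) {
  stopifnot_scalar(skill, "skill", 0, 1)
  stopifnot_scalar(perseveration_rate, "perseveration_rate", 0, 1)
  stopifnot_scalar(distraction_rate, "distraction_rate", 0, 1)
  with_seed(seed, {
    rule <- sample(wcst_rules, 1)
    prev_rule <- NA_character_
    streak <- 0L
    completed <- 0L
    rows <- vector("list", max_trials)
    t <- 0L
    while (t < max_trials && completed < n_categories) {
      t <- t + 1L
      card <- c(color = sample.int(4L, 1L), shape = sample.int(4L, 1L),
                number = sample.int(4L, 1L))
      correct_deck <- unname(card[rule])
      u <- stats::runif(1)
      choice <- if (u < distraction_rate) {
        sample.int(4L, 1L)
      } else if (!is.na(prev_rule) &&
                 u < distraction_rate + perseveration_rate) {
        unname(card[prev_rule])
      } else if (stats::runif(1) < skill) {
        correct_deck
      } else {
        sample(setdiff(1:4, correct_deck), 1L)
      }
      matched <- wcst_rules[card[wcst_rules] == choice]
      correct <- rule %in% matched
      rows[[t]] <- data.frame(
        trial = t, rule = rule, choice = choice,
        matched_categories = paste(matched, collapse = "|"),
        feedback = if (correct) "correct" else "incorrect",
        stringsAsFactors = FALSE)
      if (correct) {
        streak <- streak + 1L
        if (streak == 10L) {
          completed <- completed + 1L
          if (completed < n_categories) {
            prev_rule <- rule
            rule <- sample(setdiff(wcst_rules, rule), 1L)
            streak <- 0L
          }
        }
      } else {
        streak <- 0L
      }
    }
    do.call(rbind, rows[seq_len(t)])
  })
}

#' Write / read a WCST trial log as CSV
#'
#' @param log Trial-log data.frame (see [simulate_wcst_agent()]).
#' @param path File path.
#' @return `read_trial_log` returns the trial-log data.frame.
#' @export
write_trial_log <- function(log, path) {
  utils::write.csv(log, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  log <- utils::read.csv(path, stringsAsFactors = FALSE)
  log$matched_categories[is.na(log$matched_categories)] <- ""
  log
}
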