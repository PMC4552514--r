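# WCST performance scoring, standardization, pooling and clustering.

validate_trial_log <- function(log, max_trials = 128L, n_categories = 9L) {
  need <- c("trial", "rule", "choice", "matched_categories", "feedback")
  missing <- setdiff(need, names(log))
  if (length(missing)) {
    stop("trial log lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(log)
  if (n < 1L) stop("empty trial log", call. = FALSE)
  if (n > max_trials) {
    stop(sprintf("trial log exceeds the %d-card limit", max_trials),
         call. = FALSE)
  }
  streak <- 0L
  completed_at_shift <- FALSE
  for (i in seq_len(n)) {
    if (i > 1L && log$rule[i] != log$rule[i - 1L]) {
      # a rule may only change right after a completed category, where the
      # streak has just been reset to zero by the 10th correct answer
      if (!completed_at_shift) {
        stop(sprintf("invalid trial log: rule change at trial %d without 10 consecutive correct",
                     log$trial[i]), call. = FALSE)
      }
    }
    completed_at_shift <- FALSE
    if (log$feedback[i] == "correct") {
      streak <- streak + 1L
      if (streak == 10L) {
        completed_at_shift <- TRUE
        streak <- 0L
      }
    } else {
      streak <- 0L
    }
  }
  invisible(TRUE)
}

#' Score a WCST trial log
#'
#' Derives the three performance measures from a trial log: completed
#' categories (runs of 10 consecutive correct matches), perseverative
#' errors (incorrect responses whose chosen deck matches the rule that was
#' active before the most recent rule change), and nonperseverative errors
#' (all other incorrect responses), the latter sub-classified as efficient
#' (committed while searching for the new rule, i.e. before the first
#' correct match under it) or distraction (committed after the current rule
#' had already been demonstrated). A response that is both perseverative
#' and early counts as perseverative.
#'
#' @param log Trial-log data.frame with columns `trial`, `rule`, `choice`,
#'   `matched_categories` (pipe-separated), `feedback`.
#' @param validate Check the task-mechanics invariants first?
#' @return List with `completed_categories`, `perseverative_errors`,
#'   `nonperseverative_errors`, `efficient_errors`, `distraction_errors`,
#'   `total_errors`, `n_trials`.
#' @export
score_trial_log <- function(log, validate = TRUE) {
  if (validate) validate_trial_log(log)
  n <- nrow(log)
  matched <- strsplit(ifelse(is.na(log$matched_categories), "",
                             log$matched_categories), "|", fixed = TRUE)
  completed <- 0L
  persev <- 0L
  efficient <- 0L
  distraction <- 0L
  streak <- 0L
  prev_rule <- NA_character_
  acquired <- FALSE   # current rule demonstrated since the last shift?
  for (i in seq_len(n)) {
    if (i > 1L && log$rule[i] != log$rule[i - 1L]) {
      prev_rule <- log$rule[i - 1L]
      acquired <- FALSE
    }
    if (log$feedback[i] == "correct") {
      acquired <- TRUE
      streak <- streak + 1L
      if (streak == 10L) {
        completed <- completed + 1L
        streak <- 0L
      }
    } else {
      streak <- 0L
      if (!is.na(prev_rule) && prev_rule %in% matched[[i]]) {
        persev <- persev + 1L
      } else if (acquired) {
        distraction <- distraction + 1L
      } else {
        efficient <- efficient + 1L
      }
    }
  }
  list(completed_categories = completed,
       perseverative_errors = persev,
       nonperseverative_errors = efficient + distraction,
       efficient_errors = efficient,
       distraction_errors = distraction,
       total_errors = persev + efficient + distraction,
       n_trials = n)
}

#' Standardize a performance measure across a cohort
#'
#' z = (V - mean(V)) / SD(V) with the cohort sample standard deviation
#' (n - 1 denominator).
#'
#' @param values Numeric vector, one raw value per subject.
#' @return Numeric vector of z-scores (cohort mean 0, SD 1).
#' @export
standardize <- function(values) {
  if (length(values) < 2L) {
    stop("standardization needs a cohort of at least 2 subjects",
         call. = FALSE)
  }
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    stop("degenerate cohort: zero standard deviation", call. = FALSE)
  }
  (values - mean(values)) / s
}

#' Pool standardized WCST measures into a performance z-score
#'
#' Weighted average of the three standardized measures, normalized by the
#' sum of absolute weights. Completed categories carry a positive weight and
#' both error counts carry negative weights, so larger pooled z means
#' better performance. The result is invariant to positive rescaling of the
#' weight vector.
#'
#' @param z_categories,z_persev,z_nonpersev Standardized measures.
#' @param weights Numeric length-3 weights `(categories, perseverative,
#'   nonperseverative)`; default `c(1, -1, -1)`.
#' @return Pooled performance z-score(s).
#' @export
pool_zscore <- function(z_categories, z_persev, z_nonpersev,
                        weights = c(1, -1, -1)) {
  if (length(weights) != 3L || !all(is.finite(weights))) {
    stop("`weights` must be 3 finite numbers", call. = FALSE)
  }
  if (weights[1] < 0 || weights[2] > 0 || weights[3] > 0) {
    stop("category weight must be >= 0 and error weights <= 0",
         call. = FALSE)
  }
  denom <- sum(abs(weights))
  if (denom == 0) stop("all-zero weights", call. = FALSE)
  (weights[1] * z_categories + weights[2] * z_persev +
     weights[3] * z_nonpersev) / denom
}

#' Score a cohort of WCST trial logs
#'
#' Convenience wrapper: scores each log, standardizes the three measures
#' across the cohort and pools them into the performance z-score.
#'
#' @param logs List of trial-log data.frames.
#' @param weights Pooling weights, see [pool_zscore()].
#' @return data.frame with raw counts, per-measure z-scores and `z_score`.
#' @export
score_cohort <- function(logs, weights = c(1, -1, -1)) {
  sc <- lapply(logs, score_trial_log)
  out <- data.frame(
    completed_categories = vapply(sc, `[[`, 0L, "completed_categories"),
    perseverative_errors = vapply(sc, `[[`, 0L, "perseverative_errors"),
    nonperseverative_errors = vapply(sc, `[[`, 0L, "nonperseverative_errors"))
  out$z_categories <- standardize(out$completed_categories)
  out$z_persev <- standardize(out$perseverative_errors)
  out$z_nonpersev <- standardize(out$nonperseverative_errors)
  out$z_score <- pool_zscore(out$z_categories, out$z_persev, out$z_nonpersev,
                             weights)
  out
}

#' Cluster subjects into performance levels
#'
#' One-dimensional K-means (k = 3 by default, best of `n_init` random
#' starts) on the pooled performance z-scores. Clusters are relabelled by
#' descending mean as good / medium / poor.
#'
#' @param z_scores Numeric vector of pooled z-scores.
#' @param k Number of performance levels.
#' @param seed RNG seed for the K-means initializations.
#' @param n_init Number of random initializations.
#' @return List with `labels` (factor good/medium/poor in input order) and
#'   `summary` (per-cluster n, mean, SD), plus the within-cluster sum of
#'   squares `tot_withinss`.
#' @export
cluster_performance <- function(z_scores, k = 3L, seed = 1L, n_init = 25L) {
  if (length(unique(z_scores)) < k) {
    stop(sprintf("need at least %d distinct z-scores for %d clusters", k, k),
         call. = FALSE)
  }
  if (length(z_scores) == k) {
    # one subject per level: the partition is forced
    km <- list(cluster = seq_len(k),
               centers = matrix(z_scores, ncol = 1), tot.withinss = 0)
  } else {
    km <- with_seed(seed,
                    stats::kmeans(matrix(z_scores, ncol = 1), centers = k,
                                  nstart = n_init, iter.max = 100L))
  }
  level_names <- if (k == 3L) c("good", "medium", "poor") else
    paste0("level", seq_len(k))
  ord <- order(km$centers[, 1], decreasing = TRUE)
  labels <- factor(level_names[match(km$cluster, ord)], levels = level_names)
  summary <- data.frame(
    cluster = level_names,
    n = as.integer(table(labels)[level_names]),
    mean_z = vapply(level_names, function(l) mean(z_scores[labels == l]), 0),
    sd_z = vapply(level_names, function(l) stats::sd(z_scores[labels == l]), 0),
    row.names = NULL, stringsAsFactors = FALSE)
  list(labels = labels, summary = summary, tot_withinss = km$tot.withinss)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items
#' (1 = identical partitions, ~0 = chance).
#'
#' @param a,b Vectors of cluster labels.
#' @return Adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
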