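# End-to-end orchestration: synthetic or file-based cohorts through
# preprocessing, feature extraction, WCST scoring and the statistical
# designs, with CSV/JSON artifacts and a reproducibility manifest.

#' Run the full analysis pipeline on a cohort
#'
#' In `"synthetic"` mode the cohort is generated from `config`
#' subject-by-subject (recordings are synthesized, processed and released
#' to bound memory). In `"files"` mode, `files` names per-subject EDF
#' recordings and WCST trial-log CSVs on disk. Either way each subject's
#' recordings pass the fixed preprocessing chain, spectral features are
#' extracted, trial logs are scored and standardized across the cohort,
#' subjects are clustered into performance levels, and the statistical
#' designs are run over the feature table (all subjects plus the
#' good-performers and elders subgroup analyses). Subjects failing feature
#' extraction (e.g. too few accepted epochs) are skipped with a message
#' and recorded in the manifest; the run only fails when no subject
#' completes.
#'
#' @param config A [cohort_config()] (synthetic mode; also supplies the
#'   epoch/threshold defaults in files mode when `params` is not given).
#' @param mode `"synthetic"` or `"files"`.
#' @param files data.frame for files mode: columns `subject_id`, `age`,
#'   `task_edf`, `baseline_edf`, `trial_log`.
#' @param params Preprocessing parameters, see [preprocess_params()].
#' @param out_dir Optional output directory for the artifact bundle
#'   (features and statistics CSVs, cluster summary JSON, manifest JSON).
#' @param artifacts Plant artifacts in synthetic mode?
#' @return List with `features` (wide per-subject table), `stats` (tidy
#'   results for all + subgroups), `clusters`, `scores`, `manifest`.
#' @export
run_pipeline <- function(config, mode = c("synthetic", "files"),
                         files = NULL, params = preprocess_params(),
                         out_dir = NULL, artifacts = TRUE) {
  mode <- match.arg(mode)
  if (mode == "synthetic") {
    if (is.null(config$seed)) stop("synthetic mode requires a seed",
                                   call. = FALSE)
    truths <- cohort_truths(config)
    n <- length(truths)
    ids <- vapply(truths, `[[`, "", "subject_id")
    ages <- vapply(truths, `[[`, 0, "age")
    groups <- vapply(truths, `[[`, "", "age_group")
  } else {
    need <- c("subject_id", "age", "task_edf", "baseline_edf", "trial_log")
    if (is.null(files) || !all(need %in% names(files))) {
      stop("files mode needs a data.frame with columns ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    n <- nrow(files)
    ids <- as.character(files$subject_id)
    ages <- files$age
    groups <- if ("age_group" %in% names(files)) {
      as.character(files$age_group)
    } else {
      cut(ages, c(-Inf, 45, 66, Inf), labels = c("young", "mid", "elder"))
    }
  }

  feat_rows <- vector("list", n)
  logs <- vector("list", n)
  failures <- character()
  for (i in seq_len(n)) {
    res <- tryCatch({
      if (mode == "synthetic") {
        bundle <- subject_recordings(truths[[i]], config,
                                     artifacts = artifacts)
        task <- bundle$task
        baseline <- bundle$baseline
        logs[[i]] <- bundle$trial_log
      } else {
        for (f in c("task_edf", "baseline_edf", "trial_log")) {
          if (!file.exists(files[[f]][i])) {
            stop("unreadable input: ", files[[f]][i], call. = FALSE)
          }
        }
        task <- read_edf(files$task_edf[i])
        baseline <- read_edf(files$baseline_edf[i])
        logs[[i]] <- read_trial_log(files$trial_log[i])
      }
      sf <- subject_features(task, baseline, params,
                             seed = config$seed + 2L * i)
      cbind(data.frame(subject_id = ids[i], age = ages[i],
                       age_group = as.character(groups[i]),
                       stringsAsFactors = FALSE),
            sf$features)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (grepl("unreadable input", conditionMessage(res))) stop(res)
      message(sprintf("subject %s skipped: %s", ids[i],
                      conditionMessage(res)))
      failures <- c(failures, ids[i])
    } else {
      feat_rows[[i]] <- res
    }
  }
  done <- !vapply(feat_rows, is.null, TRUE)
  if (!any(done)) stop("no subject completed the pipeline", call. = FALSE)
  features <- do.call(rbind, feat_rows[done])

  scores <- score_cohort(logs[done])
  scores$subject_id <- features$subject_id
  features$z_score <- scores$z_score
  clusters <- cluster_performance(features$z_score, seed = config$seed)
  features$performance_cluster <- as.character(clusters$labels)

  stats_all <- run_design(features, subgroup = "all")
  stats_good <- tryCatch(run_design(features, subgroup = "good_performers"),
                         error = function(e) NULL)
  stats_eld <- tryCatch(run_design(features, subgroup = "elders"),
                        error = function(e) NULL)
  stats <- do.call(rbind, Filter(Negate(is.null),
                                 list(stats_all, stats_good, stats_eld)))

  manifest <- list(
    package_version = as.character(utils::packageVersion("eegwcst")),
    mode = mode, seed = config$seed,
    n_subjects = n, n_completed = sum(done), failed_subjects = failures,
    task_duration = config$task_duration,
    baseline_duration = config$baseline_duration,
    fs = config$fs, epoch_length = config$epoch_length,
    amp_thresh = params$amp_thresh, ptp_thresh = params$ptp_thresh,
    ocular_correction = params$ocular_correction)

  out <- list(features = features, stats = stats, clusters = clusters,
              scores = scores, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(features, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    utils::write.csv(stats, file.path(out_dir, "statistics.csv"),
                     row.names = FALSE)
    utils::write.csv(scores, file.path(out_dir, "wcst_scores.csv"),
                     row.names = FALSE)
    jsonlite::write_json(clusters$summary,
                         file.path(out_dir, "clusters.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Tidy (long) view of a wide feature table
#'
#' @param features Wide feature table from [run_pipeline()].
#' @return data.frame with `subject_id`, `feature`, `value`.
#' @export
features_long <- function(features) {
  meta <- c("subject_id", "age", "age_group", "z_score",
            "performance_cluster")
  cols <- setdiff(names(features), meta)
  cols <- cols[vapply(features[cols], is.numeric, TRUE)]
  out <- do.call(rbind, lapply(cols, function(cn) {
    data.frame(subject_id = features$subject_id, feature = cn,
               value = features[[cn]], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
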