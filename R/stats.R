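# Statistical designs: two-way ANOVA (age group x performance cluster),
# linear regression on age and performance z-score, and partial
# correlations controlling the collinear companion variable.

#' Two-way ANOVA of a feature on age group and performance cluster
#'
#' Unbalanced-design ANOVA with Type II sums of squares. The interaction
#' term is included when every non-empty cell holds at least two
#' observations and is dropped otherwise (the designs of interest report
#' main effects).
#'
#' @param data data.frame containing the feature and both factors.
#' @param feature Name of the response column.
#' @param factor_a,factor_b Names of the factor columns.
#' @return data.frame with one row per term: `term`, `F`, `df`, `df_resid`,
#'   `p`, plus `feature`, `design`, `n`.
#' @export
two_way_anova <- function(data, feature, factor_a = "age_group",
                          factor_b = "performance_cluster") {
  fa <- droplevels(factor(data[[factor_a]]))
  fb <- droplevels(factor(data[[factor_b]]))
  y <- data[[feature]]
  if (nlevels(fa) < 2L || nlevels(fb) < 2L) {
    stop(sprintf("both factors need >= 2 non-empty levels (%s: %d, %s: %d)",
                 factor_a, nlevels(fa), factor_b, nlevels(fb)),
         call. = FALSE)
  }
  if (stats::var(y) == 0) {
    stop("constant feature: F statistics undefined", call. = FALSE)
  }
  cells <- table(fa, fb)
  with_inter <- all(cells[cells > 0] >= 2L) && all(cells > 0)
  d <- data.frame(y = y, A = fa, B = fb)
  fit <- if (with_inter) stats::lm(y ~ A * B, data = d) else
    stats::lm(y ~ A + B, data = d)
  aov2 <- car::Anova(fit, type = 2)
  terms <- rownames(aov2)
  keep <- terms != "Residuals"
  out <- data.frame(
    feature = feature, design = "anova2",
    term = c(factor_a, factor_b, if (with_inter) "interaction")[
      seq_len(sum(keep))],
    F = aov2$`F value`[keep],
    df = aov2$Df[keep],
    df_resid = aov2$Df[!keep],
    p = aov2$`Pr(>F)`[keep],
    n = length(y), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Linear regression of a feature on age and performance
#'
#' Ordinary least squares with intercept; reports slope, standard error,
#' t and p per predictor.
#'
#' @param data data.frame containing the feature and predictors.
#' @param feature Response column name.
#' @param predictors Character vector of predictor column names.
#' @return data.frame with `term`, `estimate`, `se`, `t`, `p` per
#'   predictor, plus `feature`, `design`, `n`.
#' @export
linear_regression <- function(data, feature,
                              predictors = c("age", "z_score")) {
  n <- nrow(data)
  if (n <= length(predictors) + 1L) {
    stop("need n > number of predictors + 1", call. = FALSE)
  }
  X <- as.matrix(data[, predictors, drop = FALSE])
  if (length(predictors) > 1L) {
    cc <- stats::cor(X)
    diag(cc) <- 0
    if (any(abs(cc) > 1 - 1e-12)) {
      idx <- which(abs(cc) == max(abs(cc)), arr.ind = TRUE)[1, ]
      stop(sprintf("perfectly collinear predictors: %s and %s",
                   predictors[idx[1]], predictors[idx[2]]), call. = FALSE)
    }
  }
  fml <- stats::as.formula(paste(feature, "~",
                                 paste(predictors, collapse = " + ")))
  fit <- stats::lm(fml, data = data)
  cf <- summary(fit)$coefficients
  cf <- cf[rownames(cf) != "(Intercept)", , drop = FALSE]
  data.frame(feature = feature, design = "regression",
             term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
             t = cf[, 3], p = cf[, 4], n = n,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' First-order partial correlation
#'
#' r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2)), equal to
#' the correlation of the residuals from regressing x on z and y on z. The
#' p-value comes from the t distribution with n - 3 degrees of freedom.
#'
#' @param x,y,z Numeric vectors of equal length (n >= 4); `z` is the
#'   controlled variable.
#' @return List with `r`, `df`, `t`, `p`, `n`.
#' @export
partial_correlation <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n) {
    stop("x, y, z must have the same length", call. = FALSE)
  }
  if (n < 4L) stop("partial correlation needs n >= 4", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0 || stats::sd(z) == 0) {
    stop("constant input: correlation undefined", call. = FALSE)
  }
  rxy <- stats::cor(x, y)
  rxz <- stats::cor(x, z)
  ryz <- stats::cor(y, z)
  if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12) {
    stop("degenerate control: |correlation with z| = 1", call. = FALSE)
  }
  r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  r <- min(max(r, -1), 1)
  df <- n - 3L
  tt <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, df = df, t = tt, p = 2 * stats::pt(-abs(tt), df), n = n)
}

#' Run the full statistical design over a feature table
#'
#' Applies, per feature column, the two-way ANOVA (age group x performance
#' cluster), the two-predictor linear regression (age, z-score) and both
#' partial correlations (feature-age controlling z-score; feature-z-score
#' controlling age). Subgroup modes replicate the confirmatory analyses:
#' `"good_performers"` restricts to the good cluster and tests age effects
#' (Pearson and age partialling z-score); `"elders"` restricts to the
#' oldest group and tests performance effects.
#'
#' @param features Feature table: one row per subject, metadata columns
#'   `subject_id`, `age`, `age_group`, `z_score`, `performance_cluster`
#'   plus numeric feature columns.
#' @param feature_cols Feature columns to analyze (default: all numeric
#'   non-metadata columns).
#' @param subgroup `"all"`, `"good_performers"` or `"elders"`.
#' @param p_adjust Optional multiple-testing correction applied within each
#'   design (`"none"` or `"BH"`).
#' @return Tidy data.frame of results (one row per feature x design x
#'   term) with a `subgroup` column.
#' @export
run_design <- function(features, feature_cols = NULL,
                       subgroup = c("all", "good_performers", "elders"),
                       p_adjust = c("none", "BH")) {
  subgroup <- match.arg(subgroup)
  p_adjust <- match.arg(p_adjust)
  meta <- c("subject_id", "age", "age_group", "z_score",
            "performance_cluster", "apf_low_confidence")
  if (is.null(feature_cols)) {
    feature_cols <- setdiff(names(features)[vapply(features, is.numeric,
                                                   TRUE)],
                            meta)
  }
  dat <- switch(subgroup,
                all = features,
                good_performers =
                  features[features$performance_cluster == "good", ],
                elders = features[features$age_group == "elder", ])
  if (!nrow(dat)) stop(sprintf("subgroup '%s' is empty", subgroup),
                       call. = FALSE)
  out <- list()
  for (f in feature_cols) {
    res <- tryCatch(if (subgroup == "all") {
      # a saturated or degenerate factorial design (tiny cohorts) drops
      # the ANOVA rows for this feature but keeps the other designs
      av <- tryCatch(two_way_anova(dat, f), error = function(e) NULL)
      lr <- linear_regression(dat, f)
      pc_age <- partial_correlation(dat[[f]], dat$age, dat$z_score)
      pc_z <- partial_correlation(dat[[f]], dat$z_score, dat$age)
      rbind(
        if (!is.null(av)) {
          data.frame(feature = f, design = "anova2", term = av$term,
                     estimate = av$F, p = av$p, n = av$n,
                     stringsAsFactors = FALSE)
        },
        data.frame(feature = f, design = "regression", term = lr$term,
                   estimate = lr$estimate, p = lr$p, n = lr$n,
                   stringsAsFactors = FALSE),
        data.frame(feature = f, design = "partial_corr",
                   term = c("age", "z_score"),
                   estimate = c(pc_age$r, pc_z$r),
                   p = c(pc_age$p, pc_z$p), n = pc_age$n,
                   stringsAsFactors = FALSE))
    } else if (subgroup == "good_performers") {
      ct <- stats::cor.test(dat[[f]], dat$age)
      pc <- partial_correlation(dat[[f]], dat$age, dat$z_score)
      data.frame(feature = f, design = c("pearson", "partial_corr"),
                 term = "age", estimate = c(unname(ct$estimate), pc$r),
                 p = c(ct$p.value, pc$p), n = nrow(dat),
                 stringsAsFactors = FALSE)
    } else {
      ct <- stats::cor.test(dat[[f]], dat$z_score)
      pc <- partial_correlation(dat[[f]], dat$z_score, dat$age)
      data.frame(feature = f, design = c("pearson", "partial_corr"),
                 term = "z_score", estimate = c(unname(ct$estimate), pc$r),
                 p = c(ct$p.value, pc$p), n = nrow(dat),
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      message(sprintf("feature %s skipped in subgroup %s: %s", f, subgroup,
                      conditionMessage(e)))
      NULL
    })
    out[[f]] <- res
  }
  if (!length(Filter(Negate(is.null), out))) {
    stop("no feature could be analyzed", call. = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$subgroup <- subgroup
  if (p_adjust == "BH") {
    for (d in unique(out$design)) {
      sel <- out$design == d
      out$p[sel] <- stats::p.adjust(out$p[sel], "BH")
    }
  }
  out
}
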