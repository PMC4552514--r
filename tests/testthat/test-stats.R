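# Statistical designs: two-way ANOVA, regression, partial correlation.

test_that("partial correlation reproduces the closed-form value", {
  # construct vectors with exact sample correlations r_xy = 0.5,
  # r_xz = 0.6, r_yz = 0.6 from an orthonormal basis
  n <- 12
  e <- qr.Q(qr(cbind(rep(1, n), matrix(rnorm(n * 3), n))))[, 2:4]
  x <- e[, 1]
  z <- 0.6 * e[, 1] + 0.8 * e[, 2]
  b <- (0.6 - 0.5 * 0.6) / 0.8
  y <- 0.5 * e[, 1] + b * e[, 2] + sqrt(1 - 0.25 - b^2) * e[, 3]
  pc <- partial_correlation(x, y, z)
  expect_equal(pc$r, (0.5 - 0.36) / (1 - 0.36), tolerance = 1e-12)
  expect_equal(pc$r, 0.21875, tolerance = 1e-12)
})

test_that("partial correlation equals the residual-regression oracle", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    z <- rnorm(n)
    x <- 0.5 * z + rnorm(n)
    y <- -0.3 * z + 0.4 * x + rnorm(n)
    pc <- partial_correlation(x, y, z)
    oracle <- cor(resid(lm(x ~ z)), resid(lm(y ~ z)))
    expect_equal(pc$r, oracle, tolerance = 1e-10)
  }
})

test_that("partial correlation edge behaviour", {
  set.seed(3)
  z <- rnorm(50)
  x <- rnorm(50)
  expect_equal(partial_correlation(x, x, z)$r, 1)
  big <- partial_correlation(rnorm(1000), rnorm(1000), rnorm(1000))
  expect_lt(abs(big$r), 0.1)
  expect_error(partial_correlation(x, rnorm(50), x), "degenerate")
  expect_error(partial_correlation(x[1:3], x[1:3], z[1:3]), "n >= 4")
  expect_error(partial_correlation(x, rnorm(10), z), "same length")
})

test_that("type II sums of squares reduce to classical ANOVA when balanced", {
  set.seed(21)
  d <- expand.grid(A = factor(1:3), B = factor(1:2), rep = 1:5)
  d$y <- rnorm(nrow(d)) + as.numeric(d$A)
  res <- two_way_anova(d, "y", "A", "B")
  cl <- summary(stats::aov(y ~ A * B, data = d))[[1]]
  rownames(cl) <- trimws(rownames(cl))
  expect_equal(res$F[res$term == "A"], cl["A", "F value"],
               tolerance = 1e-8)
  expect_equal(res$F[res$term == "B"], cl["B", "F value"],
               tolerance = 1e-8)
  expect_equal(res$p[res$term == "interaction"], cl["A:B", "Pr(>F)"],
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("two-way ANOVA recovers a planted main effect and not a null one", {
  set.seed(77)
  n <- 90
  d <- data.frame(A = factor(sample(1:3, n, TRUE)),
                  B = factor(sample(1:3, n, TRUE)))
  d$y <- 2 * as.numeric(d$A) + rnorm(n)
  res <- two_way_anova(d, "y", "A", "B")
  expect_lt(res$p[res$term == "A"], 0.01)
  expect_gt(res$p[res$term == "B"], 0.05)
  # row permutation leaves the statistics unchanged
  perm <- d[sample(n), ]
  res2 <- two_way_anova(perm, "y", "A", "B")
  expect_equal(res$F, res2$F, tolerance = 1e-10)
})

test_that("two-way ANOVA validates its factors and response", {
  d <- data.frame(A = factor(rep(1, 10)), B = factor(rep(1:2, 5)),
                  y = rnorm(10))
  expect_error(two_way_anova(d, "y", "A", "B"), "levels")
  d2 <- data.frame(A = factor(rep(1:2, 5)), B = factor(rep(1:2, each = 5)),
                   y = rep(1, 10))
  expect_error(two_way_anova(d2, "y", "A", "B"), "constant")
})

test_that("regression recovers noiseless coefficients and flags collinearity", {
  set.seed(5)
  d <- data.frame(age = runif(40, 20, 80))
  d$z_score <- rnorm(40)
  d$y <- 2 * d$age + 1e-9 * rnorm(40)
  res <- linear_regression(d, "y")
  expect_equal(res$estimate[res$term == "age"], 2, tolerance = 1e-6)
  expect_lt(abs(res$estimate[res$term == "z_score"]), 1e-6)
  d$dup <- d$age
  expect_error(linear_regression(d, "y", c("age", "dup")), "collinear")
  expect_error(linear_regression(d[1:3, ], "y"), "n >")
})

test_that("regression slopes transform correctly under predictor rescaling", {
  set.seed(8)
  d <- data.frame(age = runif(50, 20, 80), z_score = rnorm(50))
  d$y <- 0.5 * d$age - 1.2 * d$z_score + rnorm(50)
  r1 <- linear_regression(d, "y")
  d2 <- transform(d, age = age / 10)
  r2 <- linear_regression(d2, "y")
  expect_equal(r2$estimate[r2$term == "age"],
               10 * r1$estimate[r1$term == "age"], tolerance = 1e-10)
  expect_equal(r2$p, r1$p, tolerance = 1e-10)
})

test_that("run_design covers all designs and subgroup modes", {
  set.seed(13)
  n <- 45
  feats <- data.frame(
    subject_id = sprintf("S%02d", 1:n),
    age = runif(n, 20, 80),
    age_group = sample(c("young", "mid", "elder"), n, TRUE),
    z_score = rnorm(n),
    performance_cluster = sample(c("good", "medium", "poor"), n, TRUE),
    f1 = rnorm(n), f2 = rnorm(n))
  res <- run_design(feats)
  expect_setequal(unique(res$design), c("anova2", "regression",
                                        "partial_corr"))
  expect_true(all(res$p >= 0 & res$p <= 1))
  good <- run_design(feats, subgroup = "good_performers")
  expect_true(all(good$term == "age"))
  eld <- run_design(feats, subgroup = "elders")
  expect_true(all(eld$term == "z_score"))
  feats2 <- feats[feats$age_group != "elder", ]
  expect_error(run_design(feats2, subgroup = "elders"), "empty")
})
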