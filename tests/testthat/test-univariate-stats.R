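test_that("Welch t from summaries matches t.test on raw data", {
  set.seed(5)
  for (i in 1:25) {
    x <- rnorm(sample(5:40, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(5:40, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    ref <- t.test(x, y)
    gs <- group_summary(length(x), mean(x), sd(x), length(y), mean(y), sd(y))
    wt <- welch_t(gs)
    expect_equal(wt$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(wt$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(wt$p, ref$p.value, tolerance = 1e-10)
  }
  same <- group_summary(10, 1, 1, 12, 1, 1)
  expect_equal(welch_t(same)$statistic, 0)
  expect_equal(welch_t(same)$p, 1)
  expect_error(welch_t(group_summary(5, 1, 0, 5, 2, 0)), "zero")
})

test_that("pooled-SD Cohen's d: invariances and degenerate cases", {
  gs <- group_summary(21, 71.52, 4.33, 39, 68.87, 3.41)
  d <- cohens_d(gs)
  scaled <- group_summary(21, 71.52 * 3, 4.33 * 3, 39, 68.87 * 3, 3.41 * 3)
  expect_equal(cohens_d(scaled), d, tolerance = 1e-12)
  expect_equal(cohens_d(group_summary(10, 2, 1, 10, 2, 2)), 0)
  expect_error(cohens_d(group_summary(5, 1, 0, 5, 1, 0)), "zero")
})

test_that("Yates chi-square and Cramer's V", {
  # proportionally identical rows
  expect_equal(chi2_cramers_v(matrix(c(10, 30, 20, 60), 2, byrow = TRUE))$cramers_v,
               0, tolerance = 1e-12)
  # invariant to swapping rows or columns
  set.seed(6)
  for (i in 1:20) {
    m <- matrix(rpois(4, 15) + 1, 2)
    v0 <- chi2_cramers_v(m)$cramers_v
    expect_equal(chi2_cramers_v(m[2:1, ])$cramers_v, v0)
    expect_equal(chi2_cramers_v(m[, 2:1])$cramers_v, v0)
    ref <- suppressWarnings(chisq.test(m, correct = TRUE))
    expect_equal(chi2_cramers_v(m)$statistic, unname(ref$statistic))
  }
  # small deviation is floored to zero by the continuity correction
  visual <- matrix(c(20, 1, 36, 3), 2, byrow = TRUE)
  expect_equal(chi2_cramers_v(visual)$statistic, 0)
  expect_equal(chi2_cramers_v(visual)$cramers_v, 0)
  expect_error(chi2_cramers_v(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "zero margin")
})

test_that("pairwise Pearson matrix matches the direct formula", {
  set.seed(12)
  X <- matrix(rnorm(20 * 4), 20, 4)
  X[c(3, 25, 61)] <- NA
  vars <- data.frame(name = paste0("v", 1:4), domain = "gait",
                     kind = "continuous", units = "")
  ft <- feature_table(X, c(rep("faller", 8), rep("non_faller", 12)), vars)
  pm <- pearson_matrix(ft)
  expect_equal(diag(pm$r), rep(1, 4), ignore_attr = TRUE)
  expect_true(isSymmetric(pm$r))
  for (i in 1:3) for (j in (i + 1):4) {
    ok <- complete.cases(X[, c(i, j)])
    a <- X[ok, i]; b <- X[ok, j]
    rij <- sum((a - mean(a)) * (b - mean(b))) /
      ((length(a) - 1) * sd(a) * sd(b))
    expect_equal(pm$r[i, j], rij, tolerance = 1e-12)
    expect_equal(pm$n[i, j], sum(ok), ignore_attr = TRUE)
  }
  # exact linear relation
  Y <- cbind(x = rnorm(12), y = 0)
  Y[, 2] <- 2 * Y[, 1] + 3
  ft2 <- feature_table(Y, c(rep("faller", 5), rep("non_faller", 7)),
                       vars[1:2, ])
  pm2 <- pearson_matrix(ft2)
  expect_equal(pm2$r[1, 2], 1, tolerance = 1e-12)
  expect_true(pm2$collinear[1, 2])
  expect_equal(pm2$label[1, 2], "large")
})

test_that("Bartlett's sphericity follows the closed form", {
  expect_equal(bartlett_sphericity(diag(4), 60)$statistic, 0)
  expect_equal(bartlett_sphericity(diag(4), 60)$p, 1)
  r <- matrix(0.9, 3, 3); diag(r) <- 1
  bt <- bartlett_sphericity(r, 60)
  # det of a 3x3 equicorrelation matrix: (1-r)^2 (1+2r)
  expect_equal(bt$statistic,
               -(60 - 1 - (2 * 3 + 5) / 6) * log(0.1^2 * 2.8),
               tolerance = 1e-12)
  expect_equal(bt$df, 3)
  expect_true(bt$redundant)
  near <- matrix(0.999, 3, 3); diag(near) <- 1
  expect_lt(bartlett_sphericity(near, 60)$p, 1e-10)
  sing <- matrix(1, 3, 3)
  expect_error(bartlett_sphericity(sing, 60), "singular")
})

test_that("univariate screen dispatches by variable kind", {
  cfg <- small_config(seed = 33, n_nuisance = c(balance = 0, gait = 0,
                                                clinical = 0, strength = 0,
                                                body_composition = 0))
  ft <- generate_cohort(cfg)
  scr <- univariate_screen(ft)
  expect_equal(nrow(scr), ncol(ft$values))
  expect_setequal(scr$test[ft$variables$kind == "binary"], "chi2_yates")
  expect_true(all(scr$p >= 0 & scr$p <= 1))
  expect_true(all(scr$effect_size >= 0))
  # welch null calibration under a no-effect generator
  nullvars <- data.frame(name = sprintf("v%02d", 1:20), domain = "gait",
                         panel = "assessment", kind = "continuous",
                         units = "", faller_mean = 0, faller_sd = 1,
                         nonfaller_mean = 0, nonfaller_sd = 1,
                         faller_p = NA_real_, nonfaller_p = NA_real_,
                         signal = FALSE)
  rej <- 0; tot <- 0
  for (s in 1:25) {
    cfg0 <- cohort_config(nullvars, within_r = setNames(rep(0, 5), c(
      "balance", "gait", "clinical", "strength", "body_composition")),
      missing_rate = 0, seed = 100 + s)
    scr0 <- univariate_screen(generate_cohort(cfg0))
    rej <- rej + sum(scr0$p < 0.05); tot <- tot + nrow(scr0)
  }
  expect_gt(rej / tot, 0.015)   # coarse null sanity; the deep calibration
  expect_lt(rej / tot, 0.10)    # lives in the acceptance suite
})
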