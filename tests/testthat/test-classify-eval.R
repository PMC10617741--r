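test_that("ROC/AUC equals the concordant-pair oracle, including ties", {
  set.seed(15)
  for (i in 1:30) {
    n1 <- sample(3:12, 1); n0 <- sample(3:18, 1)
    y <- c(rep(1, n1), rep(0, n0))
    scores <- if (i %% 3 == 0) sample(1:4, n1 + n0, replace = TRUE)
              else rnorm(n1 + n0)
    rr <- roc_report(scores, y)
    expect_equal(rr$auc, auc_bruteforce(scores, y), tolerance = 1e-12)
    # ROC is monotone in both coordinates
    expect_true(all(diff(rr$roc$fpr) >= 0))
    expect_true(all(diff(rr$roc$tpr) >= 0))
  }
  # agreement with an independent ROC implementation
  set.seed(16)
  y <- c(rep(1, 21), rep(0, 39))
  s <- rnorm(60) + y
  expect_equal(roc_report(s, y)$auc,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("Youden cutoff and confusion counts are internally consistent", {
  set.seed(17)
  y <- c(rep(1, 21), rep(0, 39))
  s <- rnorm(60) + 1.2 * y
  rr <- roc_report(s, y)
  conf <- confusion_at(s, y, rr$cutoff)
  expect_equal(conf$sensitivity, rr$sensitivity)
  expect_equal(conf$specificity, rr$specificity)
  j <- rr$sensitivity + rr$specificity - 1
  for (th in unique(s))
    expect_lte(confusion_at(s, y, th)$sensitivity +
                 confusion_at(s, y, th)$specificity - 1, j + 1e-12)
  # boundary cutoffs
  all_in <- confusion_at(s, y, min(s))
  expect_equal(all_in$sensitivity, 1)
  expect_equal(all_in$specificity, 0)
  none_in <- confusion_at(s, y, Inf)
  expect_equal(none_in$sensitivity, 0)
  expect_equal(none_in$specificity, 1)
  # the study's arithmetic: 18/21 and 28/39 correct
  expect_equal(round(100 * 18 / 21), 86)
  expect_equal(round(100 * 28 / 39), 72)
  # separated scores give AUC 1, null scores hover at 0.5
  expect_equal(roc_report(c(2, 3, 4, 0, 1), c(1, 1, 1, 0, 0))$auc, 1)
  set.seed(18)
  nulls <- replicate(40, roc_report(rnorm(60), y)$auc)
  expect_equal(mean(nulls), 0.5, tolerance = 0.1)
  expect_error(roc_report(rnorm(5), rep(1, 5)), "both classes")
})

test_that("logistic reports: intercept-only closed form and diagnostics", {
  ft <- separable_table(seed = 19, shift = 0)
  y <- group_indicator(ft)
  fit <- logistic_fit(ft, character(0))
  expect_equal(unname(coef(fit)[1]), log(21 / 39), tolerance = 1e-8)
  expect_equal(unique(round(fit$fitted, 10)), round(21 / 60, 10))
  expect_equal(fit$mcfadden_r2, 0, tolerance = 1e-8)
  # duplicated predictor is rank-deficient
  X <- cbind(ft$values, dup = ft$values[, 1])
  vars <- rbind(ft$variables, data.frame(name = "dup", domain = "gait",
                                         kind = "continuous", units = ""))
  ftd <- feature_table(X, as.character(ft$group), vars)
  expect_error(logistic_fit(ftd, c("signal", "dup")), "rank-deficient")
  # VIF agrees with the auxiliary-regression definition
  ft2 <- separable_table(seed = 20, shift = 1)
  preds <- c("signal", "noise01", "noise02")
  rep2 <- logistic_fit(ft2, preds)
  for (p in preds) {
    r2 <- summary(lm(reformulate(setdiff(preds, p), p),
                     data = as.data.frame(ft2$values)))$r.squared
    expect_equal(unname(rep2$vif[p]), 1 / (1 - r2), tolerance = 1e-6)
  }
  # McFadden matches its definition
  glm_fit <- glm(y ~ ft2$values[, preds], family = binomial())
  null_ll <- logLik(glm(y ~ 1, family = binomial()))
  expect_equal(rep2$mcfadden_r2, 1 - as.numeric(logLik(glm_fit)) /
                 as.numeric(null_ll), tolerance = 1e-8)
})

test_that("backward stepwise keeps signal, drops noise, never raises the criterion", {
  ft <- separable_table(seed = 23, shift = 2.5)
  full <- logistic_fit(ft, ft$variables$name)
  for (crit in c("AIC", "BIC")) {
    ref <- stepwise_backward(full, crit)
    expect_true("signal" %in% ref$predictors)
    expect_lte(length(ref$predictors), length(full$predictors))
    expect_true(all(diff(ref$path$criterion) < 0))
  }
  # pure noise: BIC collapses to (or near) the intercept-only model
  ftn <- separable_table(seed = 24, shift = 0)
  refn <- stepwise_backward(logistic_fit(ftn, ftn$variables$name), "BIC")
  expect_lte(length(refn$predictors), 2)
})

test_that("LOOCV accuracy: separable vs label-permuted data", {
  ft <- separable_table(seed = 25, shift = 4)
  cv <- loocv_accuracy(ft, "signal")
  expect_gt(cv$accuracy, 0.95)
  expect_identical(cv$accuracy, loocv_accuracy(ft, "signal")$accuracy)
  set.seed(26)
  ftp <- feature_table(ft$values, sample(as.character(ft$group)),
                       ft$variables)
  cvp <- loocv_accuracy(ftp, c("signal", "noise01", "noise02"))
  expect_lt(abs(cvp$accuracy - 0.65), 0.25)
})

test_that("PLSCA and forest classifiers wire scores into the ROC layer", {
  ft <- separable_table(seed = 27, shift = 4)
  pc <- plsca_classifier(ft, ft$variables$name)
  expect_gt(pc$roc$auc, 0.95)
  expect_gt(cor(pc$scores, group_indicator(ft)), 0)
  rc <- rf_classifier(ft, ft$variables$name, seed = 2)
  expect_gt(rc$roc$auc, 0.95)
  expect_identical(rf_classifier(ft, ft$variables$name, seed = 2)$scores,
                   rc$scores)
  # null data: both engines near chance
  ftn <- separable_table(seed = 28, shift = 0)
  expect_lt(plsca_classifier(ftn, ftn$variables$name)$roc$auc, 0.75)
})
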