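# The three classifiers (logistic regression with backward refinement,
# random forest, PLSCA latent score) and the shared evaluation layer:
# empirical ROC/AUC with a Mann-Whitney p-value, Youden-optimal cutoff,
# confusion counts, leave-one-out cross-validation.

as_binary_labels <- function(labels) {
  if (is.factor(labels)) as.integer(labels == "faller")
  else {
    labels <- as.integer(labels)
    if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1 or a faller factor")
    labels
  }
}

#' Empirical ROC analysis
#'
#' Builds the empirical ROC over all score thresholds (score >= cutoff is
#' classified faller), computes the AUC by the trapezoid rule — equal to the
#' Mann-Whitney U statistic scaled by \code{1/(n1 n0)} with ties counted one
#' half — a two-sided p-value for AUC = 0.5 from the normal-approximate
#' Mann-Whitney test (tie-corrected variance), and the optimal cutoff
#' maximizing Youden's J = sensitivity + specificity - 1 (ties resolved to
#' the lower threshold).
#'
#' @param scores numeric decision values, higher = more faller-like
#' @param labels faller/non-faller factor or 0/1 vector (1 = faller)
#' @return object of class \code{"roc_report"}: \code{auc}, \code{auc_p},
#'   \code{roc} (data frame threshold/fpr/tpr), \code{cutoff},
#'   \code{sensitivity}, \code{specificity}, \code{confusion} (TP/FN/TN/FP),
#'   \code{constant_scores} flag, \code{scores}, \code{labels}
#' @export
roc_report <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  if (anyNA(scores) || anyNA(y)) stop("missing scores or labels")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  constant <- length(unique(scores)) == 1L
  r <- rank(scores)
  U <- sum(r[y == 1]) - n1 * (n1 + 1) / 2
  auc <- U / (n1 * n0)
  N <- n1 + n0
  ties <- table(scores)
  tiecor <- sum(ties^3 - ties) / (N * (N - 1))
  varU <- n1 * n0 / 12 * ((N + 1) - tiecor)
  z <- if (varU > 0) (U - n1 * n0 / 2) / sqrt(varU) else 0
  auc_p <- if (constant) 1 else 2 * stats::pnorm(-abs(z))
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(th) sum(scores >= th & y == 1) / n1, numeric(1))
  fpr <- vapply(thr, function(th) sum(scores >= th & y == 0) / n0, numeric(1))
  roc <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  jj <- tpr - fpr
  best <- which(jj == max(jj))
  cutoff <- min(thr[best])        # ties -> lower threshold
  conf <- confusion_at(scores, y, cutoff)
  structure(list(auc = auc, auc_p = auc_p, roc = roc, cutoff = cutoff,
                 sensitivity = conf$sensitivity,
                 specificity = conf$specificity,
                 confusion = conf$counts, constant_scores = constant,
                 scores = scores, labels = y),
            class = "roc_report")
}

#' @export
print.roc_report <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (p = %.3g)%s\n", x$auc, x$auc_p,
              if (x$constant_scores) " [constant scores]" else ""))
  cat(sprintf("Youden cutoff %.4g: sensitivity %.0f%%, specificity %.0f%%\n",
              x$cutoff, 100 * x$sensitivity, 100 * x$specificity))
  cat(sprintf("confusion: TP %d, FN %d, TN %d, FP %d\n",
              x$confusion["TP"], x$confusion["FN"],
              x$confusion["TN"], x$confusion["FP"]))
  invisible(x)
}

#' Confusion counts at a score cutoff
#'
#' Scores at or above the cutoff are classified faller. Sensitivity is
#' TP/(TP+FN) over true fallers, specificity TN/(TN+FP) over non-fallers.
#'
#' @param scores numeric decision values
#' @param labels faller factor or 0/1 vector
#' @param cutoff classification threshold
#' @return list with \code{counts} (named TP/FN/TN/FP),
#'   \code{sensitivity}, \code{specificity}
#' @export
confusion_at <- function(scores, labels, cutoff) {
  y <- as_binary_labels(labels)
  pred <- as.integer(scores >= cutoff)
  tp <- sum(pred == 1 & y == 1); fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0); fp <- sum(pred == 1 & y == 0)
  list(counts = c(TP = tp, FN = fn, TN = tn, FP = fp),
       sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}

#' Logistic regression classifier with collinearity diagnostics
#'
#' Maximum-likelihood binomial logit of the faller indicator on the chosen
#' predictors, with per-predictor variance inflation factors (from the
#' auxiliary regressions among the predictors, computed as the diagonal of
#' the inverse predictor correlation matrix), AIC, BIC and McFadden
#' pseudo-R-squared (1 - logLik(model)/logLik(intercept-only)).
#' Perfect separation is detected from fitted probabilities pinned at 0/1
#' and reported in the \code{separation} flag rather than silently ignored.
#'
#' @param x a complete \code{\link{feature_table}}
#' @param predictors character vector of predictor variable names
#' @return object of class \code{"logistic_report"} with \code{model}
#'   (the glm), \code{coefficients} (estimate, p), \code{vif}, \code{aic},
#'   \code{bic}, \code{mcfadden_r2}, \code{fitted} probabilities,
#'   \code{separation}, plus the table and predictor list for refitting
#' @export
logistic_fit <- function(x, predictors) {
  stopifnot(inherits(x, "feature_table"))
  if (any(x$mask)) stop("feature table contains missing cells; impute first")
  if (length(predictors) >= nrow(x$values))
    stop("more predictors than participants")
  y <- group_indicator(x)
  df <- as.data.frame(x$values[, predictors, drop = FALSE])
  names(df) <- predictors
  df$.y <- y
  fit <- suppressWarnings(
    stats::glm(.y ~ ., family = stats::binomial(), data = df))
  if (anyNA(stats::coef(fit))) stop("rank-deficient design")
  null_fit <- stats::glm(.y ~ 1, family = stats::binomial(), data = df)
  mcf <- 1 - as.numeric(stats::logLik(fit)) / as.numeric(stats::logLik(null_fit))
  vifs <- if (length(predictors) >= 2L) {
    # 1 / (1 - R^2_j) of each predictor on the others = diag of the inverse
    # correlation matrix
    stats::setNames(diag(solve(stats::cor(x$values[, predictors]))),
                    predictors)
  } else stats::setNames(rep(1, length(predictors)), predictors)
  sm <- summary(fit)$coefficients
  fitted <- stats::fitted(fit)
  separation <- any(fitted > 1 - 1e-8) || any(fitted < 1e-8)
  structure(list(model = fit,
                 coefficients = data.frame(term = rownames(sm),
                                           estimate = sm[, 1],
                                           p = sm[, 4],
                                           stringsAsFactors = FALSE),
                 vif = vifs, aic = stats::AIC(fit), bic = stats::BIC(fit),
                 mcfadden_r2 = max(0, mcf), fitted = fitted,
                 separation = separation, table = x,
                 predictors = predictors),
            class = "logistic_report")
}

#' @export
print.logistic_report <- function(x, ...) {
  cat(sprintf("logistic model: %d predictor(s), AIC %.2f, BIC %.2f, McFadden R2 %.2f%s\n",
              length(x$predictors), x$aic, x$bic, x$mcfadden_r2,
              if (x$separation) " [separation]" else ""))
  tab <- round(x$coefficients[, c("estimate", "p")], 4)
  if (length(x$vif)) tab$vif <- round(c(NA, x$vif), 2)
  print(tab)
  invisible(x)
}

#' @export
coef.logistic_report <- function(object, ...) stats::coef(object$model)

criterion_value <- function(fit, criterion)
  if (criterion == "AIC") stats::AIC(fit$model) else stats::BIC(fit$model)

#' Backward stepwise refinement of a logistic model
#'
#' Iteratively removes the predictor whose removal most decreases the chosen
#' information criterion, until no removal decreases it (the intercept-only
#' model can be reached). Exact criterion ties are broken by removing the
#' predictor with the largest p-value in the current model, making the
#' elimination path deterministic.
#'
#' @param report a \code{\link{logistic_fit}} result
#' @param criterion \code{"AIC"} (default) or \code{"BIC"}
#' @return a \code{logistic_report} for the refined model, with the
#'   elimination \code{path} (data frame of step, dropped term, criterion)
#'   attached
#' @export
stepwise_backward <- function(report, criterion = c("AIC", "BIC")) {
  stopifnot(inherits(report, "logistic_report"))
  criterion <- match.arg(criterion)
  current <- report
  path <- data.frame(step = 0L, dropped = "",
                     criterion = criterion_value(current, criterion),
                     stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    preds <- current$predictors
    if (!length(preds)) break
    base_c <- criterion_value(current, criterion)
    cand <- lapply(preds, function(pr) {
      remaining <- setdiff(preds, pr)
      if (length(remaining)) logistic_fit(current$table, remaining)
      else intercept_only_fit(current$table)
    })
    cvals <- vapply(cand, criterion_value, numeric(1), criterion = criterion)
    if (min(cvals) >= base_c) break
    best <- which(cvals == min(cvals))
    if (length(best) > 1L) {
      pvals <- current$coefficients$p[match(preds[best],
                                            current$coefficients$term)]
      best <- best[which.max(pvals)]
    } else best <- best[1L]
    current <- cand[[best]]
    step <- step + 1L
    path <- rbind(path, data.frame(step = step, dropped = preds[best],
                                   criterion = cvals[best],
                                   stringsAsFactors = FALSE))
  }
  current$path <- path
  current$criterion <- criterion
  current
}

intercept_only_fit <- function(x) {
  y <- group_indicator(x)
  df <- data.frame(.y = y)
  fit <- stats::glm(.y ~ 1, family = stats::binomial(), data = df)
  structure(list(model = fit,
                 coefficients = data.frame(term = "(Intercept)",
                                           estimate = stats::coef(fit)[1],
                                           p = summary(fit)$coefficients[1, 4],
                                           stringsAsFactors = FALSE),
                 vif = numeric(0), aic = stats::AIC(fit),
                 bic = stats::BIC(fit), mcfadden_r2 = 0,
                 fitted = stats::fitted(fit), separation = FALSE,
                 table = x, predictors = character(0)),
            class = "logistic_report")
}

#' Leave-one-out cross-validated accuracy of a logistic model
#'
#' For each participant, the model is refitted on the remaining n - 1 and
#' the held-out participant is classified at probability 0.5 (not at the
#' in-sample Youden cutoff, to avoid information leakage). Folds that fail
#' to converge are counted and reported, not silently dropped.
#'
#' @param x a complete \code{\link{feature_table}}
#' @param predictors character vector of predictor names
#' @return list with \code{accuracy}, \code{predictions} (0/1),
#'   \code{probabilities}, \code{n_nonconverged}
#' @export
loocv_accuracy <- function(x, predictors) {
  stopifnot(inherits(x, "feature_table"))
  if (any(x$mask)) stop("feature table contains missing cells; impute first")
  y <- group_indicator(x)
  df <- as.data.frame(x$values[, predictors, drop = FALSE])
  names(df) <- predictors
  df$.y <- y
  n <- nrow(df)
  prob <- numeric(n)
  nonconv <- 0L
  for (i in seq_len(n)) {
    w <- withCallingHandlers(
      stats::glm(.y ~ ., family = stats::binomial(), data = df[-i, ]),
      warning = function(cond) {
        if (grepl("converge", conditionMessage(cond))) nonconv <<- nonconv + 1L
        invokeRestart("muffleWarning")
      })
    prob[i] <- stats::predict(w, newdata = df[i, , drop = FALSE],
                              type = "response")
  }
  pred <- as.integer(prob >= 0.5)
  list(accuracy = mean(pred == y), predictions = pred,
       probabilities = prob, n_nonconverged = nonconv)
}

#' PLSCA latent-score classifier
#'
#' Standardizes the chosen predictors, fits a group-indicator PLSCA and uses
#' the first-component latent scores as the classifier's decision values in
#' a \code{\link{roc_report}}. Sign canonicalization in the PLSCA fit makes
#' the score orientation (higher = more faller-like) explicit.
#'
#' @param x a complete \code{\link{feature_table}}
#' @param predictors character vector of predictor names
#' @return list with \code{roc} (a roc_report), \code{fit} (the plsca),
#'   \code{inertia}, \code{scores}
#' @export
plsca_classifier <- function(x, predictors) {
  stopifnot(inherits(x, "feature_table"))
  sub <- zscore_columns(select_variables(x, predictors))
  g <- group_indicator(x)
  gz <- matrix((g - mean(g)) / stats::sd(g), ncol = 1,
               dimnames = list(NULL, "faller"))
  fit <- fit_plsca(gz, sub$values)
  scores <- latent_scores(fit, sub$values)
  list(roc = roc_report(scores, x$group), fit = fit,
       inertia = fit$inertia, scores = scores)
}

#' Random-forest OOB classifier
#'
#' Fits the importance forest on the chosen predictors and evaluates the
#' out-of-bag faller vote fractions as decision values in a
#' \code{\link{roc_report}}.
#'
#' @param x a complete \code{\link{feature_table}}
#' @param predictors character vector of predictor names
#' @param n_trees number of trees (default 500)
#' @param seed integer seed
#' @return list with \code{roc}, \code{forest} (the forest_report),
#'   \code{scores}
#' @export
rf_classifier <- function(x, predictors, n_trees = 500, seed = 1L) {
  sub <- select_variables(x, predictors)
  forest <- fit_forest(sub, n_trees = n_trees, seed = seed)
  scores <- oob_predictions(forest)
  if (anyNA(scores))
    stop("some participants were never out of bag; increase n_trees")
  list(roc = roc_report(as.numeric(scores), x$group), forest = forest,
       scores = as.numeric(scores))
}
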