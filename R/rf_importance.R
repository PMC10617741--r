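# Random-forest importance engine: 500-tree classification forest with
# mean-decrease-in-Gini importance and out-of-bag validation.

#' Fit a classification random forest for variable importance
#'
#' 500-tree classification forest (Gini impurity, \code{floor(sqrt(p))}
#' candidate features per split, bootstrap sampling with replacement) on a
#' complete (imputed) feature table with the faller/non-faller label as the
#' response. Reports the mean decrease in the Gini index per variable, the
#' out-of-bag error rate, per-participant out-of-bag vote fractions, and an
#' out-of-bag p-value from a one-sided binomial test of OOB accuracy against
#' the no-information (majority-class) rate.
#'
#' @param x a complete \code{\link{feature_table}}
#' @param n_trees number of trees (default 500)
#' @param mtry features tried per split (default \code{floor(sqrt(p))})
#' @param seed integer seed
#' @return object of class \code{"forest_report"} with \code{importance}
#'   (named mean decrease in Gini), \code{oob_error}, \code{oob_p},
#'   \code{votes} (faller vote fraction per participant), \code{n_trees},
#'   \code{seed}, and the underlying \code{randomForest} fit
#' @export
fit_forest <- function(x, n_trees = 500, mtry = NULL, seed = 1L) {
  stopifnot(inherits(x, "feature_table"))
  if (any(x$mask)) stop("feature table contains missing cells; impute first")
  X <- x$values
  y <- x$group
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  set.seed(seed)
  fit <- randomForest::randomForest(x = X, y = y, ntree = n_trees,
                                    mtry = mtry, importance = FALSE)
  imp <- fit$importance[, "MeanDecreaseGini"]
  votes <- fit$votes[, "faller"]
  never_oob <- fit$oob.times == 0
  votes[never_oob] <- NA_real_
  pred <- fit$predicted
  correct <- sum(pred == y, na.rm = TRUE)
  nir <- max(table(y)) / length(y)
  oob_error <- mean(pred != y, na.rm = TRUE)
  oob_p <- stats::binom.test(correct, length(y), p = nir,
                             alternative = "greater")$p.value
  structure(list(importance = imp, oob_error = oob_error, oob_p = oob_p,
                 votes = votes, n_never_oob = sum(never_oob),
                 n_trees = n_trees, mtry = mtry, seed = seed,
                 no_information_rate = nir, fit = fit,
                 participant_ids = x$participant_ids),
            class = "forest_report")
}

#' @export
print.forest_report <- function(x, ...) {
  cat(sprintf("random forest: %d trees, mtry %d, seed %d\n",
              x$n_trees, x$mtry, x$seed))
  cat(sprintf("OOB error %.1f%% (no-information rate %.1f%%), binomial p = %.3g\n",
              100 * x$oob_error, 100 * x$no_information_rate, x$oob_p))
  cat("top importance (mean decrease in Gini):\n")
  print(round(utils::head(sort(x$importance, decreasing = TRUE), 10), 3))
  invisible(x)
}

#' Out-of-bag class probabilities
#'
#' Per-participant out-of-bag vote fraction for the faller class; the
#' forest's internally cross-validated score used for ROC analysis.
#' Participants never out of bag (possible at very small tree counts) carry
#' \code{NA}.
#'
#' @param report a \code{\link{fit_forest}} result
#' @return named numeric vector of vote fractions in [0, 1]
#' @export
oob_predictions <- function(report) {
  stopifnot(inherits(report, "forest_report"))
  stats::setNames(report$votes, report$participant_ids)
}
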