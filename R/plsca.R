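# Partial least squares correlation analysis (PLSCA): SVD of the cross-block
# correlation matrix, singular-value inertia as a shared-information measure,
# leave-one-variable-out (LOVO) importance, between-domain inertia with
# permutation inference, and latent scores for classification.

check_standardized <- function(M, tol = 1e-6, label = "block") {
  mu <- colMeans(M)
  s <- apply(M, 2, stats::sd)
  if (any(abs(mu) > tol) || any(abs(s - 1) > 1e-3))
    stop(label, " must be column-standardized (mean 0, SD 1)")
  invisible(TRUE)
}

as_block <- function(x) {
  if (inherits(x, "feature_table")) {
    if (any(x$mask)) stop("block contains missing cells; impute first")
    x$values
  } else as.matrix(x)
}

#' Cross-correlation matrix between two standardized blocks
#'
#' \code{R = t(X) Y / (n - 1)} for two column-standardized blocks observed on
#' the same participants; entries equal the pairwise Pearson correlations.
#' For group-vs-features analyses X is the z-scored faller indicator (a
#' single column).
#'
#' @param x,y matrices or feature_tables with z-scored columns and matching
#'   rows
#' @return the cross-correlation matrix (ncol(x) x ncol(y))
#' @export
cross_correlation <- function(x, y) {
  X <- as_block(x); Y <- as_block(y)
  if (nrow(X) != nrow(Y)) stop("blocks must have the same participants")
  check_standardized(X, label = "x"); check_standardized(Y, label = "y")
  crossprod(X, Y) / (nrow(X) - 1)
}

#' Fit a PLSCA decomposition
#'
#' Singular value decomposition of the cross-block correlation matrix. The
#' singular values quantify shared information: the inertia is the sum of
#' squared singular values over the retained components, and untruncated it
#' equals the squared Frobenius norm of R exactly. Saliences (singular
#' vectors) are sign-canonicalized: when x is a single group-indicator
#' column the first left salience is forced positive, so the first latent
#' score correlates positively with faller = 1; otherwise the largest-
#' magnitude element of each left salience is made positive.
#'
#' @param x,y standardized blocks (see \code{\link{cross_correlation}})
#' @param k number of retained components for the inertia (default all)
#' @return object of class \code{"plsca"} with \code{singular_values},
#'   \code{u}/\code{v} (left/right saliences, columns orthonormal),
#'   \code{inertia}, \code{k}, \code{R}, and the block column names
#' @export
fit_plsca <- function(x, y, k = NULL) {
  R <- cross_correlation(x, y)
  if (all(R == 0)) stop("degenerate all-zero cross-correlation matrix")
  sv <- svd(R)
  K <- length(sv$d)
  if (is.null(k)) k <- K
  if (k < 1 || k > K) stop("k out of range")
  u <- sv$u; v <- sv$v
  for (comp in seq_len(K)) {
    flip <- if (ncol(R) >= 1 && nrow(R) == 1L) sign(u[1L, comp])
            else sign(u[which.max(abs(u[, comp])), comp])
    if (flip < 0) { u[, comp] <- -u[, comp]; v[, comp] <- -v[, comp] }
  }
  structure(list(singular_values = sv$d, u = u, v = v,
                 inertia = sum(sv$d[seq_len(k)]^2), k = k, R = R,
                 x_names = rownames(R), y_names = colnames(R)),
            class = "plsca")
}

#' @export
print.plsca <- function(x, ...) {
  cat(sprintf("PLSCA: %d x %d cross-correlation block, %d component(s) retained\n",
              nrow(x$R), ncol(x$R), x$k))
  cat(sprintf("singular values: %s\n",
              paste(signif(utils::head(x$singular_values, 5), 4), collapse = ", ")))
  cat(sprintf("inertia: %.4f\n", x$inertia))
  invisible(x)
}

#' @export
summary.plsca <- function(object, ...) {
  d2 <- object$singular_values^2
  data.frame(component = seq_along(d2),
             singular_value = object$singular_values,
             squared = d2, proportion = d2 / sum(d2))
}

#' Leave-one-variable-out PLSCA importance
#'
#' The importance of each y-block variable is the decrease in singular value
#' inertia when that variable is left out and the decomposition refitted.
#' With untruncated inertia the decrease equals the dropped column's squared
#' norm in R, so every importance is non-negative and they sum to the
#' baseline inertia when x is a single column.
#'
#' @param x,y standardized blocks; y must have at least 2 variables
#' @param k retained components (default all, i.e. untruncated)
#' @return object of class \code{"lovo_importance"}: data frame-like list
#'   with \code{importance} (named vector), \code{baseline_inertia}, \code{k}
#' @export
lovo_importance <- function(x, y, k = NULL) {
  Y <- as_block(y)
  if (ncol(Y) < 2L) stop("y must contain at least 2 variables")
  full <- fit_plsca(x, Y, k = k)
  imp <- vapply(seq_len(ncol(Y)), function(j) {
    sub <- fit_plsca(x, Y[, -j, drop = FALSE], k = k)
    full$inertia - sub$inertia
  }, numeric(1))
  names(imp) <- colnames(Y)
  structure(list(importance = imp, baseline_inertia = full$inertia,
                 k = full$k),
            class = "lovo_importance")
}

#' @export
print.lovo_importance <- function(x, ...) {
  cat(sprintf("LOVO PLSCA importance over %d variables (baseline inertia %.4f)\n",
              length(x$importance), x$baseline_inertia))
  print(utils::head(sort(x$importance, decreasing = TRUE), 10))
  invisible(x)
}

#' Between-domain shared information
#'
#' Measured inertia of the PLSCA between two domain blocks and its
#' normalized value, the measured inertia divided by the summed variable
#' counts of the two blocks, which makes domain pairs of different sizes
#' comparable.
#'
#' @param a,b standardized domain blocks on the same participants
#' @return list with \code{measured}, \code{normalized}, \code{p_a},
#'   \code{p_b}
#' @export
between_domain_inertia <- function(a, b) {
  A <- as_block(a); B <- as_block(b)
  if (ncol(A) == 0 || ncol(B) == 0) stop("empty block")
  fit <- fit_plsca(A, B)
  list(measured = fit$inertia,
       normalized = normalize_inertia(fit$inertia, ncol(A), ncol(B)),
       p_a = ncol(A), p_b = ncol(B))
}

#' Normalize a measured inertia by block sizes
#'
#' @param measured measured (untruncated) inertia
#' @param p_a,p_b variable counts of the two blocks
#' @return measured / (p_a + p_b)
#' @export
normalize_inertia <- function(measured, p_a, p_b) measured / (p_a + p_b)

#' Permutation p-value for shared inertia
#'
#' Permutes the participant rows of y \code{b} times, refits the PLSCA and
#' compares the permuted inertias with the observed one:
#' \code{p = (1 + #(perm >= obs)) / (b + 1)}.
#'
#' @param x,y standardized blocks
#' @param b number of permutations (>= 99, default 999)
#' @param seed integer seed
#' @return the permutation p-value
#' @export
permutation_pvalue <- function(x, y, b = 999, seed = 1L) {
  if (b < 99) stop("use at least 99 permutations")
  X <- as_block(x); Y <- as_block(y)
  obs <- fit_plsca(X, Y)$inertia
  set.seed(seed)
  n <- nrow(Y)
  exceed <- 0L
  for (i in seq_len(b)) {
    Yp <- Y[sample.int(n), , drop = FALSE]
    if (fit_plsca(X, Yp)$inertia >= obs) exceed <- exceed + 1L
  }
  (1 + exceed) / (b + 1)
}

#' Latent participant scores on the first PLSCA component
#'
#' Projection of each participant's standardized y-block row onto the first
#' right salience. With the sign canonicalization of \code{\link{fit_plsca}}
#' the score correlates positively with the faller coding when x is the
#' group indicator; these scores are the PLSCA classifier's decision values.
#'
#' @param fit a fitted \code{"plsca"} object
#' @param y the standardized y block the model was fitted on (or new data
#'   with the same columns)
#' @return numeric vector of per-participant scores
#' @export
latent_scores <- function(fit, y) {
  stopifnot(inherits(fit, "plsca"))
  Y <- as_block(y)
  if (ncol(Y) != nrow(fit$v)) stop("column mismatch with fitted saliences")
  as.numeric(Y %*% fit$v[, 1L])
}
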