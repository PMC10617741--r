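# Univariate screening statistics: Welch t-tests and pooled-SD Cohen's d from
# group summaries, Yates-corrected chi-square with Cramer's V, pairwise
# Pearson correlation with collinearity flags, Bartlett's sphericity.

#' Two-group summary statistics
#'
#' Group sizes, means and SDs for fallers (group 1) and non-fallers
#' (group 2), the sufficient statistics for \code{\link{welch_t}} and
#' \code{\link{cohens_d}}.
#'
#' @param n1,mean1,sd1 faller count, mean, SD
#' @param n2,mean2,sd2 non-faller count, mean, SD
#' @return an object of class \code{"group_summary"}
#' @export
group_summary <- function(n1, mean1, sd1, n2, mean2, sd2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  structure(list(n1 = n1, mean1 = mean1, sd1 = sd1,
                 n2 = n2, mean2 = mean2, sd2 = sd2),
            class = "group_summary")
}

#' Welch two-sample t-test from group summaries
#'
#' Unequal-variance t statistic
#' \code{t = (mean1 - mean2) / sqrt(sd1^2/n1 + sd2^2/n2)} with
#' Welch-Satterthwaite degrees of freedom and a two-tailed p-value.
#'
#' @param gs a \code{\link{group_summary}}
#' @return list with \code{statistic}, \code{df}, \code{p}
#' @export
welch_t <- function(gs) {
  stopifnot(inherits(gs, "group_summary"))
  if (gs$sd1 == 0 && gs$sd2 == 0) stop("both group SDs are zero")
  v1 <- gs$sd1^2 / gs$n1
  v2 <- gs$sd2^2 / gs$n2
  tstat <- (gs$mean1 - gs$mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (gs$n1 - 1) + v2^2 / (gs$n2 - 1))
  list(statistic = tstat, df = df,
       p = 2 * stats::pt(-abs(tstat), df))
}

#' Pooled-SD Cohen's d from group summaries
#'
#' Effect-size magnitude \code{|mean1 - mean2| / s_pooled} with
#' \code{s_pooled = sqrt(((n1-1) sd1^2 + (n2-1) sd2^2) / (n1+n2-2))}.
#' Reported as a magnitude, and invariant to rescaling all means and SDs by
#' a common positive factor.
#'
#' @param gs a \code{\link{group_summary}}
#' @return the effect size d (>= 0)
#' @export
cohens_d <- function(gs) {
  stopifnot(inherits(gs, "group_summary"))
  sp <- sqrt(((gs$n1 - 1) * gs$sd1^2 + (gs$n2 - 1) * gs$sd2^2) /
               (gs$n1 + gs$n2 - 2))
  if (sp == 0) stop("pooled SD is zero")
  abs(gs$mean1 - gs$mean2) / sp
}

#' Yates-corrected chi-square and Cramer's V for a 2x2 table
#'
#' Chi-square with continuity correction (floored at zero when the corrected
#' deviation is negative) and the Cramer's V effect size
#' \code{sqrt(chi2 / (n * min(r-1, c-1)))}.
#'
#' @param table2x2 2x2 matrix of non-negative integer counts with positive
#'   margins (rows = groups, columns = outcome present/absent)
#' @return list with \code{statistic}, \code{df}, \code{p}, \code{cramers_v}
#' @export
chi2_cramers_v <- function(table2x2) {
  table2x2 <- as.matrix(table2x2)
  stopifnot(all(dim(table2x2) == 2L), all(table2x2 >= 0))
  if (any(rowSums(table2x2) == 0) || any(colSums(table2x2) == 0))
    stop("zero margin")
  ct <- suppressWarnings(stats::chisq.test(table2x2, correct = TRUE))
  n <- sum(table2x2)
  v <- sqrt(unname(ct$statistic) / n)   # min(r-1, c-1) = 1 for a 2x2 table
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, cramers_v = v)
}

#' Pairwise Pearson correlation matrix with p-values and collinearity flags
#'
#' Pairwise-complete Pearson correlations across the columns of a feature
#' table, with two-sided p-values from the t distribution, magnitude labels
#' at the 0.10/0.30/0.50 thresholds (small/moderate/large) and a
#' \code{|r| > 0.50} high-collinearity flag.
#'
#' @param x a \code{\link{feature_table}}
#' @param min_pairs minimum complete pairs required per variable pair
#'   (default 3)
#' @return list with matrices \code{r}, \code{p}, \code{n} (complete pairs),
#'   character matrix \code{label}, logical matrix \code{collinear}
#' @export
pearson_matrix <- function(x, min_pairs = 3) {
  stopifnot(inherits(x, "feature_table"))
  vals <- x$values
  p <- ncol(vals)
  obs <- !x$mask
  npair <- crossprod(obs)
  if (any(npair < min_pairs))
    stop("fewer than ", min_pairs, " complete pairs for some variable pair")
  r <- stats::cor(vals, use = "pairwise.complete.obs")
  tstat <- r * sqrt((npair - 2) / pmax(1 - r^2, .Machine$double.eps))
  pv <- 2 * stats::pt(-abs(tstat), npair - 2)
  diag(pv) <- 0
  ar <- abs(r)
  label <- matrix(as.character(cut(ar, c(-Inf, 0.10, 0.30, 0.50, Inf),
                                   labels = c("negligible", "small",
                                              "moderate", "large"),
                                   right = FALSE)),
                  p, p, dimnames = dimnames(r))
  diag(label) <- "large"
  list(r = r, p = pv, n = npair, label = label, collinear = ar > 0.50)
}

#' Bartlett's test of sphericity
#'
#' Tests whether a correlation matrix differs from the identity (redundancy
#' in the data): \code{chi2 = -(n - 1 - (2p + 5)/6) log det(R)} on
#' \code{p(p-1)/2} degrees of freedom, upper tail. A p-value below 0.05 is
#' read as redundancy present.
#'
#' @param r correlation matrix (positive definite)
#' @param n number of participants (must exceed the number of variables)
#' @return list with \code{statistic}, \code{df}, \code{p},
#'   \code{redundant} (logical, p < 0.05)
#' @export
bartlett_sphericity <- function(r, n) {
  r <- as.matrix(r)
  p <- ncol(r)
  stopifnot(nrow(r) == p, n > p)
  d <- det(r)
  if (d <= 0) stop("singular correlation matrix")
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * log(d)
  df <- p * (p - 1) / 2
  pv <- stats::pchisq(chi2, df, lower.tail = FALSE)
  list(statistic = chi2, df = df, p = pv, redundant = pv < 0.05)
}

#' Univariate screen of a feature table
#'
#' Per-variable two-group comparison: Welch t and pooled-SD Cohen's d for
#' continuous variables (computed from the observed cells), Yates chi-square
#' and Cramer's V for binary variables. Flags mirror p <= 0.10 / 0.05 /
#' 0.001; no multiple-testing correction is applied.
#'
#' @param x a \code{\link{feature_table}}
#' @return data frame with columns \code{variable}, \code{domain},
#'   \code{test}, \code{statistic}, \code{df}, \code{p}, \code{effect_size},
#'   \code{effect_family}, \code{flag}
#' @export
univariate_screen <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  fal <- x$group == "faller"
  rows <- lapply(seq_len(ncol(x$values)), function(j) {
    v <- x$values[, j]
    kind <- x$variables$kind[j]
    if (kind == "continuous") {
      v1 <- v[fal & !is.na(v)]
      v2 <- v[!fal & !is.na(v)]
      gs <- group_summary(length(v1), mean(v1), stats::sd(v1),
                          length(v2), mean(v2), stats::sd(v2))
      wt <- welch_t(gs)
      data.frame(variable = x$variables$name[j],
                 domain = x$variables$domain[j], test = "welch_t",
                 statistic = wt$statistic, df = wt$df, p = wt$p,
                 effect_size = cohens_d(gs), effect_family = "cohens_d",
                 stringsAsFactors = FALSE)
    } else {
      tab <- table(factor(fal[!is.na(v)], levels = c(TRUE, FALSE)),
                   factor(v[!is.na(v)] == 1, levels = c(TRUE, FALSE)))
      cv <- chi2_cramers_v(tab)
      data.frame(variable = x$variables$name[j],
                 domain = x$variables$domain[j], test = "chi2_yates",
                 statistic = cv$statistic, df = cv$df, p = cv$p,
                 effect_size = cv$cramers_v, effect_family = "cramers_v",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$flag <- cut(out$p, c(-Inf, 0.001, 0.05, 0.10, Inf),
                  labels = c("***", "**", "*", ""))
  out
}
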