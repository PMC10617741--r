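# Probabilistic PCA (latent Gaussian factor model x = mu + W z + eps,
# z ~ N(0, I_q), eps ~ N(0, sigma2 I)) fitted by expectation-maximization
# with missing entries handled as latent data; conditional expectations
# impute the missing cells.

obs_loglik <- function(Xs, mu, W, sigma2) {
  q <- ncol(W)
  ll <- 0
  for (i in seq_len(nrow(Xs))) {
    o <- which(!is.na(Xs[i, ]))
    Wo <- W[o, , drop = FALSE]
    e <- Xs[i, o] - mu[o]
    M <- sigma2 * diag(q) + crossprod(Wo)
    cM <- chol(M)
    logdet <- (length(o) - q) * log(sigma2) + 2 * sum(log(diag(cM)))
    wte <- crossprod(Wo, e)
    quad <- (sum(e^2) - sum(backsolve(cM, wte, transpose = TRUE)^2)) / sigma2
    ll <- ll - 0.5 * (length(o) * log(2 * pi) + logdet + quad)
  }
  ll
}

#' Fit probabilistic PCA by EM on a table with missing cells
#'
#' Columns are standardized (observed mean 0, SD 1) before fitting and the
#' model stores the centers/scales so imputations are returned on the
#' original scale. The EM treats the latent factors and the missing cells as
#' latent data (conditional-maximization steps for the mean, loadings and
#' noise variance), so the observed-data log-likelihood is non-decreasing
#' across iterations; the per-iteration trace is stored. Convergence is a
#' relative log-likelihood change below \code{tol}.
#'
#' @param x a \code{\link{feature_table}} (missing cells allowed; every row
#'   and column must have at least one observed cell)
#' @param q latent dimension (default 5; must be below \code{min(n, p)})
#' @param tol relative log-likelihood convergence tolerance (default 1e-6)
#' @param max_iter maximum EM iterations (default 1000)
#' @param seed seed for the random loading initialization
#' @return object of class \code{"ppca_model"} with \code{W} (p x q),
#'   \code{mu}, \code{sigma2}, \code{center}, \code{scale}, \code{loglik}
#'   (trace), \code{converged}, \code{iterations}, \code{q},
#'   \code{variable_names}
#' @export
fit_ppca <- function(x, q = 5, tol = 1e-6, max_iter = 1000, seed = 1L) {
  stopifnot(inherits(x, "feature_table"))
  X <- x$values
  n <- nrow(X); p <- ncol(X)
  if (q < 1 || q >= min(n, p)) stop("q must satisfy 1 <= q < min(n, p)")
  if (any(rowSums(!x$mask) == 0)) stop("row with no observed cells")
  if (any(colSums(!x$mask) == 0)) stop("column with no observed cells")
  center <- colMeans(X, na.rm = TRUE)
  scl <- apply(X, 2, stats::sd, na.rm = TRUE)
  if (any(is.na(scl)) || any(scl == 0))
    stop("constant or single-valued column; cannot standardize")
  Xs <- sweep(sweep(X, 2, center, "-"), 2, scl, "/")
  set.seed(seed)
  W <- matrix(stats::rnorm(p * q, sd = 0.1), p, q)
  mu <- rep(0, p)
  sigma2 <- 1
  obs_idx <- lapply(seq_len(n), function(i) which(!is.na(Xs[i, ])))
  ll_trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # E-step
    m_list <- vector("list", n)
    Szz_list <- vector("list", n)
    for (i in seq_len(n)) {
      o <- obs_idx[[i]]
      Wo <- W[o, , drop = FALSE]
      M <- sigma2 * diag(q) + crossprod(Wo)
      Minv <- chol2inv(chol(M))
      m_i <- Minv %*% crossprod(Wo, Xs[i, o] - mu[o])
      m_list[[i]] <- m_i
      Szz_list[[i]] <- sigma2 * Minv + tcrossprod(m_i)
    }
    # CM-step 1: mean (loadings fixed at current value)
    mu_new <- mu
    for (j in seq_len(p)) {
      tot <- 0
      for (i in seq_len(n)) {
        if (j %in% obs_idx[[i]]) {
          tot <- tot + (Xs[i, j] - sum(W[j, ] * m_list[[i]]))
        } else tot <- tot + mu[j]
      }
      mu_new[j] <- tot / n
    }
    # CM-step 2: loadings
    Szz_sum <- Reduce(`+`, Szz_list)
    W_new <- W
    for (j in seq_len(p)) {
      a <- rep(0, q)
      for (i in seq_len(n)) {
        if (j %in% obs_idx[[i]]) {
          a <- a + (Xs[i, j] - mu_new[j]) * as.numeric(m_list[[i]])
        } else {
          a <- a + (mu[j] - mu_new[j]) * as.numeric(m_list[[i]]) +
            as.numeric(Szz_list[[i]] %*% W[j, ])
        }
      }
      W_new[j, ] <- solve(Szz_sum, a)
    }
    # CM-step 3: noise variance
    tot <- 0
    for (i in seq_len(n)) {
      o <- obs_idx[[i]]
      m_i <- as.numeric(m_list[[i]])
      Szz <- Szz_list[[i]]
      for (j in seq_len(p)) {
        wj <- W_new[j, ]
        if (j %in% o) {
          e <- Xs[i, j] - mu_new[j]
          tot <- tot + e^2 - 2 * sum(wj * m_i) * e +
            as.numeric(wj %*% Szz %*% wj)
        } else {
          dlt <- mu[j] - mu_new[j]
          bj <- W[j, ] - wj
          tot <- tot + dlt^2 + 2 * dlt * sum(bj * m_i) +
            as.numeric(bj %*% Szz %*% bj) + sigma2
        }
      }
    }
    sigma2_new <- max(tot / (n * p), 1e-12)
    mu <- mu_new; W <- W_new; sigma2 <- sigma2_new
    ll <- obs_loglik(Xs, mu, W, sigma2)
    ll_trace <- c(ll_trace, ll)
    if (iter > 1) {
      if (abs(ll - ll_trace[iter - 1]) < tol * abs(ll_trace[iter - 1])) {
        converged <- TRUE
        break
      }
    }
  }
  if (!converged)
    warning("PPCA EM did not converge in ", max_iter, " iterations")
  structure(list(W = W, mu = mu, sigma2 = sigma2,
                 center = center, scale = scl, loglik = ll_trace,
                 converged = converged, iterations = length(ll_trace),
                 q = q, seed = seed, variable_names = colnames(X)),
            class = "ppca_model")
}

#' @export
print.ppca_model <- function(x, ...) {
  cat(sprintf("PPCA model: %d variables, q = %d, sigma2 = %.4g\n",
              length(x$mu), x$q, x$sigma2))
  cat(sprintf("EM %s after %d iterations (final log-likelihood %.3f)\n",
              if (x$converged) "converged" else "did NOT converge",
              x$iterations, utils::tail(x$loglik, 1)))
  invisible(x)
}

#' Impute missing cells with a fitted PPCA model
#'
#' Missing cells are replaced by their conditional expectations under the
#' model (the posterior mean of the latent factors given the row's observed
#' cells, pushed through the loadings and de-standardized); observed cells
#' are untouched and the mask is cleared. The original mask is retained as
#' the \code{"imputed"} attribute.
#'
#' @param x the \code{\link{feature_table}} to complete
#' @param model a \code{\link{fit_ppca}} result fitted to the same columns
#' @return a complete \code{feature_table}
#' @export
impute_missing <- function(x, model) {
  stopifnot(inherits(x, "feature_table"), inherits(model, "ppca_model"))
  if (!identical(colnames(x$values), model$variable_names))
    stop("column mismatch between table and model")
  if (!any(x$mask)) {
    attr(x, "imputed") <- x$mask
    return(x)
  }
  Xs <- sweep(sweep(x$values, 2, model$center, "-"), 2, model$scale, "/")
  q <- model$q
  out <- Xs
  for (i in seq_len(nrow(Xs))) {
    mi <- which(is.na(Xs[i, ]))
    if (!length(mi)) next
    o <- which(!is.na(Xs[i, ]))
    Wo <- model$W[o, , drop = FALSE]
    M <- model$sigma2 * diag(q) + crossprod(Wo)
    z <- solve(M, crossprod(Wo, Xs[i, o] - model$mu[o]))
    out[i, mi] <- model$mu[mi] + model$W[mi, , drop = FALSE] %*% z
  }
  filled <- sweep(sweep(out, 2, model$scale, "*"), 2, model$center, "+")
  filled[!x$mask] <- x$values[!x$mask]   # observed cells bitwise-preserved
  ft <- feature_table(filled, as.character(x$group), x$variables,
                      x$participant_ids)
  attr(ft, "imputed") <- x$mask
  ft
}
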