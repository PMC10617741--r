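# Jenks natural-breaks selection of "important" variables on importance
# scores, and union refinement of the two engines' selections.

#' Fisher-Jenks natural breaks
#'
#' Exact dynamic-programming optimum of the 1-D classification problem:
#' partition the sorted values into \code{n_classes} contiguous classes
#' minimizing the total within-class sum of squared deviations. Returns the
#' class boundaries (the maximum of each class but the last), so for the
#' default two classes a single break value separates the lower from the
#' upper class.
#'
#' @param scores numeric vector with at least \code{n_classes} distinct
#'   values
#' @param n_classes number of classes (default 2)
#' @return numeric vector of \code{n_classes - 1} break values
#' @export
jenks_breaks <- function(scores, n_classes = 2) {
  x <- sort(as.numeric(scores))
  n <- length(x)
  if (length(unique(x)) < n_classes)
    stop("fewer distinct values than classes")
  # prefix sums for O(1) within-class SSD
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  ssd <- function(i, j) { # inclusive 1-based range
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  # dp[k, j]: minimal SSD of splitting x[1..j] into k classes
  dp <- matrix(Inf, n_classes, n)
  back <- matrix(0L, n_classes, n)
  for (j in seq_len(n)) dp[1, j] <- ssd(1, j)
  if (n_classes > 1) {
    for (k in 2:n_classes) {
      for (j in k:n) {
        for (m in (k - 1):(j - 1)) {
          cand <- dp[k - 1, m] + ssd(m + 1, j)
          if (cand < dp[k, j]) { dp[k, j] <- cand; back[k, j] <- m }
        }
      }
    }
  }
  bounds <- integer(0)
  j <- n
  for (k in n_classes:2) {
    m <- back[k, j]
    bounds <- c(m, bounds)
    j <- m
  }
  x[bounds]
}

#' Select important variables above the Jenks break
#'
#' Two-class Jenks natural breaks on the importance scores; variables
#' strictly above the break (the upper class) are selected as important.
#' Ties at the break value fall below (conservative). A manually supplied
#' \code{override} cutoff replaces the Jenks break, realizing the
#' subjective-validation step of a scree-plot elbow; any override used is
#' recorded in the result.
#'
#' @param importance named numeric vector of importance scores (one engine)
#' @param engine label for the engine (\code{"rf"} or \code{"lovo"})
#' @param override optional manual cutoff; selection is strictly above it
#' @return object of class \code{"selection_result"} with \code{scores},
#'   \code{break_value}, \code{selected} (character), \code{engine},
#'   \code{override}
#' @export
select_above_break <- function(importance, engine = "engine", override = NULL) {
  if (is.null(names(importance)) || anyNA(importance))
    stop("importance must be a fully named, complete score vector")
  if (is.null(override)) {
    brk <- jenks_breaks(importance, 2)[1L]
  } else brk <- override
  sel <- names(importance)[importance > brk]
  if (!length(sel) && length(unique(importance)) >= 2 && is.null(override))
    stop("degenerate selection: no scores above the break")
  structure(list(scores = sort(importance, decreasing = TRUE),
                 break_value = brk, selected = sel, engine = engine,
                 override = !is.null(override)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("%s selection: %d of %d variables above break %.4g%s\n",
              x$engine, length(x$selected), length(x$scores), x$break_value,
              if (x$override) " (manual override)" else ""))
  print(x$selected)
  invisible(x)
}

#' Union of the important variables from two engines
#'
#' De-duplicated union of two selections over the same variable universe,
#' with per-variable provenance (selected by the random forest only, by the
#' LOVO PLSCA only, or by both). Commutative and monotone in both
#' arguments.
#'
#' @param a,b \code{\link{select_above_break}} results over the same
#'   variables
#' @return data frame with columns \code{variable}, \code{provenance}
#' @export
union_important <- function(a, b) {
  stopifnot(inherits(a, "selection_result"), inherits(b, "selection_result"))
  if (!setequal(names(a$scores), names(b$scores)))
    stop("selections are over different variable universes")
  universe <- names(a$scores)
  keep <- universe[universe %in% union(a$selected, b$selected)]
  prov <- ifelse(keep %in% a$selected & keep %in% b$selected, "both",
                 ifelse(keep %in% a$selected, paste0(a$engine, "_only"),
                        paste0(b$engine, "_only")))
  data.frame(variable = keep, provenance = prov, stringsAsFactors = FALSE)
}
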