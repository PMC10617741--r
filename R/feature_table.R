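DOMAINS <- c("balance", "gait", "clinical", "strength", "body_composition")
GROUP_LEVELS <- c("non_faller", "faller")

#' Participant-by-variable feature table
#'
#' The central container of the package: a numeric matrix of participants by
#' named assessment variables, a two-level faller/non-faller group factor, a
#' variable metadata table assigning each column to one of the five analysis
#' domains (balance, gait, clinical, strength, body_composition), and an
#' explicit missingness mask. Fallers are always coded 1 and non-fallers 0
#' wherever a numeric group coding is needed.
#'
#' @param values numeric matrix (participants x variables); \code{NA} marks a
#'   missing cell. Column names must match \code{variables$name}.
#' @param group character or factor of length \code{nrow(values)} with levels
#'   \code{"faller"} and \code{"non_faller"} (both must occur).
#' @param variables data frame with columns \code{name}, \code{domain},
#'   \code{kind} (\code{"continuous"} or \code{"binary"}) and \code{units}.
#' @param participant_ids optional character vector of row identifiers.
#' @return an object of class \code{"feature_table"} with elements
#'   \code{values}, \code{mask} (logical, \code{TRUE} = missing),
#'   \code{group}, \code{variables}, \code{participant_ids}.
#' @export
feature_table <- function(values, group, variables, participant_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  p <- ncol(values)
  if (is.null(participant_ids)) {
    participant_ids <- if (!is.null(rownames(values))) rownames(values) else
      sprintf("P%03d", seq_len(n))
  }
  if (length(participant_ids) != n)
    stop("participant_ids length must equal the number of rows")
  if (anyDuplicated(participant_ids))
    stop("participant_ids must be unique")
  variables <- as.data.frame(variables, stringsAsFactors = FALSE)
  req <- c("name", "domain", "kind")
  if (!all(req %in% names(variables)))
    stop("variables must have columns name, domain, kind")
  if (is.null(variables$units)) variables$units <- ""
  if (nrow(variables) != p)
    stop("variables must describe exactly the matrix columns")
  if (anyDuplicated(variables$name))
    stop("duplicated variable names")
  bad <- setdiff(unique(variables$domain), DOMAINS)
  if (length(bad))
    stop("unknown domain(s): ", paste(bad, collapse = ", "))
  if (!all(variables$kind %in% c("continuous", "binary")))
    stop("variable kind must be 'continuous' or 'binary'")
  colnames(values) <- variables$name
  rownames(values) <- participant_ids
  group <- as.character(group)
  if (length(group) != n) stop("group length must equal the number of rows")
  if (!all(group %in% GROUP_LEVELS))
    stop("group labels must be 'faller' or 'non_faller'")
  if (length(unique(group)) != 2L)
    stop("both group levels must be present")
  if (min(table(group)) < 2L)
    stop("fewer than 2 participants in one group")
  group <- factor(group, levels = GROUP_LEVELS)
  mask <- is.na(values)
  structure(
    list(values = values, mask = mask, group = group,
         variables = variables, participant_ids = participant_ids),
    class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  tab <- table(x$group)
  cat(sprintf("feature_table: %d participants (fallers = %d, non-fallers = %d) x %d variables\n",
              nrow(x$values), tab[["faller"]], tab[["non_faller"]], ncol(x$values)))
  dom <- table(factor(x$variables$domain, levels = DOMAINS))
  cat("domains:", paste(sprintf("%s = %d", names(dom), dom), collapse = ", "), "\n")
  nm <- sum(x$mask)
  cat(sprintf("missing cells: %d (%.1f%%)\n", nm, 100 * nm / length(x$mask)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Numeric faller indicator (faller = 1, non-faller = 0)
#' @param x a feature_table
#' @return integer vector of 0/1
#' @export
group_indicator <- function(x) as.integer(x$group == "faller")

#' Subset the columns of a feature table
#' @param x a feature_table
#' @param vars character vector of variable names to keep (order preserved)
#' @return a feature_table with the selected columns
#' @export
select_variables <- function(x, vars) {
  stopifnot(inherits(x, "feature_table"))
  miss <- setdiff(vars, x$variables$name)
  if (length(miss)) stop("unknown variable(s): ", paste(miss, collapse = ", "))
  idx <- match(vars, x$variables$name)
  feature_table(x$values[, idx, drop = FALSE], as.character(x$group),
                x$variables[idx, , drop = FALSE], x$participant_ids)
}

#' Read a feature table from a data CSV plus metadata sidecar
#'
#' The data file is plain RFC 4180 CSV with a header row, one identifier
#' column, the group column and one numeric column per variable; missing
#' cells are empty strings. The sidecar CSV carries the domain tags with
#' columns \code{name,domain,kind,units}.
#'
#' @param path path to the data CSV
#' @param meta_path path to the metadata sidecar CSV
#' @param group_column name of the group column (default \code{"group"})
#' @param id_column name of the identifier column (default
#'   \code{"participant_id"}; absent means row numbers are used)
#' @return a \code{feature_table}
#' @export
read_feature_table <- function(path, meta_path, group_column = "group",
                               id_column = "participant_id") {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!group_column %in% names(raw)) stop("missing group column: ", group_column)
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  ids <- if (id_column %in% names(raw)) raw[[id_column]] else
    sprintf("P%03d", seq_len(nrow(raw)))
  group <- raw[[group_column]]
  if (any(group == "" | is.na(group))) stop("missing group labels")
  varcols <- setdiff(names(raw), c(group_column, id_column))
  if (anyDuplicated(varcols)) stop("duplicated variable names in CSV header")
  vals <- sapply(varcols, function(v) {
    cell <- raw[[v]]
    out <- rep(NA_real_, length(cell))
    obs <- !(cell == "" | is.na(cell))
    num <- suppressWarnings(as.numeric(cell[obs]))
    if (anyNA(num))
      stop("non-numeric cell(s) in column '", v, "'")
    out[obs] <- num
    out
  })
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(NULL, varcols))
  meta <- meta[match(varcols, meta$name), , drop = FALSE]
  if (anyNA(meta$name)) stop("metadata sidecar does not cover all variables")
  feature_table(vals, group, meta, ids)
}

#' Write a feature table to a data CSV plus metadata sidecar
#'
#' Inverse of \code{\link{read_feature_table}}: missing cells become empty
#' strings, column order is deterministic, and a round trip preserves values,
#' mask and group labels exactly (values are printed at full precision).
#'
#' @param x a feature_table
#' @param path output data CSV path
#' @param meta_path output metadata CSV path
#' @return invisibly, the two paths
#' @export
write_feature_table <- function(x, path, meta_path) {
  stopifnot(inherits(x, "feature_table"))
  chr <- apply(x$values, 2, function(col) {
    out <- sprintf("%.17g", col)
    out[is.na(col)] <- ""
    out
  })
  df <- data.frame(participant_id = x$participant_ids,
                   group = as.character(x$group),
                   chr, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  utils::write.csv(x$variables[, c("name", "domain", "kind", "units")],
                   meta_path, row.names = FALSE, quote = TRUE)
  invisible(c(path, meta_path))
}

#' Partition a feature table into single-domain sub-tables
#'
#' Splits the columns by their domain tag into up to five "data packages"
#' sharing the parent's rows and groups. Column order within each domain is
#' preserved, and the union of the partition's columns is exactly the parent's
#' columns.
#'
#' @param x a feature_table
#' @return named list of feature_table objects, one per non-empty domain
#' @export
partition_domains <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  if (any(is.na(x$variables$domain) | x$variables$domain == ""))
    stop("untagged variable(s)")
  doms <- intersect(DOMAINS, unique(x$variables$domain))
  out <- lapply(doms, function(d)
    select_variables(x, x$variables$name[x$variables$domain == d]))
  names(out) <- doms
  out
}

#' Standardize each column to mean 0, sample SD 1
#'
#' Standardization is computed over the observed (non-missing) entries of
#' each column; the missing mask is preserved. Required before any PLSCA
#' computation so that cross-products are correlations.
#'
#' @param x a feature_table
#' @return a feature_table with standardized columns
#' @export
zscore_columns <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  vals <- x$values
  for (j in seq_len(ncol(vals))) {
    v <- vals[, j]
    obs <- !is.na(v)
    if (sum(obs) < 2L)
      stop("column '", colnames(vals)[j], "' has fewer than 2 observed values")
    s <- stats::sd(v[obs])
    if (s == 0)
      stop("constant column: ", colnames(vals)[j])
    vals[, j] <- (v - mean(v[obs])) / s
  }
  feature_table(vals, as.character(x$group), x$variables, x$participant_ids)
}
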