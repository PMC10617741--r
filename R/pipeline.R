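# Orchestration of the two-stage strategy: five single-domain analyses
# (univariate screen -> dual importance ranking -> Jenks selection -> union)
# feeding a multi-domain refinement with PPCA imputation, three classifiers,
# stepwise refinement and the between-domain inertia table.

#' Pipeline run configuration
#'
#' Engine parameters for a full pipeline run. Every stochastic stage derives
#' its seed from \code{seed}, so a run is a pure function of (input table,
#' config).
#'
#' @param n_trees random-forest trees (default 500)
#' @param q PPCA latent dimension (default 5)
#' @param permutations permutations for between-domain inertia p-values
#'   (default 999)
#' @param seed master seed (default 1)
#' @param override optional named list of manual Jenks cutoffs per engine
#'   (\code{rf}, \code{lovo})
#' @return an object of class \code{"run_config"}
#' @export
run_config <- function(n_trees = 500, q = 5, permutations = 999, seed = 1L,
                       override = list()) {
  structure(list(n_trees = n_trees, q = q, permutations = permutations,
                 seed = as.integer(seed), override = override),
            class = "run_config")
}

complete_table <- function(x, cfg) {
  if (!any(x$mask)) return(x)
  q <- min(cfg$q, min(dim(x$values)) - 1L)
  model <- fit_ppca(x, q = q, seed = cfg$seed + 7L)
  impute_missing(x, model)
}

importance_stage <- function(tbl, cfg) {
  forest <- fit_forest(tbl, n_trees = cfg$n_trees, seed = cfg$seed + 11L)
  gz <- matrix(scale(group_indicator(tbl)), ncol = 1,
               dimnames = list(NULL, "faller"))
  ztbl <- zscore_columns(tbl)
  lovo <- lovo_importance(gz, ztbl$values)
  rf_sel <- select_above_break(forest$importance, engine = "rf",
                               override = cfg$override$rf)
  lovo_sel <- select_above_break(lovo$importance, engine = "lovo",
                                 override = cfg$override$lovo)
  list(forest = forest, lovo = lovo, rf_sel = rf_sel, lovo_sel = lovo_sel,
       union = union_important(rf_sel, lovo_sel))
}

#' Single-domain analysis
#'
#' Runs one data package through the consistent single-domain strategy:
#' univariate screen, random-forest and LOVO-PLSCA importance, Jenks
#' selections and their union, then baseline (all variables) and refined
#' (union variables) classifiers with ROC evaluation. Missing cells are
#' PPCA-imputed first. A baseline logistic model is only fitted when the
#' variable count is small enough relative to n for a stable ML fit.
#'
#' @param domain_table a single-domain \code{\link{feature_table}}
#' @param cfg a \code{\link{run_config}}
#' @return object of class \code{"domain_report"}; element \code{important}
#'   is the domain's refined variable list carried into the multi-domain
#'   stage
#' @export
run_single_domain <- function(domain_table, cfg = run_config()) {
  stopifnot(inherits(domain_table, "feature_table"))
  domain <- unique(domain_table$variables$domain)
  tbl <- complete_table(domain_table, cfg)
  screen <- univariate_screen(tbl)
  imp <- importance_stage(tbl, cfg)
  important <- imp$union$variable
  n <- nrow(tbl$values); p <- ncol(tbl$values)
  models <- list(
    baseline_plsca = plsca_classifier(tbl, tbl$variables$name),
    baseline_rf = list(roc = roc_report(as.numeric(imp$forest$votes),
                                        tbl$group),
                       forest = imp$forest),
    refined_plsca = if (length(important) >= 1)
      plsca_classifier(tbl, important),
    refined_rf = if (length(important) >= 1)
      rf_classifier(tbl, important, n_trees = cfg$n_trees,
                    seed = cfg$seed + 13L),
    refined_logistic = if (length(important) >= 1 && length(important) < n - 1)
      logistic_fit(tbl, important))
  if (p < n - 1) models$baseline_logistic <- logistic_fit(tbl,
                                                          tbl$variables$name)
  structure(list(domain = domain, table = tbl, screen = screen,
                 rf_importance = imp$forest$importance,
                 lovo_importance = imp$lovo$importance,
                 rf_selection = imp$rf_sel, lovo_selection = imp$lovo_sel,
                 union = imp$union, important = important, models = models,
                 config = cfg),
            class = "domain_report")
}

#' @export
print.domain_report <- function(x, ...) {
  cat(sprintf("single-domain report [%s]: %d variables screened, %d selected as important\n",
              paste(x$domain, collapse = "/"), nrow(x$screen),
              length(x$important)))
  aucs <- vapply(Filter(Negate(is.null), x$models),
                 function(m) m$roc$auc, numeric(1))
  print(round(aucs, 3))
  invisible(x)
}

#' Multi-domain analysis
#'
#' Aggregates the important variables of the single-domain reports into the
#' multi-domain data package, PPCA-imputes the missing cells, repeats the
#' univariate screen and dual importance ranking, refines by the Jenks
#' union, and fits the three classifiers on the refined set: PLSCA (with
#' permutation inertia p-value), random forest (OOB), and logistic
#' regression with LOOCV plus backward AIC- and BIC-refined models
#' (reporting whether the two criteria agree). Also computes the pairwise
#' between-domain shared-information table (measured inertia, normalized
#' inertia, permutation p) over the domain blocks of the multi-domain
#' package.
#'
#' @param x the parent \code{\link{feature_table}} holding all domains
#' @param single_reports list of \code{\link{run_single_domain}} results
#' @param cfg a \code{\link{run_config}}
#' @return an object of class \code{"multi_domain_report"}
#' @export
run_multi_domain <- function(x, single_reports, cfg = run_config()) {
  stopifnot(inherits(x, "feature_table"))
  vars <- unlist(lapply(single_reports, `[[`, "important"))
  origin <- rep(vapply(single_reports, function(r) r$domain[1], ""),
                vapply(single_reports, function(r) length(r$important), 0L))
  if (anyDuplicated(vars)) stop("a variable appears in two domain reports")
  package_tbl <- select_variables(x, vars)
  tbl <- complete_table(package_tbl, cfg)
  screen <- univariate_screen(tbl)
  imp <- importance_stage(tbl, cfg)
  refined <- imp$union$variable
  n <- nrow(tbl$values)
  gz <- matrix(scale(group_indicator(tbl)), ncol = 1,
               dimnames = list(NULL, "faller"))
  ztbl <- zscore_columns(tbl)
  plsca_m <- plsca_classifier(tbl, refined)
  plsca_p <- permutation_pvalue(gz, ztbl$values[, refined, drop = FALSE],
                                b = cfg$permutations, seed = cfg$seed + 17L)
  rf_m <- rf_classifier(tbl, refined, n_trees = cfg$n_trees,
                        seed = cfg$seed + 19L)
  logi <- if (length(refined) < n - 1) logistic_fit(tbl, refined)
  logi_roc <- if (!is.null(logi)) roc_report(logi$fitted, tbl$group)
  logi_cv <- if (!is.null(logi)) loocv_accuracy(tbl, refined)
  aic_m <- if (!is.null(logi)) stepwise_backward(logi, "AIC")
  bic_m <- if (!is.null(logi)) stepwise_backward(logi, "BIC")
  agree <- if (!is.null(logi))
    setequal(aic_m$predictors, bic_m$predictors) else NA
  refined_roc <- if (!is.null(aic_m) && length(aic_m$predictors))
    roc_report(aic_m$fitted, tbl$group)
  refined_cv <- if (!is.null(aic_m) && length(aic_m$predictors))
    loocv_accuracy(tbl, aic_m$predictors)
  inertia_tbl <- between_domain_table(ztbl, cfg)
  structure(list(variables = vars, variable_origin = origin, table = tbl,
                 screen = screen,
                 rf_importance = imp$forest$importance,
                 lovo_importance = imp$lovo$importance,
                 rf_selection = imp$rf_sel, lovo_selection = imp$lovo_sel,
                 union = imp$union, refined = refined,
                 models = list(
                   plsca = c(plsca_m, list(permutation_p = plsca_p)),
                   rf = rf_m,
                   logistic = if (!is.null(logi))
                     list(fit = logi, roc = logi_roc, loocv = logi_cv),
                   refined_logistic = if (!is.null(aic_m))
                     list(fit = aic_m, roc = refined_roc, loocv = refined_cv,
                          bic_fit = bic_m, criteria_agree = agree)),
                 between_domain = inertia_tbl, config = cfg),
            class = "multi_domain_report")
}

between_domain_table <- function(ztbl, cfg) {
  doms <- intersect(DOMAINS, unique(ztbl$variables$domain))
  k <- length(doms)
  measured <- normalized <- pval <- matrix(NA_real_, k, k,
                                           dimnames = list(doms, doms))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i >= j) next
    A <- ztbl$values[, ztbl$variables$domain == doms[i], drop = FALSE]
    B <- ztbl$values[, ztbl$variables$domain == doms[j], drop = FALSE]
    bd <- between_domain_inertia(A, B)
    measured[i, j] <- measured[j, i] <- bd$measured
    normalized[i, j] <- normalized[j, i] <- bd$normalized
    pv <- permutation_pvalue(A, B, b = cfg$permutations,
                             seed = cfg$seed + 23L + i * 31L + j)
    pval[i, j] <- pval[j, i] <- pv
  }
  list(measured = measured, normalized = normalized, p = pval)
}

#' @export
print.multi_domain_report <- function(x, ...) {
  cat(sprintf("multi-domain report: package of %d variables, refined set of %d\n",
              length(x$variables), length(x$refined)))
  cat("refined variables:\n"); print(x$refined)
  cat(sprintf("PLSCA AUC %.2f (inertia %.2f, permutation p %.3g); RF AUC %.2f\n",
              x$models$plsca$roc$auc, x$models$plsca$inertia,
              x$models$plsca$permutation_p, x$models$rf$roc$auc))
  if (!is.null(x$models$logistic))
    cat(sprintf("logistic AUC %.2f (LOOCV %.0f%%); refined logistic %s (criteria agree: %s)\n",
                x$models$logistic$roc$auc,
                100 * x$models$logistic$loocv$accuracy,
                if (!is.null(x$models$refined_logistic$roc))
                  sprintf("AUC %.2f (LOOCV %.0f%%)",
                          x$models$refined_logistic$roc$auc,
                          100 * x$models$refined_logistic$loocv$accuracy)
                else "intercept-only",
                x$models$refined_logistic$criteria_agree))
  cat("normalized between-domain inertia:\n")
  print(round(x$between_domain$normalized, 2))
  invisible(x)
}

#' Run the full two-stage pipeline
#'
#' Partitions the table into its domains, runs every single-domain analysis
#' and then the multi-domain refinement.
#'
#' @param x a \code{\link{feature_table}} covering the assessment domains
#' @param cfg a \code{\link{run_config}}
#' @return list with \code{singles} (named domain reports) and \code{multi}
#'   (the \code{multi_domain_report})
#' @export
run_pipeline <- function(x, cfg = run_config()) {
  parts <- partition_domains(x)
  singles <- lapply(parts, run_single_domain, cfg = cfg)
  multi <- run_multi_domain(x, singles, cfg)
  list(singles = singles, multi = multi)
}

write_tsv <- function(df, path)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)

#' Write a machine-readable report for a pipeline run
#'
#' Emits, under \code{outdir}: the univariate screen
#' (\code{univariate.tsv}), both importance rankings with selection flags
#' (\code{importance_rf.tsv}, \code{importance_lovo.tsv}), the refined-set
#' listing with provenance (\code{refined_set.tsv}), the ROC curves of the
#' fitted classifiers (\code{roc_<model>.tsv}), the between-domain inertia
#' table (\code{between_domain.tsv}) and a YAML summary
#' (\code{summary.yaml}). Re-running with the same inputs overwrites the
#' files identically.
#'
#' @param report a \code{\link{run_multi_domain}} result
#' @param outdir output directory (created if needed)
#' @return invisibly, the written file paths
#' @export
write_report <- function(report, outdir) {
  stopifnot(inherits(report, "multi_domain_report"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  f <- file.path(outdir, "univariate.tsv")
  write_tsv(report$screen, f); paths <- c(paths, f)
  for (eng in c("rf", "lovo")) {
    imp <- sort(report[[paste0(eng, "_importance")]], decreasing = TRUE)
    sel <- report[[paste0(eng, "_selection")]]
    df <- data.frame(variable = names(imp), importance = imp,
                     rank = seq_along(imp),
                     selected = names(imp) %in% sel$selected)
    f <- file.path(outdir, sprintf("importance_%s.tsv", eng))
    write_tsv(df, f); paths <- c(paths, f)
  }
  f <- file.path(outdir, "refined_set.tsv")
  write_tsv(report$union, f); paths <- c(paths, f)
  for (nm in names(report$models)) {
    m <- report$models[[nm]]
    roc <- if (!is.null(m$roc)) m$roc else next
    f <- file.path(outdir, sprintf("roc_%s.tsv", nm))
    write_tsv(roc$roc, f); paths <- c(paths, f)
  }
  bd <- report$between_domain
  doms <- rownames(bd$measured)
  pairs <- which(upper.tri(bd$measured), arr.ind = TRUE)
  f <- file.path(outdir, "between_domain.tsv")
  write_tsv(data.frame(domain_a = doms[pairs[, 1]],
                       domain_b = doms[pairs[, 2]],
                       measured = bd$measured[pairs],
                       normalized = bd$normalized[pairs],
                       p = bd$p[pairs]), f)
  paths <- c(paths, f)
  summary_list <- list(
    package_size = length(report$variables),
    refined_size = length(report$refined),
    refined = as.list(report$refined),
    seed = report$config$seed,
    n_trees = report$config$n_trees,
    permutations = report$config$permutations,
    auc = list(
      plsca = report$models$plsca$roc$auc,
      rf = report$models$rf$roc$auc,
      logistic = if (!is.null(report$models$logistic))
        report$models$logistic$roc$auc,
      refined_logistic = if (!is.null(report$models$refined_logistic$roc))
        report$models$refined_logistic$roc$auc),
    loocv = list(
      logistic = if (!is.null(report$models$logistic))
        report$models$logistic$loocv$accuracy,
      refined_logistic = if (!is.null(report$models$refined_logistic$loocv))
        report$models$refined_logistic$loocv$accuracy),
    criteria_agree = report$models$refined_logistic$criteria_agree)
  f <- file.path(outdir, "summary.yaml")
  yaml::write_yaml(summary_list, f); paths <- c(paths, f)
  invisible(paths)
}
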