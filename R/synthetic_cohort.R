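# Synthetic two-group cohort generator. Emulates the statistical structure the
# downstream analysis assumes: per-variable two-group means/SDs, block
# multicollinearity on latent normals (Gaussian-copula style for binary
# variables), MCAR missingness, and trial-level gait series.

#' Cohort generative specification
#'
#' Full description of a synthetic faller/non-faller cohort: group sizes, a
#' per-variable table of group means/SDs (continuous) or event probabilities
#' (binary), within- and between-domain correlation levels applied to the
#' latent normals, an MCAR missingness rate, and a seed.
#'
#' @param variables data frame with columns \code{name}, \code{domain},
#'   \code{kind}, \code{units}, \code{panel} (\code{"baseline"} descriptive
#'   characteristics vs \code{"assessment"} domain measures), \code{signal}
#'   (logical: carries a configured group difference), and for continuous
#'   variables \code{faller_mean}, \code{faller_sd}, \code{nonfaller_mean},
#'   \code{nonfaller_sd}; for binary variables \code{faller_p},
#'   \code{nonfaller_p}.
#' @param n_fallers,n_nonfallers group sizes (defaults 21 and 39)
#' @param within_r named vector of common within-domain correlations
#'   (default 0.6 for every domain)
#' @param cross_r data frame with columns \code{a}, \code{b}, \code{r} giving
#'   between-domain correlation levels (unlisted pairs default to
#'   \code{default_cross_r})
#' @param default_cross_r correlation for domain pairs not listed (default 0)
#' @param missing_rate proportion of continuous cells set MCAR missing,
#'   in [0, 0.5]
#' @param seed integer seed making generation fully reproducible
#' @return an object of class \code{"cohort_config"}
#' @export
cohort_config <- function(variables, n_fallers = 21, n_nonfallers = 39,
                          within_r = NULL, cross_r = NULL,
                          default_cross_r = 0,
                          missing_rate = 0.02, seed = 1L) {
  variables <- as.data.frame(variables, stringsAsFactors = FALSE)
  stopifnot(n_fallers >= 2, n_nonfallers >= 2)
  if (missing_rate < 0 || missing_rate > 0.5)
    stop("missing_rate must be in [0, 0.5]")
  cont <- variables$kind == "continuous"
  if (any(cont) &&
      (any(variables$faller_sd[cont] <= 0) || any(variables$nonfaller_sd[cont] <= 0)))
    stop("SDs must be positive")
  if (any(!cont)) {
    pr <- c(variables$faller_p[!cont], variables$nonfaller_p[!cont])
    if (any(pr < 0 | pr > 1)) stop("event probabilities must be in [0,1]")
  }
  if (is.null(within_r)) within_r <- stats::setNames(rep(0.6, length(DOMAINS)), DOMAINS)
  structure(list(variables = variables, n_fallers = n_fallers,
                 n_nonfallers = n_nonfallers, within_r = within_r,
                 cross_r = cross_r, default_cross_r = default_cross_r,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("cohort_config: %d fallers + %d non-fallers, %d variables, missing_rate %.3g, seed %d\n",
              x$n_fallers, x$n_nonfallers, nrow(x$variables), x$missing_rate, x$seed))
  invisible(x)
}

fixture_continuous <- function() {
  # name, domain, panel, signal flag, faller mean/sd, non-faller mean/sd
  rows <- list(
    # -- baseline descriptive characteristics --
    c("age_years",                "clinical", "baseline", 71.52, 4.33, 68.87, 3.41),
    c("mass_kg",                  "clinical", "baseline", 65.43, 10.67, 62.31, 10.55),
    c("height_m",                 "clinical", "baseline", 1.62, 0.05, 1.60, 0.06),
    c("bmi_kg_m2",                "clinical", "baseline", 25.13, 4.06, 24.25, 3.60),
    c("systolic_bp_mmhg",         "clinical", "baseline", 121.27, 12.73, 125.56, 13.65),
    c("diastolic_bp_mmhg",        "clinical", "baseline", 75.56, 5.94, 77.33, 8.39),
    c("resting_hr_bpm",           "clinical", "baseline", 69.52, 7.22, 69.50, 6.82),
    c("n_medications",            "clinical", "baseline", 1.14, 1.06, 0.92, 1.11),
    c("weekly_alcohol_units",     "clinical", "baseline", 10.60, 9.61, 8.06, 8.13),
    c("fes_i",                    "clinical", "baseline", 20.43, 2.77, 18.68, 2.61),
    c("gds",                      "clinical", "baseline", 1.29, 1.71, 1.33, 2.25),
    c("mmse",                     "clinical", "baseline", 29.43, 0.98, 29.36, 0.84),
    c("physical_activity_met_min","clinical", "baseline", 5990, 3711, 7463, 3860),
    # -- balance assessment variables --
    c("posterior_endpoint_excursion_pct", "balance", "assessment", 43.95, 13.34, 42.62, 12.02),
    c("anterior_maximum_excursion_pct",   "balance", "assessment", 82.05, 17.60, 91.67, 15.52),
    c("ec_left_sway_velocity",            "balance", "assessment", 5.67, 3.18, 6.03, 2.71),
    c("posterior_directional_control_pct","balance", "assessment", 65.52, 20.38, 59.35, 19.08),
    c("right_endpoint_excursion_pct",     "balance", "assessment", 61.57, 22.52, 65.87, 15.82),
    c("ec_right_sway_velocity",           "balance", "assessment", 7.02, 3.56, 5.97, 2.75),
    c("right_directional_control_pct",    "balance", "assessment", 81.10, 8.28, 75.74, 10.28),
    c("eo_right_sway_velocity",           "balance", "assessment", 1.61, 0.98, 1.24, 0.45),
    c("ec_somatosensory_ratio",           "balance", "assessment", 4.07, 1.35, 3.93, 1.38),
    c("composite_directional_control_pct","balance", "assessment", 78.27, 7.36, 74.25, 8.11),
    c("foam_ec_sway_velocity",            "balance", "assessment", 1.62, 0.45, 1.49, 0.43),
    # -- gait assessment variables --
    c("ugs_braking_phase_duration_s", "gait", "assessment", 0.32, 0.03, 0.30, 0.03),
    c("ugs_to_knee_angle_deg",        "gait", "assessment", 127, 4, 130, 5),
    c("ugs_step_length_index",        "gait", "assessment", 0.43, 0.02, 0.46, 0.03),
    c("mad_ugs_step_length_pct",      "gait", "assessment", 1.80, 1.38, 1.37, 0.47),
    c("mad_ugs_braking_phase_duration_pct", "gait", "assessment", 2.77, 1.85, 4.94, 2.64),
    c("mgs_step_length_index",        "gait", "assessment", 0.49, 0.02, 0.52, 0.03),
    c("mad_mgs_to_knee_angle_pct",    "gait", "assessment", 1.17, 0.54, 0.83, 0.47),
    c("mad_mgs_step_frequency_pct",   "gait", "assessment", 0.62, 0.52, 1.11, 0.82),
    c("mgs_to_knee_angle_deg",        "gait", "assessment", 132, 3, 134, 4),
    c("mad_ugs_braking_peak_force_pct", "gait", "assessment", 6.45, 3.83, 4.62, 2.24),
    c("mad_ugs_time_to_midstance_peak_force_pct", "gait", "assessment", 2.59, 1.72, 1.78, 0.88),
    # -- clinical assessment variables --
    c("poma_total_score",   "clinical", "assessment", 26.22, 1.70, 27.31, 1.17),
    c("tug_time_s",         "clinical", "assessment", 8.24, 1.18, 7.61, 1.17),
    c("poma_balance_score", "clinical", "assessment", 15.09, 1.58, 15.69, 0.57),
    c("ugs_m_s",            "clinical", "assessment", 1.42, 0.12, 1.50, 0.14),
    c("gait_speed_reserve", "clinical", "assessment", 1.33, 0.13, 1.29, 0.12),
    # -- strength assessment variables --
    c("pf120_dl_pt",        "strength", "assessment", 0.43, 0.16, 0.51, 0.15),
    c("pf60_sa_pct",        "strength", "assessment", 7.77, 6.51, 6.68, 4.48),
    c("ke60_sa_pct",        "strength", "assessment", 4.59, 4.41, 4.55, 3.46),
    c("df120_dl_pt",        "strength", "assessment", 0.20, 0.04, 0.23, 0.05),
    c("pf120_ndl_pt",       "strength", "assessment", 0.34, 0.13, 0.41, 0.13),
    c("kf120_dl_pt",        "strength", "assessment", 0.59, 0.15, 0.67, 0.15),
    c("kf120_ndl_pt",       "strength", "assessment", 0.49, 0.15, 0.59, 0.15),
    c("kf60_ndl_pt",        "strength", "assessment", 0.63, 0.13, 0.71, 0.14),
    c("pf60_ndl_pt",        "strength", "assessment", 0.50, 0.17, 0.60, 0.22),
    c("kf120_sa_pct",       "strength", "assessment", 6.72, 4.41, 4.33, 2.44),
    c("trunk_flex45_angpt_deg", "strength", "assessment", 57.62, 11.64, 51.98, 9.37),
    c("kf60_dl_pt",         "strength", "assessment", 0.74, 0.12, 0.81, 0.13),
    c("df60_ndl_pt",        "strength", "assessment", 0.23, 0.04, 0.27, 0.06),
    c("df120_ndl_pt",       "strength", "assessment", 0.17, 0.04, 0.20, 0.05),
    # -- body composition assessment variables --
    c("dl_thigh_mq_combined",  "body_composition", "assessment", 34.01, 4.26, 36.07, 5.18),
    c("sa_shank_mq_pf_pct",    "body_composition", "assessment", 7.48, 5.40, 7.27, 4.87),
    c("dl_thigh_mq_ke",        "body_composition", "assessment", 21.98, 3.12, 23.43, 3.92),
    c("thigh_mq_combined",     "body_composition", "assessment", 31.69, 4.73, 34.44, 5.22),
    c("femoral_strength_index","body_composition", "assessment", 1.37, 0.29, 1.45, 0.23),
    c("dl_thigh_mq_isom_ke",   "body_composition", "assessment", 30.09, 5.00, 32.21, 7.02),
    c("trochanter_bmd",        "body_composition", "assessment", 0.70, 0.11, 0.67, 0.10),
    c("ndl_shank_mq_pf",       "body_composition", "assessment", 19.66, 6.85, 22.34, 8.53),
    c("almi_kg_m2",            "body_composition", "assessment", 6.27, 0.72, 6.21, 0.68),
    c("total_fat_mass_kg",     "body_composition", "assessment", 24.14, 7.69, 21.46, 7.19))
  df <- data.frame(
    name = vapply(rows, `[`, "", 1L),
    domain = vapply(rows, `[`, "", 2L),
    panel = vapply(rows, `[`, "", 3L),
    kind = "continuous", units = "",
    faller_mean = as.numeric(vapply(rows, `[`, "", 4L)),
    faller_sd = as.numeric(vapply(rows, `[`, "", 5L)),
    nonfaller_mean = as.numeric(vapply(rows, `[`, "", 6L)),
    nonfaller_sd = as.numeric(vapply(rows, `[`, "", 7L)),
    faller_p = NA_real_, nonfaller_p = NA_real_,
    stringsAsFactors = FALSE)
  df$signal <- TRUE
  df
}

#' Built-in fixture cohort configuration
#'
#' A ready-made \code{\link{cohort_config}} encoding the study conditions the
#' package is exercised under: 21 fallers and 39 non-fallers; every variable
#' of the printed group-summary tables with its printed group means/SDs (13
#' baseline descriptive characteristics, 2 binary impairment indicators, and
#' the 51 multi-domain assessment variables: 11 balance, 11 gait, 5 clinical,
#' 14 strength, 10 body-composition); additional no-effect nuisance variables
#' bringing each domain up to its full collected size (52 balance, 99 gait,
#' 10 clinical, 70 strength, 34 body-composition); within-domain correlation
#' 0.6, strength/body-composition cross-correlation 0.7, balance weakly
#' coupled (0.1) to the other domains; and 2\% MCAR missingness.
#'
#' @param n_nuisance named integer vector of no-effect variables added per
#'   domain; set to zeros to keep only the printed variables
#' @param missing_rate MCAR missingness proportion (default 0.02)
#' @param seed generation seed (default 1)
#' @return a \code{cohort_config}
#' @export
builtin_fixture_config <- function(n_nuisance = c(balance = 41, gait = 88,
                                                  clinical = 5, strength = 56,
                                                  body_composition = 24),
                                   missing_rate = 0.02, seed = 1L) {
  df <- fixture_continuous()
  bin <- data.frame(
    name = c("visual_impairment", "hearing_impairment"),
    domain = "clinical", panel = "baseline", kind = "binary", units = "",
    faller_mean = NA_real_, faller_sd = NA_real_,
    nonfaller_mean = NA_real_, nonfaller_sd = NA_real_,
    faller_p = c(20 / 21, 5 / 21), nonfaller_p = c(36 / 39, 7 / 39),
    signal = TRUE, stringsAsFactors = FALSE)
  nuis <- do.call(rbind, lapply(names(n_nuisance), function(d) {
    k <- n_nuisance[[d]]
    if (k == 0) return(NULL)
    data.frame(name = sprintf("noise_%s_%02d", d, seq_len(k)),
               domain = d, panel = "assessment", kind = "continuous",
               units = "", faller_mean = 0, faller_sd = 1,
               nonfaller_mean = 0, nonfaller_sd = 1,
               faller_p = NA_real_, nonfaller_p = NA_real_,
               signal = FALSE, stringsAsFactors = FALSE)
  }))
  vars <- rbind(df, bin, if (!is.null(nuis)) nuis)
  cross <- data.frame(
    a = c("balance", "balance", "balance", "balance",
          "strength", "gait", "gait", "gait", "clinical", "clinical"),
    b = c("gait", "clinical", "strength", "body_composition",
          "body_composition", "clinical", "strength", "body_composition",
          "strength", "body_composition"),
    r = c(0.1, 0.1, 0.1, 0.1, 0.7, 0.4, 0.4, 0.25, 0.25, 0.2),
    stringsAsFactors = FALSE)
  cohort_config(vars, n_fallers = 21, n_nonfallers = 39,
                cross_r = cross, missing_rate = missing_rate, seed = seed)
}

#' Variable subsets of a cohort configuration
#'
#' \code{assessment_variables} returns the names of the domain assessment
#' variables (everything except the baseline descriptive characteristics);
#' \code{multidomain_variables} returns the assessment variables that carry
#' a configured group difference — for the built-in fixture these are the
#' 51 variables of the printed multi-domain package (11 balance, 11 gait,
#' 5 clinical, 14 strength, 10 body-composition).
#'
#' @param config a \code{\link{cohort_config}}
#' @return character vector of variable names
#' @export
assessment_variables <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  config$variables$name[config$variables$panel == "assessment"]
}

#' @rdname assessment_variables
#' @export
multidomain_variables <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  v <- config$variables
  v$name[v$panel == "assessment" & v$signal]
}

# Assemble the latent-normal correlation matrix from the block levels and
# repair to the nearest PSD correlation matrix if needed.
assemble_correlation <- function(config) {
  v <- config$variables
  p <- nrow(v)
  R <- matrix(config$default_cross_r, p, p)
  for (d in unique(v$domain)) {
    idx <- which(v$domain == d)
    r <- if (d %in% names(config$within_r)) config$within_r[[d]] else 0.6
    R[idx, idx] <- r
  }
  if (!is.null(config$cross_r)) {
    for (k in seq_len(nrow(config$cross_r))) {
      ia <- which(v$domain == config$cross_r$a[k])
      ib <- which(v$domain == config$cross_r$b[k])
      R[ia, ib] <- config$cross_r$r[k]
      R[ib, ia] <- config$cross_r$r[k]
    }
  }
  diag(R) <- 1
  repaired <- FALSE
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    R <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
    repaired <- TRUE
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-6) stop("correlation matrix not PSD after repair")
  }
  # guard against residual tiny negatives for the factorization
  attr(R, "psd_repaired") <- repaired
  R
}

#' Generate a synthetic cohort
#'
#' Draws each group from a multivariate normal on the latent scale with the
#' block correlation structure of the config; continuous variables are scaled
#' to the group's mean/SD, binary variables are obtained by thresholding
#' their latent normal at the group's probability quantile (Gaussian-copula
#' construction). MCAR missingness is then injected into the continuous
#' cells. Fully reproducible from the config seed.
#'
#' @param config a \code{\link{cohort_config}}
#' @return a \code{\link{feature_table}}; attribute \code{"psd_repaired"}
#'   reports whether the requested correlation matrix needed nearest-PSD
#'   repair
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  v <- config$variables
  R <- assemble_correlation(config)
  set.seed(config$seed)
  draw_group <- function(n, means, sds, probs) {
    Z <- MASS::mvrnorm(n, mu = rep(0, nrow(v)), Sigma = R)
    X <- Z
    cont <- v$kind == "continuous"
    X[, cont] <- sweep(sweep(Z[, cont, drop = FALSE], 2, sds[cont], "*"),
                       2, means[cont], "+")
    if (any(!cont)) {
      for (j in which(!cont))
        X[, j] <- as.numeric(Z[, j] <= stats::qnorm(probs[j]))
    }
    X
  }
  Xf <- draw_group(config$n_fallers, v$faller_mean, v$faller_sd, v$faller_p)
  Xn <- draw_group(config$n_nonfallers, v$nonfaller_mean, v$nonfaller_sd,
                   v$nonfaller_p)
  X <- rbind(Xf, Xn)
  group <- c(rep("faller", config$n_fallers),
             rep("non_faller", config$n_nonfallers))
  if (config$missing_rate > 0) {
    cont <- which(v$kind == "continuous")
    m <- matrix(stats::runif(nrow(X) * length(cont)) < config$missing_rate,
                nrow(X), length(cont))
    X[, cont][m] <- NA_real_
  }
  ft <- feature_table(X, group,
                      v[, c("name", "domain", "kind", "units")],
                      sprintf("P%03d", seq_len(nrow(X))))
  attr(ft, "psd_repaired") <- attr(R, "psd_repaired")
  ft
}

#' Generate trial-level gait series
#'
#' For every participant and gait-domain variable, draws \code{steps}
#' per-step values about the participant's latent level with additive
#' Laplace(b) noise, so that the expected percentage MAD is known in closed
#' form (the MAD of a Laplace(b) distribution is \code{b log 2}).
#'
#' @param config a \code{\link{cohort_config}}
#' @param steps steps per participant and variable (default 5, must be >= 2)
#' @param dispersion Laplace scale b of the within-participant step noise
#'   (same units as the variable; default 0.05)
#' @return long-format data frame with columns \code{participant_id},
#'   \code{variable}, \code{trial_index}, \code{value}
#' @export
generate_trial_level <- function(config, steps = 5, dispersion = 0.05) {
  stopifnot(inherits(config, "cohort_config"))
  if (steps < 2) stop("steps must be >= 2")
  ft <- generate_cohort(config)
  gait_vars <- ft$variables$name[ft$variables$domain == "gait"]
  if (!length(gait_vars)) stop("config has no gait variables")
  levels_mat <- ft$values[, gait_vars, drop = FALSE]
  n <- nrow(levels_mat)
  rlap <- function(k, b) {
    u <- stats::runif(k)
    ifelse(u < 0.5, b * log(2 * u), -b * log(2 * (1 - u)))
  }
  out <- expand.grid(trial_index = seq_len(steps),
                     variable = gait_vars,
                     participant_id = ft$participant_ids,
                     stringsAsFactors = FALSE)
  lev <- levels_mat[cbind(match(out$participant_id, ft$participant_ids),
                          match(out$variable, gait_vars))]
  out$value <- lev + if (dispersion > 0) rlap(nrow(out), dispersion) else 0
  out[, c("participant_id", "variable", "trial_index", "value")]
}
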