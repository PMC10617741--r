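test_that("generation is a deterministic function of the config seed", {
  cfg <- small_config(missing_rate = 0.05, seed = 13)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$values, b$values)
  expect_identical(a$mask, b$mask)
  cfg2 <- small_config(missing_rate = 0.05, seed = 14)
  expect_false(identical(generate_cohort(cfg2)$values, a$values))
})

test_that("large samples recover the configured group means and effects", {
  cfg <- builtin_fixture_config(n_nuisance = c(balance = 0, gait = 0,
                                               clinical = 0, strength = 0,
                                               body_composition = 0),
                                missing_rate = 0, seed = 21)
  cfg$n_fallers <- 5000
  cfg$n_nonfallers <- 5000
  ft <- generate_cohort(cfg)
  v <- cfg$variables
  cont <- which(v$kind == "continuous")
  fal <- ft$group == "faller"
  zf <- (colMeans(ft$values[fal, v$name[cont]]) - v$faller_mean[cont]) /
    (v$faller_sd[cont] / sqrt(5000))
  zn <- (colMeans(ft$values[!fal, v$name[cont]]) - v$nonfaller_mean[cont]) /
    (v$nonfaller_sd[cont] / sqrt(5000))
  expect_lt(max(abs(c(zf, zn))), 4.5)        # simultaneous band over 64 vars
  expect_lt(median(abs(c(zf, zn))), 1.5)
  # pooled-SD effect sizes recover the configured standardized differences
  some <- c("ugs_step_length_index", "mgs_step_length_index",
            "kf120_sa_pct", "age_years", "tug_time_s")
  for (nm in some) {
    i <- match(nm, v$name)
    conf <- group_summary(5000, v$faller_mean[i], v$faller_sd[i],
                          5000, v$nonfaller_mean[i], v$nonfaller_sd[i])
    est <- group_summary(5000, mean(ft$values[fal, nm]),
                         sd(ft$values[fal, nm]),
                         5000, mean(ft$values[!fal, nm]),
                         sd(ft$values[!fal, nm]))
    expect_equal(cohens_d(est), cohens_d(conf), tolerance = 0.08)
  }
  # binary variables hit the configured event probabilities
  expect_lt(abs(mean(ft$values[fal, "hearing_impairment"]) - 5 / 21), 0.03)
  expect_lt(abs(mean(ft$values[!fal, "visual_impairment"]) - 36 / 39), 0.03)
})

test_that("MCAR missingness lands at the configured rate", {
  cfg <- small_config(missing_rate = 0.1, seed = 31,
                      n_nuisance = c(balance = 0, gait = 0, clinical = 0,
                                     strength = 0, body_composition = 0))
  ft <- generate_cohort(cfg)
  cont <- ft$variables$kind == "continuous"
  ncells <- nrow(ft$values) * sum(cont)
  nmiss <- sum(ft$mask[, cont])
  expect_lt(abs(nmiss - 0.1 * ncells), 4 * sqrt(ncells * 0.1 * 0.9))
  expect_equal(sum(ft$mask[, !cont]), 0)   # binary cells stay observed
  expect_error(cohort_config(cfg$variables, missing_rate = 0.6),
               "missing_rate")
})

test_that("correlation blocks shape the generated dependence", {
  cfg <- builtin_fixture_config(n_nuisance = c(balance = 0, gait = 0,
                                               clinical = 0, strength = 0,
                                               body_composition = 0),
                                missing_rate = 0, seed = 8)
  cfg$n_fallers <- 3000; cfg$n_nonfallers <- 3000
  ft <- generate_cohort(cfg)
  fal <- ft$group == "faller"
  strg <- ft$variables$name[ft$variables$domain == "strength"][1:6]
  bal <- ft$variables$name[ft$variables$domain == "balance"][1:6]
  R <- cor(ft$values[fal, c(strg, bal)])
  within_strength <- R[strg, strg][upper.tri(diag(6))]
  cross <- R[strg, bal]
  expect_gt(mean(within_strength), 0.45)
  expect_lt(mean(abs(cross)), 0.2)
})

test_that("trial-level series have the configured step structure", {
  cfg <- small_config(missing_rate = 0, seed = 17,
                      n_nuisance = c(balance = 0, gait = 1, clinical = 0,
                                     strength = 0, body_composition = 0))
  tl <- generate_trial_level(cfg, steps = 5, dispersion = 0)
  expect_equal(nrow(tl), 60 * 12 * 5)     # 11 signal + 1 nuisance gait vars
  counts <- table(tl$participant_id, tl$variable)
  expect_true(all(counts == 5))
  # zero dispersion: every participant's series is constant
  one <- subset(tl, participant_id == "P001" & variable == "ugs_step_length_index")
  expect_equal(mad_percent(one$value), 0)
  expect_error(generate_trial_level(cfg, steps = 1), "steps")

  # Laplace dispersion b: MAD -> b log 2, so mad_percent -> b log2 / |median| * 100
  vars <- data.frame(name = "step_var", domain = "gait", panel = "assessment",
                     kind = "continuous", units = "",
                     faller_mean = 10, faller_sd = 1e-6,
                     nonfaller_mean = 10, nonfaller_sd = 1e-6,
                     faller_p = NA_real_, nonfaller_p = NA_real_,
                     signal = TRUE)
  cfg2 <- cohort_config(vars, n_fallers = 3, n_nonfallers = 3,
                        missing_rate = 0, seed = 23)
  tl2 <- generate_trial_level(cfg2, steps = 4001, dispersion = 0.5)
  mp <- sapply(split(tl2$value, tl2$participant_id), mad_percent)
  expect_equal(unname(mp), rep(0.5 * log(2) / 10 * 100, 6), tolerance = 0.05)
})
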