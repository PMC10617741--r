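test_that("construction checks shapes, groups and domains", {
  X <- matrix(rnorm(60 * 4), 60, 4)
  vars <- data.frame(name = paste0("v", 1:4), domain = "gait",
                     kind = "continuous", units = "")
  ft <- feature_table(X, c(rep("faller", 21), rep("non_faller", 39)), vars)
  expect_equal(dim(ft), c(60L, 4L))
  expect_equal(sum(group_indicator(ft)), 21)

  expect_error(feature_table(X, rep("faller", 60), vars), "both group levels")
  expect_error(feature_table(X, c(rep("faller", 1), rep("non_faller", 59)),
                             vars), "fewer than 2")
  vars_bad <- vars; vars_bad$domain <- "vision"
  expect_error(feature_table(X, c(rep("faller", 21), rep("non_faller", 39)),
                             vars_bad), "unknown domain")
  vars_dup <- vars; vars_dup$name <- rep("v1", 4)
  expect_error(feature_table(X, c(rep("faller", 21), rep("non_faller", 39)),
                             vars_dup), "duplicated")
})

test_that("CSV round trip preserves values, mask and groups exactly", {
  set.seed(1)
  X <- matrix(rnorm(60 * 5), 60, 5)
  X[sample(length(X), 17)] <- NA
  vars <- data.frame(name = paste0("v", 1:5),
                     domain = c("gait", "gait", "balance", "strength",
                                "clinical"),
                     kind = "continuous", units = "")
  ft <- feature_table(X, c(rep("faller", 21), rep("non_faller", 39)), vars)
  d <- withr::local_tempdir()
  write_feature_table(ft, file.path(d, "data.csv"), file.path(d, "meta.csv"))
  back <- read_feature_table(file.path(d, "data.csv"),
                             file.path(d, "meta.csv"))
  expect_identical(back$values, ft$values)
  expect_identical(back$mask, ft$mask)
  expect_identical(as.character(back$group), as.character(ft$group))
  expect_identical(back$variables$domain, ft$variables$domain)
})

test_that("reader rejects malformed inputs", {
  d <- withr::local_tempdir()
  writeLines(c("participant_id,group,v1", "P1,faller,1.0", "P2,faller,2.0"),
             file.path(d, "one_group.csv"))
  writeLines(c("name,domain,kind,units", "v1,gait,continuous,"),
             file.path(d, "meta.csv"))
  expect_error(read_feature_table(file.path(d, "one_group.csv"),
                                  file.path(d, "meta.csv")),
               "both group levels")
  writeLines(c("participant_id,group,v1",
               "P1,faller,abc", "P2,faller,2", "P3,non_faller,3",
               "P4,non_faller,4"),
             file.path(d, "bad_cell.csv"))
  expect_error(read_feature_table(file.path(d, "bad_cell.csv"),
                                  file.path(d, "meta.csv")),
               "non-numeric")
  writeLines(c("participant_id,grp,v1", "P1,faller,1"),
             file.path(d, "no_group.csv"))
  expect_error(read_feature_table(file.path(d, "no_group.csv"),
                                  file.path(d, "meta.csv")),
               "missing group column")
})

test_that("domain partition conserves columns and matches the package sizes", {
  cfg <- builtin_fixture_config(n_nuisance = c(balance = 0, gait = 0,
                                               clinical = 0, strength = 0,
                                               body_composition = 0),
                                missing_rate = 0, seed = 2)
  ft <- generate_cohort(cfg)
  multi <- select_variables(ft, multidomain_variables(cfg))
  parts <- partition_domains(multi)
  sizes <- vapply(parts, function(p) ncol(p$values), integer(1))
  expect_equal(unname(sizes[c("balance", "gait", "clinical", "strength",
                              "body_composition")]),
               c(11L, 11L, 5L, 14L, 10L))
  expect_equal(sum(sizes), ncol(multi$values))
  # column-concatenating the partition reproduces the parent up to order
  recon <- do.call(cbind, lapply(parts, function(p) p$values))
  expect_equal(recon[, colnames(multi$values)], multi$values)

  single <- select_variables(ft, "tug_time_s")
  expect_named(partition_domains(single), "clinical")
})

test_that("z-scoring standardizes observed entries and keeps the mask", {
  X <- cbind(a = c(1, 2, 3), b = c(1, NA, 3))
  vars <- data.frame(name = c("a", "b"), domain = "gait",
                     kind = "continuous", units = "")
  ft <- feature_table(rbind(X, X), rep(c("faller", "non_faller"), each = 3),
                      vars)
  z <- zscore_columns(ft)
  expect_equal(unname(z$values[1:3, "a"]),
               unname((c(1, 2, 3) - 2) / sd(rep(c(1, 2, 3), 2))))
  expect_identical(z$mask, ft$mask)
  # idempotence
  z2 <- zscore_columns(z)
  expect_equal(z2$values, z$values, tolerance = 1e-12)
  # hand computation on a 3-row column with one missing cell
  Y <- cbind(a = c(1, 2, 3, 4), b = c(1, NA, 3, NA))
  ft2 <- feature_table(Y, c("faller", "faller", "non_faller", "non_faller"),
                       vars)
  z3 <- zscore_columns(ft2)
  expect_equal(unname(z3$values[, "b"]),
               c((1 - 2) / sqrt(2), NA, (3 - 2) / sqrt(2), NA))
  # constant column errors
  C <- cbind(a = c(1, 2, 3, 4), b = rep(5, 4))
  ftc <- feature_table(C, c("faller", "faller", "non_faller", "non_faller"),
                       vars)
  expect_error(zscore_columns(ftc), "constant")
})
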