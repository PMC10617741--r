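# Shared fixture builders. Everything is generated in code at test time.

# Small correlated two-group cohort config: a few signal variables per domain
# plus optional noise columns, no missingness unless asked.
small_config <- function(missing_rate = 0, seed = 42L,
                         n_nuisance = c(balance = 2, gait = 3, clinical = 1,
                                        strength = 2, body_composition = 2)) {
  builtin_fixture_config(n_nuisance = n_nuisance,
                         missing_rate = missing_rate, seed = seed)
}

# A two-group table with one cleanly separating variable and noise columns.
separable_table <- function(n1 = 21, n2 = 39, p_noise = 9, seed = 7L,
                            shift = 4) {
  set.seed(seed)
  n <- n1 + n2
  X <- matrix(rnorm(n * (p_noise + 1)), n, p_noise + 1)
  X[seq_len(n1), 1] <- X[seq_len(n1), 1] + shift
  vars <- data.frame(name = c("signal", sprintf("noise%02d", seq_len(p_noise))),
                     domain = "gait", kind = "continuous", units = "")
  feature_table(X, c(rep("faller", n1), rep("non_faller", n2)), vars)
}

# Plain z-scored matrix block.
zblock <- function(n, p, seed = 1L, prefix = "v") {
  set.seed(seed)
  M <- matrix(rnorm(n * p), n, p)
  M <- scale(M)
  attr(M, "scaled:center") <- NULL
  attr(M, "scaled:scale") <- NULL
  colnames(M) <- sprintf("%s%02d", prefix, seq_len(p))
  M
}

# z-scored group indicator column for n1 fallers then n2 non-fallers
zgroup <- function(n1, n2) {
  g <- c(rep(1, n1), rep(0, n2))
  matrix((g - mean(g)) / sd(g), ncol = 1, dimnames = list(NULL, "faller"))
}

# Rank-q data with additive noise, for PPCA tests.
lowrank_data <- function(n = 60, p = 10, q = 2, noise = 0.1, seed = 3L) {
  set.seed(seed)
  Z <- matrix(rnorm(n * q), n, q)
  W <- matrix(rnorm(p * q, sd = 1), p, q)
  X <- Z %*% t(W) + matrix(rnorm(n * p, sd = noise), n, p)
  colnames(X) <- sprintf("x%02d", seq_len(p))
  X
}

as_ft <- function(X, n1 = NULL, domain = "gait") {
  n <- nrow(X)
  if (is.null(n1)) n1 <- floor(n / 3)
  vars <- data.frame(name = colnames(X), domain = domain,
                     kind = "continuous", units = "")
  feature_table(X, c(rep("faller", n1), rep("non_faller", n - n1)), vars)
}

# Piecewise-linear torque ramp: flat baseline, then a constant-slope rise,
# optionally plateauing. Sampled at `rate` Hz.
torque_ramp <- function(baseline = 2, slope = 100, rate = 2000,
                        baseline_s = 0.5, rise_s = 0.4, plateau_s = 0.2) {
  t_base <- rep(baseline, round(baseline_s * rate))
  t_rise <- baseline + slope * seq_len(round(rise_s * rate)) / rate
  t_plat <- rep(baseline + slope * rise_s, round(plateau_s * rate))
  torque_trace(c(t_base, t_rise, t_plat), rate, baseline_s)
}

# Exhaustive-search Jenks oracle: minimal within-class SSD over all
# contiguous partitions of the sorted values into k classes.
jenks_bruteforce <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  ssd <- function(v) sum((v - mean(v))^2)
  splits <- utils::combn(n - 1, k - 1)
  best <- Inf
  best_bounds <- NULL
  for (c in seq_len(ncol(splits))) {
    cuts <- c(0, splits[, c], n)
    tot <- sum(vapply(seq_len(k), function(i)
      ssd(x[(cuts[i] + 1):cuts[i + 1]]), numeric(1)))
    if (tot < best) { best <- tot; best_bounds <- x[splits[, c]] }
  }
  list(ssd = best, bounds = best_bounds)
}

# Concordant-pair AUC oracle (ties count one half).
auc_bruteforce <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Memoized full-size fixture pipeline run shared by the acceptance tests.
fixture_run_cache <- new.env(parent = emptyenv())
get_fixture_run <- function() {
  if (is.null(fixture_run_cache$run)) {
    cfg <- builtin_fixture_config(seed = 11L)
    ft <- generate_cohort(cfg)
    sub <- select_variables(ft, assessment_variables(cfg))
    fixture_run_cache$config <- cfg
    fixture_run_cache$run <- run_pipeline(sub, run_config(seed = 11L,
                                                          permutations = 199))
  }
  list(config = fixture_run_cache$config, run = fixture_run_cache$run)
}
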