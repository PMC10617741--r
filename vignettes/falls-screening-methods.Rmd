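---
title: "Multi-domain variable importance for falls-risk screening: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-domain variable importance for falls-risk screening: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fallscreen)
```

# The problem

Community-dwelling older women who fall differ from those who do not across
many partially redundant measurements: static balance posturography, gait
kinetics and kinematics, clinical mobility tests, isometric/isokinetic
strength, and DXA body composition. A screening study typically collects
far more variables (hundreds) than participants (tens), so ordinary
multivariate models such as logistic regression cannot be fitted to the full
table, and strong within-domain multicollinearity makes univariate rankings
unstable and repetitive. `fallscreen` implements a two-stage strategy for
this setting:

1. **Single-domain stage.** The table is partitioned into five "data
   packages" (balance, gait, clinical, strength, body composition). Within
   each package, variables are ranked by two complementary importance
   engines — random-forest mean decrease in the Gini index, and
   leave-one-variable-out (LOVO) partial least squares correlation analysis
   (PLSCA) inertia decrease — and the "important" variables are those above
   a Fisher–Jenks natural-breaks cut on each engine's scree of scores. The
   union of the two selections is the package's refined set.
2. **Multi-domain stage.** The per-domain refined sets are pooled, missing
   cells are imputed by probabilistic PCA, the dual ranking/selection is
   repeated, and three classifiers are fitted on the final refined set:
   a PLSCA latent-score classifier, a random forest evaluated out-of-bag,
   and logistic regression with leave-one-out cross-validation and backward
   AIC/BIC refinement. PLSCA applied bilaterally between domain blocks also
   quantifies how much information the domains share.

# The core quantities

## PLSCA inertia and LOVO importance

For two column-standardized blocks $X$ ($n \times p_x$) and $Y$
($n \times p_y$) on the same participants, PLSCA decomposes the
cross-correlation matrix

$$R = \frac{X^\top Y}{n-1}, \qquad R = U \Lambda V^\top,$$

whose entries are the pairwise Pearson correlations. The **singular value
inertia** $\sum_k \lambda_k^2$ measures shared information between the
blocks; untruncated it equals $\lVert R \rVert_F^2$ exactly, a machine-
precision identity the test suite asserts on random instances. For
group-versus-features analyses $X$ is the z-scored faller indicator
(faller = 1 throughout the package), a single column, so $R$ is the vector
of point-biserial correlations and the inertia is its squared norm.

A variable's **LOVO importance** is the drop in inertia when its column is
removed and the decomposition refitted. Untruncated, this equals the
dropped column's squared norm in $R$, which gives a second, independent
route the tests compare against the brute-force refit loop. Importances are
therefore non-negative and, with a single-column $X$, sum to the baseline
inertia.

**Components retained.** The number of retained components for a truncated
inertia is exposed (`k` in `fit_plsca`), but the default is untruncated:
with a group indicator the decomposition has a single non-zero singular
value so the two conventions coincide, and untruncated inertia is the only
choice that makes the Frobenius and column-norm identities exact.

**Sign convention.** An SVD is sign-ambiguous. The first salience pair is
canonicalized so the first latent score correlates positively with
faller = 1 (for general two-block fits, the largest-magnitude element of
each left salience is made positive), making latent scores reproducible and
their orientation in ROC analysis explicit.

**Between-domain inertia** is reported both as measured and normalized by
the summed variable counts of the two blocks,
$\text{inertia}/(p_a + p_b)$, which makes pairs of differently sized
domains comparable; significance comes from permuting the participant rows
of one block (`permutation_pvalue`, $p = (1 + \#\{perm \ge obs\})/(b+1)$).

## Jenks natural-breaks selection

The "elbow" on an importance scree is placed by the exact Fisher–Jenks
dynamic programme: partition the sorted scores into two contiguous classes
minimizing the within-class sum of squared deviations. Variables strictly
above the lower class's maximum are "important"; ties at the break fall
below (the conservative reading). Because scree elbows are in practice
validated by eye, `select_above_break` accepts a manual override cutoff,
which is recorded in the result rather than applied silently. The DP is
checked against exhaustive enumeration of all contiguous partitions for
n up to 12.

## Probabilistic PCA imputation

Missing cells are imputed under the latent Gaussian factor model
$x = \mu + W z + \varepsilon$, $z \sim N(0, I_q)$,
$\varepsilon \sim N(0, \sigma^2 I)$, fitted by EM in which both the factors
and the missing cells are latent data. The M-step is implemented as three
conditional-maximization steps (mean, loadings, noise variance), so each
iteration cannot decrease the observed-data log-likelihood; the
per-iteration trace is stored and asserted monotone in the tests. Columns
are standardized before fitting (domains have wildly different units) and
de-standardized on return; observed cells are never altered, and the
original mask is kept as provenance. Defaults: $q = 5$, relative
log-likelihood tolerance $10^{-6}$, 1000 iterations, with non-convergence
reported by warning rather than hidden. The paper trail for $q$ is thin in
this literature, so it is a visible parameter; at the study's scale
(60 participants, ~50 variables, a few percent missing) results are
insensitive to $q$ in the 2–8 range. EM converges slowly when the noise
variance is very small — the low-noise tests therefore use a slightly
looser tolerance.

## Univariate screen

Continuous variables: Welch's unequal-variance $t$ (statistic, Welch–
Satterthwaite df, two-sided p) with the pooled-SD Cohen's $d$ magnitude.
This exact pairing — Welch for p, pooled SD for $d$ — is the one that
reproduces the published descriptive tables this package's worked examples
are checked against (age: $p = 0.02$, $d = 0.71$ from
21/39 participants). Binary variables: chi-square with Yates continuity
correction (floored at zero) and Cramer's V. No multiple-testing
correction is applied at the screening stage; flags mirror the
$p \le 0.10/0.05/0.001$ convention. Correlation structure is summarized by
a pairwise-complete Pearson matrix with the 0.10/0.30/0.50 magnitude
labels and a $|r| > 0.50$ collinearity flag, plus Bartlett's sphericity
test of the correlation matrix against the identity.

## Classification and evaluation

* **ROC/AUC.** The empirical ROC over all score thresholds
  (score $\ge$ cutoff classifies faller); AUC by trapezoid, equal to the
  Mann–Whitney statistic with ties counted one half (asserted against a
  concordant-pair-counting oracle). The AUC p-value against 0.5 uses the
  tie-corrected normal approximation of the Mann–Whitney test. The
  "optimal" cutoff maximizes Youden's $J$; exact ties resolve to the lower
  threshold so more participants are flagged, the safer direction for a
  screening rule.
* **Random forest.** 500 trees, $\lfloor\sqrt{p}\rfloor$ candidate
  variables per split, unlimited depth, bootstrap with replacement — the
  canonical classification-forest configuration, all surfaced in
  `run_config`/`fit_forest`. Validation is out-of-bag: each participant is
  scored only by trees that never saw them. The OOB "p-value" is a
  one-sided binomial test of OOB accuracy against the no-information
  (majority-class) rate — a documented interpretation, since OOB error has
  no unique associated test.
* **Logistic regression.** Plain ML binomial logit with VIFs (diagonal of
  the inverse predictor correlation matrix, i.e. the auxiliary-regression
  definition), AIC/BIC, and McFadden $R^2$. Backward refinement removes,
  at each step, the predictor whose removal most decreases the criterion,
  stopping when no removal helps; exact ties are broken by the largest
  current p-value, making the path deterministic. AIC and BIC refinements
  are both run and the report states whether they agree. LOOCV refits on
  every leave-one-out fold and classifies at probability 0.5 — not at the
  in-sample Youden cutoff, which would leak the held-out label's
  information into the threshold.
* Perfect separation (easy to produce with 18 predictors and 60
  participants) is detected from pinned fitted probabilities and flagged in
  the report rather than treated as an error.

## Derived assessment measures

The trial-level formulas feeding such tables are implemented and tested
directly: the symmetry angle
$|45^\circ - \arctan(\text{left}/\text{right})|/90^\circ \times 100$
(order-invariant, 0–50%, with the right = 0 limit evaluated as
90°); Romberg (eyes closed / eyes open) and somatosensory (foam/firm) sway
ratios; gait variability as the raw median absolute deviation of five
steps as a percentage of the median (no 1.4826 consistency constant — the
measure is a relative dispersion, not a robust SD estimate); gait speed
reserve (maximal/usual); rate of torque development as the endpoint slope
$\Delta\text{torque}/\Delta t$ over 0–50/100/200 ms windows from the
contraction onset (first sample 4 Nm above the baseline mean; baseline =
leading 500 ms, configurable), on a torque trace low-pass filtered at
150 Hz with a zero-phase second-order Butterworth filter (zero-phase so the
onset is not delayed; the filter wraps `signal::filtfilt` with
odd-reflection padding to suppress edge transients); a least-squares RTD
slope is available as an option. Muscle quality is summed peak torque per
kg of regional lean mass, with flexion/extension, dorsi/plantar-flexion
and hamstrings/quadriceps ratios as simple quotients.

# The synthetic cohort generator

No participant-level data are distributable, so the package carries a
generator (`cohort_config`, `generate_cohort`) whose built-in configuration
(`builtin_fixture_config`) encodes the study conditions end to end:

* 21 fallers and 39 non-fallers;
* every variable of the published descriptive tables with its printed
  group means and SDs — 13 baseline characteristics, two binary impairment
  indicators, and the 51 multi-domain assessment variables
  (11 balance, 11 gait, 5 clinical, 14 strength, 10 body composition);
* nuisance variables with no group effect filling each domain to its full
  collected size (52/99/10/70/34; these per-domain totals are configurable
  because the published per-domain counts do not exactly sum to the quoted
  281, so the remainder is left as generator configuration);
* block dependence on the latent normals: within-domain $r = 0.6$,
  strength–body-composition cross-correlation 0.7, balance weakly coupled
  (0.1) to everything else, and moderate gait–clinical/gait–strength
  coupling (0.4) — levels chosen once to echo the published correlation
  heat-map pattern (strength and body composition nearly collinear, balance
  nearly separate, gait moderately tied to strength). A cross-block level
  exceeding the within-block level makes the assembled matrix indefinite
  for blocks this large; the generator validates eigenvalues and applies a
  nearest-PSD repair, reporting it via the `psd_repaired` attribute rather
  than silently;
* binary variables by thresholding their latent normal at the group's
  probability quantile (a Gaussian-copula construction — the published
  tables give only marginals, so the dependence structure is an explicit
  modelling choice);
* 2% missing cells, missing completely at random, injected into continuous
  cells only (the published analysis does not characterize its missingness
  mechanism, so MCAR is the default and the rate is configuration).

`generate_trial_level` additionally emits per-step gait series: each
participant's five steps scatter about their latent level with additive
Laplace(b) noise, chosen because the MAD of a Laplace(b) variable is
$b\log 2$ in closed form, giving the percentage-MAD formula a known target
in tests.

**What the generator does not emulate.** Marginals are Gaussian (real
posturographic and variability measures are right-skewed), dependence is a
homogeneous block pattern rather than the full empirical correlation
matrix, missingness is MCAR, and there is no measurement-session or
learning-effect structure. Tests passing on this cohort therefore
demonstrate that the pipeline's machinery is correct and well calibrated —
not that its discrimination estimates transfer to any particular clinical
population. The published headline metrics (e.g. AUC 0.92 for the full
multi-domain logistic model) depend on the original cohort's raw data and
are deliberately not targets; the synthetic analogue is required instead to
discriminate clearly (in-sample AUC > 0.8) and to generalize above the
no-information rate under LOOCV.

# Numerical and design choices

* **Group coding** is faller = 1, non-faller = 0 everywhere, so effect
  signs, latent-score orientations and classifier outputs agree across
  modules.
* **Standardization before PLSCA** is required, not implicit:
  `cross_correlation` rejects unstandardized blocks instead of silently
  rescaling, and missing cells must be imputed before any SVD (no pairwise
  deletion inside a decomposition).
* **Missing-data encoding**: empty strings in CSV, an explicit logical mask
  in memory, exact round-tripping guaranteed by full-precision writes.
  Domain tags travel in a metadata sidecar CSV so the data file stays a
  plain numeric table.
* **Determinism**: every stochastic stage (generation, forests,
  permutations, PPCA initialization) takes an explicit seed; the pipeline
  derives per-stage seeds from the master seed so a full run is a pure
  function of (input table, configuration).
* **Degenerate inputs** are errors, not silent coercions: constant columns
  in z-scoring, single-group tables, zero margins in 2x2 counts, singular
  correlation matrices in Bartlett's test, all-zero cross-correlation in
  PLSCA, fewer distinct scores than Jenks classes, onset thresholds never
  crossed.
* **Baseline logistic models** are only fitted in a single-domain analysis
  when the variable count is well below the participant count; with
  $p \ge n$ the likelihood is unbounded, which is the very motivation for
  the importance-based refinement.
* **Problem sizes in the test suite.** The acceptance checks run the full
  pipeline on the fixture cohort at its study scale (60 participants,
  265 assessment variables, 199 permutations for between-domain p-values),
  property suites use 20–100 random instances per identity, and the
  Welch size calibration uses 10,000 null simulations; unit tests use
  smaller cohorts so the complete suite stays fast.

# Known limitations

* PPCA provides single imputation; downstream classifiers treat imputed
  cells as observed, so imputation uncertainty is not propagated.
* The Jenks cut assumes the importance scree really has two regimes; on a
  flat scree the 2-class optimum is arbitrary, which is why the manual
  override exists.
* The permutation p-value for a refined variable set is computed after
  selection on the same data and is therefore optimistic; it is reported
  as a descriptive quantity of the fitted model, not a confirmatory test.
* OOB error and LOOCV estimate generalization under the sampling model of
  a single cohort; they do not address transportability across populations
  or instrumentation.
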