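# fallscreen

Multi-domain variable importance and classification for falls-risk
screening in older adults.

## What problem this solves

Falls screening studies collect far more measurements than participants:
static-balance posturography, gait kinetics/kinematics, clinical mobility
tests, isometric and isokinetic strength, and DXA body composition easily
yield hundreds of strongly intercorrelated variables for a cohort of a few
dozen older women. Ordinary logistic regression cannot be fitted to such a
table (p >> n), and univariate rankings drown in redundancy. `fallscreen`
is for biostatisticians and movement scientists who need a reproducible,
tested implementation of the two-stage machine-learning strategy for this
setting:

1. **Single-domain stage** — partition the table into five "data packages"
   (balance, gait, clinical, strength, body composition); within each, rank
   variables by two engines — random-forest mean decrease in the Gini index
   and leave-one-variable-out (LOVO) PLSCA inertia decrease — cut each
   scree with the exact Fisher–Jenks natural-breaks optimum, and take the
   union of the two selections.
2. **Multi-domain stage** — pool the per-domain selections, impute missing
   cells by probabilistic PCA (EM with a monotone observed-data
   likelihood), repeat the dual ranking/selection, and fit three
   classifiers on the refined set: a PLSCA latent-score classifier, a
   500-tree random forest validated out-of-bag, and logistic regression
   with backward AIC/BIC refinement and leave-one-out cross-validation.
   PLSCA applied between domain blocks quantifies their shared information.

At the core is partial least squares correlation analysis: for
column-standardized blocks `X`, `Y`, the SVD of the cross-correlation
matrix `R = XᵀY/(n−1) = UΛVᵀ`. The singular-value inertia `Σ λ_k²`
(untruncated, `= ‖R‖_F²`) measures shared information; a variable's LOVO
importance is the inertia drop when its column is left out (equal to the
dropped column's squared norm in `R`), and participants' projections on the
first salience are the PLSCA classifier's decision scores. Between-domain
inertia is normalized by the summed block sizes, `inertia/(p_a + p_b)`,
with permutation p-values.

Because no participant-level data are distributable, the package includes a
synthetic cohort generator whose built-in configuration encodes the study
conditions (21 fallers / 39 non-fallers, the printed group means and SDs of
all 51 multi-domain variables plus baseline characteristics, block
multicollinearity, 2% MCAR missingness), so the whole pipeline is testable
end to end.

## Worked example

```r
library(fallscreen)

# Univariate worked example: the age contrast from printed group summaries
gs <- group_summary(21, 71.52, 4.33, 39, 68.87, 3.41)
round(cohens_d(gs), 2)        # 0.71  (pooled-SD effect size)
round(welch_t(gs)$p, 2)       # 0.02  (Welch two-tailed p)

# Full pipeline on the built-in synthetic cohort
cfg <- builtin_fixture_config(seed = 1)
ft  <- generate_cohort(cfg)
ft
#> feature_table: 60 participants (fallers = 21, non-fallers = 39) x 280 variables
#> domains: balance = 52, gait = 99, clinical = 25, strength = 70, body_composition = 34
#> missing cells: 335 (2.0%)

sub <- select_variables(ft, assessment_variables(cfg))
res <- run_pipeline(sub, run_config(seed = 1, permutations = 199))
res$multi
#> multi-domain report: package of 61 variables, refined set of 16
#> refined variables:
#>  [1] "mgs_step_length_index"  "ugs_step_length_index"
#>  [3] "mad_ugs_time_to_midstance_peak_force_pct"  "poma_balance_score"
#>  ...
#> PLSCA AUC 0.90 (inertia 3.34, permutation p 0.005); RF AUC 0.94
#> logistic AUC 1.00 (LOOCV 98%); refined logistic AUC 1.00 (LOOCV 93%) (criteria agree: TRUE)
#> normalized between-domain inertia:
#>                  balance gait clinical strength body_composition
#> balance               NA 0.09     0.04     0.15             0.13
#> gait                0.09   NA     0.48     1.57             0.82
#> ...
```

Reading the output: the single-domain analyses fed 61 variables into the
multi-domain package; the dual Jenks selection refined them to 16, led by
the step-length indices and gait-variability measures that the generator
plants with the largest standardized group differences. The refined
logistic model separates the synthetic cohort essentially perfectly
in-sample (AUC 1.00) and holds a 93% leave-one-out accuracy, well above the
65% no-information rate; the between-domain table shows the planted
structure — strength and body composition share by far the most information
(3.65), balance is nearly decoupled from everything else.

`write_report(res$multi, "out/")` writes the univariate screen, both
importance rankings, the refined set with provenance, ROC curves, the
between-domain table and a YAML summary.

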