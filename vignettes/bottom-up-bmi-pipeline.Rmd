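---
title: "Bottom-up trait scales for predicting body mass: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bottom-up trait scales for predicting body mass: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Personality questionnaire items relate to body mass index (BMI, kg/m^2) in
ways that standard inventory aggregates (domains, facets) blur: items within
the same facet can correlate with BMI in opposite directions, so aggregating
first and correlating later loses signal. A bottom-up alternative starts from
individual items, keeps only the ones whose BMI correlations replicate across
independent samples, aggregates them into empirically derived factors for
description, and winnows them into brief scales for prediction.

The practical complication is planned missingness. Large item pools are
administered SAPA-style: each respondent answers a random subset of the pool,
so the person x item matrix is ~87% missing, completely at random by design.
Every stage of the pipeline must therefore work from pairwise-complete
statistics, and sample sizes vary per item, per item pair, and per factor.

`traitmap` implements the full pipeline over tables of 1-6 Likert responses
plus BMI, age, sex, and continent, together with a synthetic-data generator
with known ground truth so that every stage is testable without external
data.

## The generative model behind the synthetic cohorts

`generate_dataset()` draws, per person, latent trait scores `f ~ N(0, I_k)`
and forms continuous item propensities

    u_ij = lambda_j' f_i + c_j' d_i + e_ij,   e_ij ~ N(0, 1 - ||lambda_j||^2),

where `lambda_j` is item j's loading row, `d_i` the covariate vector (age,
age^2, sex, continent indicators) and `c_j` optional covariate effects
(centered at generation, zero by default). Because `u_ij` has unit variance,
responses are discretized by fixed standard-normal quantile cut-points into
six equal-mass categories. The response distribution of real questionnaire
items is not specified by the design being emulated, so equal mass is the
neutral choice; the generator makes no attempt to match real item marginals
beyond the 1-6 support.

BMI is linear in the traits:

    BMI_i = b0 + w' f_i + (covariate effects, centered) + eps_i,
    eps_i ~ N(0, noise_sd^2),

with `b0 = 25` kg/m^2 by default (a typical population mean) and
`noise_sd = 4`, giving a BMI SD near 4.5 once trait effects are added. Age is
right-skewed on [14, 89] with mean ~26.5 (shifted gamma), sex is ~62% female,
and continents put ~75% mass on North America -- the demographic profile of
large online SAPA collections. Height and weight are generated consistently
with BMI so that `bmi = weight_kg / (height_cm/100)^2` holds exactly.

Each response is then deleted independently with probability `missing_rate`
(default 0.875, matching the 87-88% missingness of real SAPA datasets). The
deletion is completely at random: missingness is independent of responses,
BMI, and covariates, and the test suite checks this. What the generator does
*not* emulate: non-MCAR mechanisms, item wording effects, near-duplicate
items, acquiescence or other response styles, and measurement error in
self-reported height and weight. Passing tests therefore demonstrate that
the *procedures* behave correctly under the design's sampling scheme, not
that real data meet the design's assumptions.

Ground truth (trait scores, loadings, outcome weights) travels as an
attribute and a YAML sidecar file, never as columns of the analysis-facing
table.

## Stage by stage

### Exclusions and residualization

`apply_exclusions()` removes persons with missing BMI, age, sex, or
continent, and persons with implausible BMI; the kept interval is
`[bmi_min, bmi_max)` with defaults 14 and 75, i.e. exclusion is
`bmi < 14 | bmi >= 75`. The filter is idempotent and logs per-reason counts.

`residualize()` regresses every item and BMI, independently, on an intercept,
age, age^2, a sex indicator, and continent one-hot indicators (most frequent
level as reference -- residuals are invariant to the coding), each variable on
its own non-missing rows, and replaces values by residuals. Missingness
patterns are untouched. Rank-deficient designs are handled by pivoting; a
variable with fewer observed rows than design columns becomes all-missing
with a warning. Two modes are used downstream: per-dataset residualization
for the dual-sample screening stage, and pooled residualization (after
`combine_tables()`) for combined-sample correlations, factor scoring, and
winnowing.

### Item screening

`item_outcome_correlations()` computes pairwise-complete Pearson correlations
of each item with residualized BMI; the two-sided p-value uses
`t = r sqrt((n-2)/(1-r^2))` on `n - 2` df. Records with fewer than `min_n`
complete pairs (default 30) are invalid: the design never states a floor, but
with 87% missingness some pairs are tiny and their correlations unstable.
`select_consistent_items()` keeps items with `p < alpha` (default .05) *and*
the same correlation sign in both datasets. No multiple-testing correction is
applied -- the lenient threshold is deliberate, because the dual-dataset
consistency requirement is itself the false-positive control: under the null
the per-item selection probability is `2 (alpha/2)^2 = 0.00125`, and the test
suite verifies this calibration by simulation. Sign agreement is evaluated on
point estimates, not confidence intervals.

Statistical power for a correlation `r` at sample size `n` uses the Fisher-z
approximation,

    power = Phi(atanh(|r|) sqrt(n-3) - z_{1-alpha/2})
          + Phi(-atanh(|r|) sqrt(n-3) - z_{1-alpha/2}),

which returns exactly `alpha` at `r = 0`. Exact noncentral-t power is not
implemented; the approximation reproduces the low-power flags of a published
14-factor summary table exactly (all 28 factor and lead-item entries), which
the acceptance suite checks.

### Factor construction

`build_corr_matrix()` forms the pairwise-complete correlation matrix of the
selected items. Under pairwise deletion such matrices are frequently
indefinite; when the smallest eigenvalue is below -1e-8 the matrix is
repaired by clipping eigenvalues (at a 1e-6 floor, slightly above zero so
that maximum-likelihood factoring remains well-posed), reconstructing, and
rescaling to unit diagonal. The repair is flagged in the result.

`parallel_analysis()` chooses the factor count k by comparing observed
eigenvalues against eigenvalues of null datasets built by permuting each
item's observed values within its own missingness pattern, reduced to a
pairwise correlation matrix identically to the observed data. The default
reference is the per-rank *mean* of the null eigenvalues (Horn's original
proposal); a 95th-percentile reference is available via `quantile = "p95"`.
The choice matters under pure noise: with the mean reference, the observed
first eigenvalue and the null eigenvalues are identically distributed when
there is no structure, so k = 0 only about half the time; the percentile
reference keeps the no-structure error rate near 5% per rank. With real
planted structure the two agree, and the retained count is the initial run
of eigenvalues exceeding the reference.

`extract_ml_factors()` delegates the maximum-likelihood fit to
`stats::factanal()` (no rotation), with uniquenesses bounded below at 0.005
as the Heywood guard. The effective sample size attached to the fit is the
harmonic mean of the off-diagonal pairwise counts -- a conservative summary
when every pair has its own n; it affects only fit statistics, not the
estimates.

`rotate_oblimin()` implements direct oblimin (gamma = 0, i.e. quartimin) via
the Bernaards-Jennrich gradient-projection algorithm for oblique rotation,
written in-package. Convergence is declared when the projected gradient norm
falls below 1e-6. Columns are sign-aligned so each factor's
largest-magnitude item loads positively. Rotation preserves communalities
(`diag(Lambda Phi Lambda')` equals the unrotated row sums of squares), which
the tests assert to 1e-6, and planted orthogonal simple structure is
recovered with Tucker congruence >= .98.

`assign_items()` maps each item to its primary (largest-magnitude) loading,
discarding items below |.30|; exact magnitude ties go to the lower-index
factor and are logged.

### Cross-sample replication

`match_factors()` pairs factors across the two solutions by absolute Tucker
congruence with greedy one-to-one assignment (largest first; minimum .70 to
accept a pair). The design being implemented only says that factors found in
one dataset are excluded, without a matching rule; greedy congruence
matching is the transparent choice and every accepted pair's congruence is
reported. Items must be assigned to the same matched pair in both solutions
to survive. For survivors, the squared loading difference
`d^2 = (loading_A - loading_B)^2` flags volatile items at `d^2 >= .04`
(inclusive -- the boundary is tested exactly at a representable value), and
the Pearson correlation of matched loadings summarizes overall similarity.

`vet_factors()` then applies, in order: the 3-item floor; a split of any
factor whose members correlate with BMI in mixed directions into two
sign-homogeneous factors (each re-checked against the floor); a drop of
factors whose *scored* correlation with BMI falls below `negligible_r`
(default .02, chosen so that a factor reported with r = .01 would be
excluded); and a manual exclusion list -- "no clear interpretation" is a human
judgement, and the package never automates it.

`score_factor()` averages a person's available member items after reversing
negatively keyed members (keys follow the sign of the loading on the matched
factor); persons with fewer than three observed members get no score. The
factor summary table reports, per factor, the member count, lead item (the
member with the strongest BMI correlation), scoreable n, factor and lead-item
correlations computed in the same subsample, and low-power flags.

### Winnowing

`winnow()` iteratively removes, from the currently most intercorrelated item
pair, the member with the weaker BMI correlation, until no remaining pair
exceeds the criterion. Both "most intercorrelated" and "weaker" are evaluated
on absolute correlations -- the verbal rule ("stronger", "higher") is
magnitude language. Correlations are never recomputed after removals, because
deleting an item does not change the remaining pairwise correlations. Ties on
pair magnitude break by lexicographic item-id pair order; ties on outcome
relevance remove the lexicographically later item. The removal trace is part
of the result, so a winnowed set can be audited and replayed. A direct
consequence of the greedy rule is that the removal sequence for a looser
criterion is a prefix of the sequence for a stricter one, so surviving set
sizes are monotone in the criterion; the tests verify both the monotonicity
and exact agreement with a naive full-re-scan oracle. Winnowing operates on
the pooled (combined-dataset) residualized correlations.

### Elastic-net prediction

`fit_elastic_net()` minimizes

    (1/2n) sum_i (y_i - b0 - x_i' b)^2 + lambda (alpha ||b||_1 + (1-alpha)/2 ||b||_2^2)

with `alpha = .50`, over a 100-point log-spaced lambda grid from
`lambda_max = max_j |x_j' y| / (n alpha)` down to `lambda_max * 1e-4`,
choosing lambda at the minimum mean 10-fold cross-validated squared error.
Folds are assigned by a seeded shuffle; the seed is a required argument, so
there is no hidden randomness. Fitting is delegated to glmnet with this
exact grid and no internal standardization.

Two numerical choices deserve note. First, missing predictors are imputed as
0 before standardization -- 0 is the mean of a residualized variable, so this
is mean imputation, the minimal-assumption way to let 87%-missing items
enter a regression; it attenuates weights toward zero in proportion to
missingness, which is the main reason out-of-sample accuracy under planned
missingness sits far below the complete-data ceiling. Second, the outcome is
standardized to zero mean and unit (1/n) variance inside the fit and
predictions are transformed back. This makes the penalized objective exactly
the one stated above on a scale-free problem (glmnet's internal outcome
scaling otherwise rescales the ridge term by sd(y)), and the tests verify
the fitted coefficients against soft-threshold stationarity (KKT) conditions
at 1e-4. Reported weights live on the standardized predictor/outcome scale;
accuracy (the Pearson correlation between prediction and observed BMI in an
independent test sample, with a Fisher-z 95% CI) is invariant to the
transform.

`compare_variable_sets()` trains one model per named predictor set -- raw
item columns or scored factor/domain/facet keys -- on the single shared
training subsample in which every set has at least one observed predictor
per person, so that no set benefits from a larger training n, and reports
per-set accuracy plus mean/median/range of the absolute predictor-BMI
correlations.

### Decile stratification

`stratify_deciles()` ranks test persons by predicted BMI (ties broken by
stable input order), partitions them into ten groups with sizes differing by
at most one, and reports per-decile means of observed BMI (and weight, taken
from per-person observed weight, never converted from BMI via an average
height). The headline statistic is the top-minus-bottom decile gap;
`decile_trend_test()` adds a Spearman test of decile index against decile
mean. With predictions of modest accuracy the middle deciles separate
poorly while the tails still differ -- the pattern the gap statistic is
designed to capture.

## Problem sizes

The analysis scripts under `analysis/` run a desk-scale version of the
design: three cohorts of 20,000 / 18,000 / 10,000 persons, 120 items on 8
latent traits (4 linked to BMI), 87.5% missingness. The test suite's
end-to-end checks use 500 null items at n = 10,000 over 20 seed pairs for
screening calibration, and five planted factors (8 items each, loadings
.55-.75, 50% missingness, n = 20,000) over 10 seeds for factor recovery --
sizes at which the Monte-Carlo error of the checked quantities is small
relative to their tolerances. These sizes are the package's choices for
demonstration and verification; nothing in the implementation depends on
them.

## Known limitations

- Missingness is handled by pairwise deletion plus zero-imputation, not by
  joint-model estimation; both are exactly what the implemented design
  prescribes, but neither is efficient.
- The MCAR assumption is structural: the pipeline has no diagnostics for
  informative missingness.
- Interpretability vetting of factors is configuration, so fully unattended
  runs keep every replicated factor regardless of whether a human could name
  it.
- Power uses the Fisher-z approximation; for n below ~20 it is rough.
- The elastic-net mixing parameter is fixed at .50 by design; no alpha
  search is provided.
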