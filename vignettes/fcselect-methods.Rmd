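---
title: "Robust FC selection: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust FC selection: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Case-control resting-state studies summarize each subject by a vector of
functional connections (FCs): Fisher-z-transformed Pearson correlations
between every pair of brain-region time courses, `R(R-1)/2` values for `R`
regions (71,631 for a 379-region parcellation). With a few hundred
subjects and tens of thousands of features, supervised feature selectors
face two systematic hazards. First, selectors optimized for prediction
prefer high signal-to-noise features, which in multi-site data are often
features driven by *site* rather than by diagnosis; such selections
collapse when audited in an independent cohort. Second, single FCs are
individually unreliable, so mass-univariate selections are unstable
across cohorts.

`fcselect` implements an unsupervised alternative: select FCs through a
principal component that carries the diagnosis signal, rather than
through per-feature discriminative power.

## The selection pipeline (`pcafs()`)

1. **PCA.** The subjects x features Fisher-z matrix is column-centered
   and decomposed by SVD. Features are *not* standardized: they already
   share the Fisher-z scale, and rescaling would inflate the influence of
   low-variance features. At most `n - 1` components exist after
   centering. Each component's sign is fixed by making its
   largest-magnitude weight positive; this is purely cosmetic, since all
   downstream direction labels derive from group means.
2. **Screening.** Every component's subject scores are tested against
   each phenotype factor: two-sample t-tests for binary factors
   (diagnosis, sex), Pearson correlation for continuous ones (age,
   symptom score, mean framewise displacement), one-way ANOVA for
   imaging site. p-values are Benjamini-Hochberg corrected *within each
   factor* across components, at `q = 0.05` by default. The t-tests use
   the pooled-variance form by default (`welch = TRUE` switches), since
   PC scores within a decomposition share a common scale.
3. **Component choice.** Among components significant for diagnosis, the
   one with the largest explained variance is chosen; ties (a
   measure-zero event) go to the lower index with a message. If none is
   significant the fit is a *null result*: a valid outcome with no
   selected features, which is exactly what happens on label-independent
   data roughly `1 - q` of the time.
4. **Weight selection.** The chosen component's weights are z-scored
   with their own sample mean and SD. Because the weight vector has unit
   norm, the sample SD essentially equals the theoretical `1/sqrt(m)` of
   an uninformative loading, so the two standardization conventions
   coincide; the sample SD is used and is additionally robust to a few
   dominant weights. Each feature gets a two-tailed standard-normal
   occurrence probability (two-tailed because both over- and
   under-connectivity are of interest), and the BH step-up at `q` over
   all features gives the selected set. An "aggressive" percentile mode
   (`mode = "percentile"`) instead keeps the top share of `|z|`; it
   exists to supply larger feature sets to classifiers, not for
   inference.
5. **Direction labels.** A selected FC is over-connectivity when the
   patient-group mean exceeds the control-group mean, under-connectivity
   otherwise; exact ties are labelled "under" and reported. Labels are
   therefore invariant to the PCA sign convention.
6. **Projection.** `predict()` scores new subjects on the discovery
   component after centering them with the *model's* feature means --
   never the new cohort's own means, which would leak its structure into
   the projection.

```{r}
library(fcselect)
sim <- gen_clinical_dataset(clinical_sim_config(seed = 7))
fit <- pcafs(sim$fc, sim$pheno)
summary(fit)
```

## FC construction from time series

`fc_vector()` and its helpers reproduce a standard rs-fMRI
post-processing chain on ROI time courses: nuisance regression (least
squares against supplied regressors plus an intercept; minimum-norm with
a warning if the design is rank-deficient), first-order Butterworth
bandpass 0.01-0.08 Hz applied forward-backward so filtering is
shift-invariant (with odd-reflection padding, because the low band edge
has a time constant of minutes and unpadded IIR transients would
contaminate short runs), motion scrubbing that censors frames with
framewise displacement strictly above 0.5 mm, and Pearson correlation +
`atanh` on the retained frames. The processing order
(regress, filter, scrub, correlate) is fixed and documented rather than
inferred: scrubbing last keeps the filter operating on a regularly
sampled series. Correlations of exactly +/-1 raise an error naming the
pair; a `tolerant` flag clips to `1 - 1e-7` instead, off by default
because perfect correlations almost always mean a duplicated or
degenerate region. Feature order is fixed bit-exactly, column-major over
the strict lower triangle, i.e. `M[lower.tri(M)]`, with 1-based
positions in the R API.

Run-level exclusion follows two rules: censored fraction above the
mean + 3 SD across runs, or less than 4 minutes of retained data.

## Harmonization

`combat_fit()`/`combat_apply()` implement the parametric empirical-Bayes
location/scale batch model with biological covariates (diagnosis, age,
sex) protected through the regression design: covariate effects are
estimated jointly but only the site location/scale adjustment is ever
removed. The nonparametric EB variant is not implemented. The fit/apply
split exists so a model can describe one table and harmonize another;
`combat_apply()` estimates site location/scale on the data it is given,
in the model's standardized space, and shrinks them toward the model's
EB priors. Under this semantics harmonizing an already harmonized table
is a no-op (exactly so with `eb = FALSE`, numerically so with
shrinkage). With `eb = FALSE` and no covariates the whole procedure
collapses to per-site standardization mapped back to the pooled
location and scale -- a useful closed form for testing, and the mode in
which site means are equalized exactly rather than up to shrinkage
residue.

`traveling_bias_estimate()` uses the fact that the same participants were
scanned at several sites: the additive two-way fit
`value = participant + site + residual` (run-count-weighted sum-to-zero
constraint on sites, identifiability guarded by a connectivity check on
the participant-site incidence graph) separates pure measurement bias
from participant identity. This is a deliberate simplification of full
traveling-subject GLM harmonization: sampling bias and protocol terms are
folded into the residual, and the output is flagged accordingly.

## Baselines and the diagnostic marker

`ttest_select()` is the mass-univariate baseline: per-feature pooled
two-sample t-tests with BH, Bonferroni, or no correction.
`lasso_select()` is the regularization baseline: repeated balanced
subsampling (undersampling the majority class), an L1-penalized
*logistic* fit per subsample with the penalty chosen by internal 10-fold
cross-validation, and majority-vote selection across subsamples. The
penalty rule defaults to the one-standard-error choice (`lambda.1se`,
the `coef.cv.glmnet` default), which yields the sparse, stability-style
selections this baseline is meant to represent; `ensemble_fit()`, whose
members exist to predict rather than to select, defaults to the
prediction-optimal `lambda.min`. Subsample count, balancing rule, and
aggregation (averaged member probabilities) are package defaults and are
all configurable.

`ensemble_fit()` accepts an `inner_selector` hook that runs *inside*
each member's training subsample, so feature computation and extraction
never see held-out subjects. The test suite enforces this with a
sentinel probe: a feature equal to the held-out labels planted only in
test rows must not raise validation AUC. Performance metrics are AUC by
the rank statistic (ties counted half), plus accuracy, sensitivity,
specificity, and Matthews correlation at the decision threshold.

## Effect-size audits

`hedges_g()` computes the standardized patient-minus-control mean
difference with pooled SD and the small-sample factor
`J = 1 - 3/(4N - 9)`; plain Cohen's d is available by flag.
`effect_summary()` tabulates mean/median/SD of the selected features'
`|g|` per dataset -- absolute values by default because selections mix
over- and under-connectivity; signed summaries are a flag away.
`cross_dataset_consistency()` is the plain Pearson correlation of two
per-feature g vectors, and `selection_overlap()` a set intersection
(for context, two random selections of sizes 78 and 65 in 71,631
features overlap by about 0.07 features in expectation).

## Traveling-subject variance decomposition

`factor_variability()` fits, per feature, the additive model
`value = grand mean + participant + scanner + protocol + residual` by
least squares with sum-to-zero contrasts (one shared design, all
features in one pass). The variability attributed to a factor is the SD
of its fitted level effects; the session factor is the residual SD.
This "SD of level effects" definition is an explicit approximation to
full traveling-subject variance modelling and is labelled as such in the
object metadata. Its bias properties are predictable: a factor with few
levels underestimates its SD slightly (the `c4` bias of a small-sample
SD), and estimation noise in the level effects inflates it by roughly
`residual^2 / runs-per-level`; at the shipped design sizes both effects
stay within a few percent, well inside the 20% recovery tolerance the
tests assert.

## What the synthetic generators emulate

`gen_clinical_dataset()` draws Fisher-z features directly (no
time-series simulation is needed to exercise selection):

* a **sparse latent disorder component**: `n_disorder_fcs` features (50
  of 1,000 by default) carry a subject factor
  `t = disorder_effect * patient + latent_sd * N(0,1)`. The group shift
  defaults to 0.8 and the within-group factor SD to 0.6 of the feature
  SD. The within-group term matters: patients vary in severity, and a
  "component" with zero within-group variance would place the planted
  eigenvalue at the random-matrix bulk edge at desk scale (n = 400,
  m = 1,000), where eigenvector recovery is information-theoretically
  marginal. Residual noise on the planted features is rescaled so their
  total SD stays at `noise_sd`, which keeps the empirical Hedge's g
  calibrated to `disorder_effect` regardless of `latent_sd`. The symptom
  score is generated from the same latent factor.
* **site structure mirroring the ComBat model**: per-(site, feature)
  additive offsets (SD 0.1) and log-normal noise scales, so
  harmonization is testable against its own generative assumptions.
* **covariate components**: age and sex load on random unit-norm feature
  directions with configurable magnitudes.
* an optional **diffuse disorder tail**: independent per-feature group
  shifts of SD `diffuse_effect_sd`, emulating the broad mass of small
  true effects in real case-control data; a consistency knob correlates
  the discovery and validation tails.
* an optional **site-confounded distractor block**
  (`confounded_distractor`): 50 low-noise features carrying a site-1
  offset while site 1 is assigned to patients with probability 0.95.
  In the cohort that has it, these features show enormous effect sizes;
  in a cohort without it they are noise. `sim_confounded_pair()` ships
  the standard such pair (distractor in discovery only, diffuse tail SD
  0.18, consistency 0.8); it is the regime in which supervised selectors
  overfit -- LASSO's selections are dominated by the distractor block and
  lose most of their effect size in validation, while the PCA route keys
  on the (higher-variance) true component and generalizes.

`gen_traveling_subject()` emulates a hub-and-spoke traveling-subject
campaign: 75 participants, 12 sites, each participant visiting one of 3
hub sites plus spokes, 2 runs per visit. Sites determine scanner type
and protocol through cyclic assignments with coprime periods (5 scanner
types, 3 protocols), so the two factors are never confounded. Runs are
sums of per-level effect vectors drawn with the configured SDs; defaults
(participant 0.17, scanner 0.06, session 0.19, protocol 0.05) use the
magnitudes reported for disorder-relevant FCs in large traveling-subject
studies. `sd_noise` defaults to 0 so the session factor *is* the
run-level residual the decomposition reports.

What the generators do **not** emulate: real FC covariance structure
(beyond the planted components, features are independent), BOLD
autocorrelation, head-motion artifacts, atlas geometry, and outcome
heterogeneity across disorders. Passing tests therefore demonstrate
that the algorithms do what they claim under their own assumptions --
not that any particular clinical finding is reproduced.

## Numerical choices and degenerate inputs

* Scrubbing uses strict inequality (`FD > threshold` censors).
* BH-FDR delegates to `stats::p.adjust(method = "BH")`; the rejection
  set is verified against a brute-force step-up enumeration in the
  tests.
* Constant features are legal in PCA (they receive zero weight); a
  component whose weights are all equal raises an error in
  `select_features()` rather than silently selecting nothing.
* `combat_fit()` refuses single sites, sites with fewer than two
  subjects, and site/covariate designs that are rank-deficient (naming
  the collinear columns). Features with zero residual variance are an
  error, not a silent skip.
* The EB iteration matches the standard parametric ComBat update with
  relative-change convergence at `1e-4`.
* Degenerate classifier evaluations (single-class test labels) raise an
  error rather than returning an undefined AUC.

## Problem sizes

The test suite and the acceptance script run at desk scale, chosen as
the package's standard verification sizes: 1,000-feature cohorts of 400
subjects for recovery and robustness, 200 replicate null cohorts for the
family-level null-control rate, a 9 x 12 x 2 complete traveling design
for bias recovery, and the 75-participant hub-and-spoke design (450
runs) for the variance decomposition. The full 71,631-feature scale is
supported (`n_rois = 379`) but is not the default.

## Known limitations

* The traveling-subject harmonization and the variance decomposition are
  simplified additive models, documented as approximations.
* `combat_apply()` with covariates requires the new cohort's covariates
  to rebuild protected means; calling it without them standardizes
  around the grand mean only (with a warning).
* PCA maximizes variance, not biological relevance; the chosen
  component's explained variance is necessarily small in a
  high-dimensional FC space, and the method inherits PCA's inability to
  distinguish biological from structured non-biological variance when
  both load on the same component.
* The ensemble classifier is a plain subsampled L1-logistic; no
  calibration, elastic net, or nonlinear members.
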