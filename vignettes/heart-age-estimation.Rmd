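---
title: "Estimating biological heart age and its correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating biological heart age and its correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heartage)
```

## The problem

Cardiac structure and tissue character change with age in measurable
ways. Given a panel of radiomics descriptors extracted from segmented
cardiac magnetic resonance images — shape features of the left ventricle
(LV), right ventricle (RV) and LV myocardium, plus first-order and
texture features of the myocardium — one can train a model that predicts
chronological age and read the residual as a biomarker: a heart that
looks older than its owner gets a positive **heart-age delta**, one that
looks younger a negative delta. The delta can then be screened against a
broad catalogue of exposures to ask what accompanies accelerated cardiac
aging.

This vignette explains the model, the corrections, and the design
decisions behind the package; the README shows the mechanics.

## The age model

Within each sex stratum, the features are first residualized on height
and weight — per-column ordinary least squares with intercept — and
standardized to zero mean and unit variance. Ages are then regressed on
the standardized residuals with a Bayesian ridge:

$$y = Xw + \varepsilon,\qquad w \sim N(0, \lambda^{-1}I),\qquad
  \varepsilon \sim N(0, \alpha^{-1}I),$$

with Gamma hyperpriors on both precisions (shape and rate $10^{-6}$,
effectively flat). The precisions are chosen by evidence maximization
(type-II maximum likelihood): iterate the closed-form posterior
$S = (\lambda I + \alpha X^\top X)^{-1}$,
$m = \alpha S X^\top y_c$ (with $y_c$ the centred response), the
effective degrees of freedom
$\gamma = \sum_j \alpha\ell_j/(\lambda + \alpha\ell_j)$ over the
eigenvalues $\ell_j$ of $X^\top X$, and the updates
$\lambda \leftarrow (\gamma + 2s_1)/(m^\top m + 2s_2)$,
$\alpha \leftarrow (n - \gamma + 2r_1)/(\lVert y_c - Xm\rVert^2 + 2r_2)$,
until the maximum absolute weight change falls below $10^{-3}$ (cap 300
iterations; hitting the cap flags the fit rather than erroring). The
eigendecomposition of $X^\top X$ is computed once and reused, which
matters at $p = 254$. The log marginal likelihood is traced per
iteration and is non-decreasing to within $10^{-6}$; a unit test asserts
this. Ridge shrinkage is what makes the model workable on radiomics
panels, whose features are heavily intercorrelated.

The ridge was chosen over alternatives with tunable hyperparameters
precisely because the evidence updates need no held-out tuning set:
plain k-fold cross-validation (default $k = 10$) produces exactly one
out-of-fold prediction per participant, and all participants are carried
into the downstream analyses.

## Regression-dilution bias and its correction

Any regression-based age estimator shrinks predictions toward the
training mean: young ages are overestimated, old ages underestimated, so
the raw delta correlates strongly and negatively with age (about −0.64
on the package's synthetic cohorts). Per fold, the package fits the line
of the training-set delta $D$ on actual age $\Omega$,

$$D = \alpha\Omega + \beta,$$

and subtracts it from the held-out predictions:

$$\mathrm{CPHA} = \text{predicted} - (\alpha\Omega + \beta),$$

the corrected predicted heart age. The delta is
$\mathrm{CPHA} - \text{age}$. Two points were genuinely open and were
resolved as follows:

* **Where the line is fitted.** The correction line is fitted on the
  deltas the fold's own model produces on its own training data, and no
  cross-fold averaging of $(\alpha, \beta)$ is done. Because training
  (in-sample) deltas are slightly less shrunk than validation deltas,
  the fitted slope underestimates the out-of-fold bias by a term of
  order $p/n$; on pooled validation folds the residual delta–age
  correlation is about $-0.02$ at $n = 10{,}000$ and $-0.015$ at the
  study-scale stratum of $15{,}920$, against $-0.64$ uncorrected. An
  inner cross-validation loop inside each training set would remove the
  remaining term at ten times the cost; it is deliberately not the
  default.
* **Which predictions the headline metrics describe.** The reported MAE
  and $R^2$ are computed on the corrected predictions pooled over
  validation folds (per-fold values are retained in the fitted object);
  the correlation of predicted with actual age is reported for both
  corrected and uncorrected predictions, since the uncorrected one is
  what the shrinkage phenomenon shows up in.

One degenerate property is worth knowing: if the features carry *no*
age signal, predictions collapse to the training mean, the fitted bias
line has slope near $-1$, and the "corrected" prediction reconstructs
actual age almost exactly — corrected $R^2 \to 1$ while the uncorrected
$R^2 \le 0$. Corrected metrics are therefore only meaningful alongside
the uncorrected ones, and the null-model test in the suite asserts on
the uncorrected $R^2$.

## Deconfounding: fidelity versus hygiene

The published analysis residualizes and standardizes the features once
on the full sample *before* cross-validation, which leaks the
standardization moments across folds. The package's default
(`mode = "paper"`) replicates that; `mode = "strict"` refits the
residualizer inside every training fold. On synthetic data the two agree
to a correlation above 0.95; both modes are first-class and the run
manifest records which was used. Confound sets are explicit arguments
everywhere: height and weight for the age model, height, weight and age
for both association stages.

Residualization is invariant to affine rescaling of the confounds
(height in metres versus centimetres changes nothing beyond $10^{-8}$),
and in-sample residuals are orthogonal to every confound column — both
are tested properties. Columns whose residuals collapse to zero variance
(relative tolerance $10^{-10}$) are dropped with a warning, never
silently.

## Association stages

Feature–age profiling correlates each deconfounded feature with the
bias-corrected heart age (CPHA; the uncorrected prediction can be
substituted) and multiplies each p-value by the number of features
tested. The PheWAS correlates deconfounded exposures with the delta and
multiplies each p-value by the number of catalogue variables in the
exposure's category for that sex — a per-category Bonferroni family.
Throughout: two-sided p-values from
$t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$ degrees of freedom; corrected p
capped at 1 (capping never flips a significance call); significance is
strict (`p_corrected < 0.05`); ranking is ascending corrected p with
ties broken by descending $|r|$, non-evaluable variables last, which
makes the order total. Raw p-values are floored at the smallest positive
double so $-\log_{10}$ stays finite; capped values render as 0.

Missing exposure values are handled pairwise per variable; a variable
with fewer than 100 usable observations is reported but flagged
not-evaluable rather than contributing an unstable correlation. Note
that the profiling stage deconfounds the features by age and then
correlates them with heart age, which is itself age-related; this
mirrors the analysis the package reproduces and is intentionally not
"fixed".

## The synthetic cohort generator

The generator is the package's test bed and defines its study
conditions. Per participant: a latent aging offset
$\delta_i \sim N(0, \sigma_\delta^2)$ with $\sigma_\delta = 5$ years
(chosen so that delta magnitudes are on the scale a population age-gap
model reports); biological age $B_i = \text{age}_i + \delta_i$; features

$$x_{ij} = \mu_j(\text{sex}) + s_j B_i + h_j\,\text{height}_i
  + w_j\,\text{weight}_i + \text{noise}_{ij},$$

with age loadings $s_j \sim U(-0.06, 0.06)$ per year, confound loadings
$U(-0.03, 0.03)$ per cm/kg, and noise composed of 10 shared latent
factors (inducing the low-rank intercorrelation radiomics panels show)
plus independent noise of standard deviation 1.5. Ages are truncated
normal on 45–82 years (women mean 62.7, sd 7.3; men 63.8, 7.6); height
and weight are sex-specific Gaussians matching the cohort the package
emulates (women 163.7 ± 6.3 cm, 68 ± 12.7 kg; men 177.4 ± 6.6 cm,
83.1 ± 13.2 kg). Heights are handled in centimetres throughout.

Planted exposures are constructed as
$e = c\,\delta/\sigma_\delta + \sqrt{1-c^2}\,z$ so their population
correlation with $\delta$ is exactly $c$ — planted on the *latent
offset*, not on age, because the PheWAS deconfounds age and only the
age-orthogonal component can carry recoverable signal. The default
planted map is deterministic (every fifth catalogue variable, magnitudes
cycling 0.05/0.1/0.2/0.3, alternating sign) so that every category mixes
clear signals, weak signals and nulls. The generator returns a truth
record (realized $\delta_i$, loadings, planted ids) that tests consume
and pipeline stages never see.

What the generator does **not** emulate: real radiomics features are
far more mutually redundant and less individually age-informative than
independent loadings produce, so the synthetic model recovers $B_i$
more faithfully than a real panel would — synthetic MAE (~2.8 y) and
$R^2$ (~0.76) are better than a real cohort's (~5 y, ~0.3), and
passing tests demonstrate pipeline correctness, not real-data
performance. There is no missingness mechanism beyond what a user masks
in, no non-White strata, no feature-extraction artefacts.

The exposure catalogue fixes the totals (666 shared + 30 female-specific
+ 5 male-specific in 13 categories) and the abdominal-MRI family size
(16); the remaining shared-category sizes are a plausible allocation,
since only the totals and that one family size are pinned down
externally. Studies with a real catalogue supply their own table.

## Numerical choices and degenerate inputs

* Ridge initialisation $\alpha_0 = 1/\mathrm{var}(y)$, $\lambda_0 = 1$;
  hyperprior parameters $10^{-6}$.
* With hyperparameter updates disabled, the posterior mean equals the
  closed-form ridge solve $(X^\top X + (\lambda/\alpha)I)^{-1}X^\top y_c$
  to $10^{-8}$ (tested against a direct solve on random instances).
* An empty design (all columns dropped) degrades to the intercept-only
  model: every prediction is $\bar y$.
* A constant age vector makes the bias-correction slope undefined and is
  an error; constant vectors in correlations yield flagged `NA`s, not
  errors.
* Fold assignment is a seeded uniform partition balanced to ±1; the
  same seed reproduces the same folds, and a master seed fans out to
  stage sub-seeds so any stage can be re-run in isolation.

## Problem sizes used by the test-suite

The suite exercises the exact published cohort counts where they are
cheap (the 32,121-row screening fixture) and scales the stochastic
checks to sizes that keep the full run under a few minutes: the
bias-correction property runs one study-scale stratum (15,920
participants, 254 features), the null-PheWAS error-control simulation
uses 200 replicates of 40 variables at n = 400, and the planted-exposure
recovery check uses 50 replicates at n = 5,000 with the full 254-feature
panel, where delta recovery reaches the fidelity the ranking property
needs.

## Known limitations

* The evidence approximation yields point precisions, not a posterior
  over them; no automatic relevance determination (per-weight
  precisions) and no feature selection, by design.
* The PheWAS is correlation-based with minimal confounder adjustment —
  no covariate-adjusted regression models, no FDR alternative, no
  outlier handling.
* `mode = "paper"` knowingly reproduces a preprocessing leak; use
  `mode = "strict"` when hygiene matters more than fidelity.
* Corrected-metric degeneracy under signal-free models, as described
  above.
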