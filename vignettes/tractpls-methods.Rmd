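---
title: "Models and methods behind tractpls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tractpls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical machinery:
the two models it fits, the conventions and numerical rules it commits to,
what the synthetic cohorts do and do not emulate, and where a genuinely
open design choice was resolved one way rather than another.

## 1. Trajectory stage: random-intercept growth models

Each of the 72 (tract, metric) measures is analyzed independently with

$$y_{ij} = \beta_0 + \sum_{k=1}^{K}\beta_k\,a_{ij}^k
  + \gamma\,G_i + \sum_{k=1}^{K}\delta_k\,G_i a_{ij}^k
  + \beta_s S_i + \beta_c C_{ij} + b_i + \varepsilon_{ij},$$

with subject $i$, scan $j$, centered age $a_{ij}$, group indicator $G_i$
(deletion vs. control), sex $S_i$, scanner $C_{ij}$, random intercept
$b_i \sim N(0,\tau^2)$ and residual $\varepsilon_{ij} \sim N(0,\sigma^2)$.
The random intercept is what makes the model appropriate for unbalanced
longitudinal designs — subjects may contribute one scan or three, at
arbitrary ages, and each contributes information in proportion to what it
carries.

Key conventions, all of which matter for reproducibility:

* **ML, not REML.** Models differing in fixed effects are compared by
  likelihood ratio, which is invalid under REML; every fit therefore uses
  maximum likelihood (`lme4::lmer(REML = FALSE)`).
* **BIC convention.** $\mathrm{BIC} = -2\,\ell + p\,\log(N_{\mathrm{scans}})$,
  where $p$ counts fixed effects plus the two variance components and the
  sample size is the number of scans (observations), matching the common
  mixed-model convention. Candidate orders $K \in \{0,1,2\}$ are fitted as
  the *full* model (group + interactions + covariates) and the minimal-BIC
  order wins, exact ties going to the lower order. The same selected order
  is then used for both hypothesis tests, which avoids comparing models of
  different orders inside one likelihood-ratio chain. BIC selection is
  invariant to recentering age (verified as a property test).
* **Age centering.** Age is centered at the pooled mean scan age before
  fitting. This is purely numerical conditioning for the quadratic term;
  coefficients are reported on the centered scale.
* **Nesting order of the tests.** The interaction terms are dropped first
  (χ² with df = K for K ≥ 1), then the group main effect (df = 1),
  each by an LRT between ML fits on identical observations. Retaining the
  interaction while testing the group effect would be the other defensible
  reading; dropping interactions first keeps the group test interpretable
  as a level difference, which is also how the result tables report
  direction. An order-0 model has no age term and hence no interaction to
  drop: the interaction test is defined as statistic 0 with p = 1 (df = 0),
  the degenerate limit of the general rule.
* **FDR families.** The group-effect p-values and the interaction p-values
  are step-up-adjusted (Benjamini–Hochberg, via `stats::p.adjust`)
  *separately*, each across all 72 measures — the most conservative family
  definition consistent with correcting each reported map. The family
  definition is recorded in the output metadata.

### Numerical edge rules

`fit_mixed()` commits to explicit behavior at three degenerate boundaries
rather than letting the optimizer fail unpredictably:

1. **Perfect fixed-effect fit** (noise-free input): the mixed model has no
   residual variance to estimate; the fit falls back to OLS with
   $\hat\tau = 0$. Log-likelihoods of perfect fits are numerically
   meaningless (they grow as the RSS approaches rounding error), so an LRT
   between two perfect fits is defined as statistic 0, p = 1.
2. **Subject-constant residuals** (noise-free input with subject-level
   offsets): the ML residual variance sits on the zero boundary, where
   `lmer` degenerates. The $\sigma^2 \to 0$ limit of the GLS estimator is
   OLS on subject means, which is fitted directly (`method =
   "subject_means"`, with a warning); its likelihood dominates any noisy
   alternative, so such orders win BIC selection, ties again to the lower
   order.
3. **Single scan per subject everywhere**: the intercept variance is
   unidentifiable; OLS is used with a warning.

Covariates observed at a single level (e.g. one scanner in a subset) are
dropped with a warning. Non-converged `lmer` fits are flagged and excluded
from order selection; tests involving them report missing p-values.

One property stated loosely in common folklore deserves care: duplicating
every observation does *not* leave mixed-model fixed effects unchanged in
unbalanced designs, because duplication halves the residual share and
re-weights within- against between-subject information. The invariance is
exact for the fixed-effects estimator and for balanced designs, and that
is the regime in which the package tests it.

## 2. Residualization: from scans to one deviation per subject

The PLS stage needs one row per subject, but the data are longitudinal.
The construction is: (1) fit age-only models (no group terms, sex and
scanner as covariates, BIC-selected order) within the analysis subset;
(2) compute each scan's residual from the *fixed-effects-only* prediction;
(3) average residuals within subject per measure.

Two deliberate choices here:

* **Random intercepts are excluded from the prediction.** Including the
  estimated $\hat b_i$ would absorb exactly the subject deviation the
  brain matrix is meant to capture; a subject lying on the population
  curve scores 0, and a subject shifted by δ scores ≈ δ.
* **Per-scan residuals are averaged**, rather than residualizing the
  per-subject average at the mean age. The two are algebraically equal for
  linear curves and differ only through Jensen-gap terms for quadratic
  ones; the mean-age variant is available as `method = "mean_age"` for
  sensitivity analysis (it evaluates scanner at the subject's first-scan
  level, since a per-subject average of a binary covariate is not a
  design point).

Age models are fitted on the same subset that enters the PLS (in-sample
residuals, as is standard for this construction); no out-of-sample or
normative-model variant is attempted. Order selection is reused from the
trajectory stage for internal consistency; fixing K = 1 globally changes
little on the default cohorts but is not the package's convention.

Finite-sample caveat: the fitted curve is pulled toward any one subject by
its own leverage (≈ p/n per scan), so "a planted offset is recovered
within 5%" is a *large-n* statement; the acceptance check uses 250
subjects, where the leverage bias is under 1%.

## 3. PLS correlation

With $X$ (subjects × 72 deviations) and $Y$ (subjects × 5 risk factors)
z-scored columnwise (sample SD, n−1), the cross-correlation matrix
$R = Y^\top X/(n-1)$ holds the Pearson correlation of every risk factor
with every measure. Its SVD $R = U S V$ yields five components; $U$ is
5×5 with behavior saliences in columns, $V$ is 5×72 with brain saliences
in rows, and $L_X = XV^\top$, $L_Y = YU$ are the subject latent scores.
The $1/(n-1)$ scaling makes the entries correlations (it rescales singular
values by a constant and changes nothing else: saliences, p-values and
bootstrap ratios are scale-invariant).

Conventions resolved here because no universal standard exists:

* **Sign convention.** Each component is flipped so its largest-magnitude
  behavior salience is positive. Any fixed rule works; this one makes the
  dominant risk factor load positively, which reads naturally.
* **Permutation scheme.** Rows of $Y_z$ are permuted (X kept fixed), R and
  its spectrum recomputed, and the k-th largest permuted singular value is
  compared with the k-th observed — rank matching, no Procrustes
  rotation. $p_k = (1 + \#\{s^{*}_k \ge s_k\})/(1 + n_{\mathrm{perm}})$,
  so p is bounded below by $1/(n_{\mathrm{perm}}+1)$ and never zero.
  Procrustes-aligned statistics change p-values only marginally when one
  component dominates, which is the regime of interest; rank matching is
  the simplest defensible scheme and is stated in the output metadata.
* **Bootstrap alignment.** Resamples of subjects (with replacement) are
  re-z-scored and re-decomposed; each bootstrap component is sign-aligned
  to the full-sample reference by the dot product of its saliences
  (behavior + brain) — sign flip only, again no Procrustes. Resamples in
  which a risk-factor column is constant cannot be z-scored and are
  redrawn, with the count logged. The bootstrap ratio mean/SD is reported
  for every weight of every component, with |ratio| > 1.96 flagged.
* **Binary columns are z-scored like continuous ones** — the construction
  treats both blocks identically, and the resulting entries are point-
  biserial correlations, which is what a correlation between a binary and
  a continuous variable is.
* **Seeding.** Permutation and bootstrap draw from independent substreams
  derived from the master seed, so changing `n_perm` does not silently
  change the bootstrap.

## 4. The synthetic cohorts

`generate_cohort()` emulates the statistical structure the two stages
assume, with every planted parameter recorded in a ground-truth object:

* **Design**: two groups of 100 subjects, ages 5–35 at first visit
  (uniform), 1–3 visits (probabilities 0.5/0.45/0.05, ≈1.5 scans per
  subject), inter-visit intervals Normal(3, 1) truncated at 0.5 y, visits
  past the age maximum dropped — reproducing the unbalanced design the
  mixed models are built for. Sex is per subject; scanner is per scan
  (probability 0.37 for the second scanner).
* **Trajectories**: FA rises linearly (≈0.0025/y from 0.38); AD declines
  linearly; RD and MD follow quadratic curves that decline steeply in
  childhood and plateau in the mid-to-late 20s (vertices near 28 and 27
  years), the canonical shape of developmental diffusivity curves.
  Diffusivities are in μm²/ms. Baseline levels vary by ±4% across tracts.
  The deletion group is offset toward higher FA and lower AD/RD/MD —
  level differences only, no group×age interaction, so interaction
  discoveries in synthetic runs are false positives by construction.
* **Noise**: per-subject random intercepts (FA 0.015, AD 0.025, RD 0.022,
  MD 0.020) and per-scan residuals (FA 0.010, AD 0.018, RD 0.015,
  MD 0.014), chosen so group offsets are ≈1 subject-SD.
* **Risk factors**: five independent Bernoulli indicators with prevalences
  taken from the subgroup sizes of a 39-patient deletion cohort
  (UHR 10/39, preterm 12/39, low baseline IQ 12/36, cognitive decline
  16/39, baseline anxiety 21/39). Mutual independence is an assumption —
  no inter-factor dependence is specified anywhere authoritative — and a
  shared-cause structure can be planted by supplying custom weights.
* **Planted association**: a rank-1 component adds
  `latent_effect · score_i · w_X[k]` to all of subject *i*'s scans, where
  `score_i` projects the z-coded risk factors onto unit weights `w_Y`
  (default ∝ 0.75 UHR, −0.57 preterm, −0.32 low IQ, −0.02 decline,
  0.03 anxiety) and `w_X` is a unit vector with positive FA and negative
  diffusivity loadings. Because the component is a subject-level constant,
  residualize-then-average recovers it. The default `latent_effect` is the
  RMS random-intercept SD, i.e. ≈1 subject-SD.

What the simulator does **not** emulate: image formation, tractography
and its failure modes, head motion, scanner physics beyond an additive
covariate, within-tract covariance beyond the single planted component,
missing data, or dependence between risk factors. Passing tests therefore
demonstrate that the statistical machinery does what it claims under its
own assumptions — not that those assumptions hold in any particular MRI
dataset.

`deviation_config()` is a degenerate configuration (flat curves, unit
subject SD, zero residual noise, one visit) whose per-subject values *are*
the deviations the residualization stage would hand to the PLS; the
repeated-run calibration and recovery studies use it so that 300 Monte
Carlo replicates do not require 21,600 mixed-model fits.

## 5. Problem sizes and what the checks show

The package's calibration and recovery studies (test suite and
`scripts/acceptance.R`) use sizes chosen to give tight Monte Carlo error
at interactive runtimes: 200 null runs at n = 200 subjects and 200
permutations for permutation-test calibration (the component-1 rejection
rate lands near the nominal 0.05); 100 runs at `latent_effect = 1.5`
subject-SD for recovery (detection essentially always; median
|cor(û₁, w_Y)| ≈ 0.99, median |cor(v̂₁, w_X)| ≈ 0.91 — the brain side is
72-dimensional and recovers more slowly than the 5-dimensional behavior
side); 200 null and 20 alternative replicates at 100 subjects/group for
LRT calibration (observed type-I ≈ 0.05–0.08) and power (a 3-residual-SD
offset is detected at p < 0.001 in every replicate); and 34 replicates per
generating order for BIC recovery (≈100% with the default curvatures).
Salience recovery at a 1-SD effect is appreciably weaker than at 1.5 SD —
the leading singular value of a null 5×72 correlation matrix at n = 200 is
≈0.75, so a planted s₁ ≈ 1 is only marginally separated; users planning a
study of this kind should treat n ≈ 40 subjects (the realistic clinical
subset size) as sufficient for *detecting* a strong component but not for
stable weight maps, which is exactly what the near-threshold bootstrap
ratios in the README example show.

## 6. Known limitations

* Random slopes, spline trajectories, and scanner harmonization beyond a
  fixed effect are out of scope by design.
* χ² asymptotics are assumed for the LRTs; a parametric-bootstrap variant
  would be more exact at small n but is not implemented.
* The permutation statistic is the raw singular value; explained-fraction
  or Procrustes-aligned statistics are alternatives that matter only when
  several components have comparable strength.
* In-sample residualization slightly shrinks extreme deviations (leverage
  ≈ p/n); at n ≈ 40 this is a few percent and is shared by the original
  construction.
* The `mean_age` residualization variant represents a subject's scanner by
  the first scan's level; subjects scanned on different scanners are
  better served by the default per-scan method.
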