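---
title: "Methods: free-water microstructure, harmonization, and decline models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: free-water microstructure, harmonization, and decline models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of the science it implements: the
models, their assumptions, the numerical choices made where a choice was
genuinely open, and what the synthetic-data tests do and do not establish
about real data.

## The bi-tensor free-water model

A voxel's diffusion signal is modelled as a two-compartment mixture of an
anisotropic tissue tensor $D$ and an isotropic free-water pool with fixed
diffusivity $d_w = 3.0\times10^{-3}\,\mathrm{mm^2/s}$ (the body-temperature
literature value for free water):

$$S(g, b) = S_0\left[(1-f)\,e^{-b\,g^\top D g} + f\,e^{-b\,d_w}\right].$$

`fit_bitensor()` minimizes the sum of squared attenuation residuals over
$(f, D)$, with $f$ logit-bounded and $D$ kept symmetric positive-definite
through a log-Cholesky parameterization. $S_0$ is fixed to the mean of the
b0 volumes. Tissue eigenvalues are constrained to the plausibility box
$[1\times10^{-4},\,2.9\times10^{-3}]\,\mathrm{mm^2/s}$ — strictly below
$d_w$, which is what makes the pure-water voxel identifiable at all — via a
quadratic box penalty inside the optimizer plus a hard clamp on return.

### Degeneracy and how it is resolved

At a single shell the problem is fundamentally ill-posed for isotropic
tissue: for any target attenuation $A$ there is a one-parameter family
$(f, D_{\rm iso})$ with
$e^{-b d} = (A - f e^{-b d_w})/(1-f)$ that fits exactly. Two regimes are
handled differently:

* **Noiseless data.** The SSE is profiled over a grid of $f$ (the tissue
  tensor has a closed-form log-linear solution at fixed $f$), and the
  smallest $f$ among exactly-tied minima is taken — the *minimal-free-water
  convention*. This makes the pure-tissue isotropic voxel report
  $f \approx 0$ and the pure-water voxel $f \approx 1$, deterministically.
* **Noisy data** (`rician_sigma` supplied). Ridge SSE differences drown in
  noise, and a free tensor soaks up noise best at low $f$, so profiling
  collapses towards $f=0$. Instead the fit is anchored at the two-point
  mixture inversion
  $f_0 = (\bar A_{\rm tis} - \bar A)/(\bar A_{\rm tis} - \bar A_w)$
  evaluated at a typical tissue diffusivity of
  $0.7\times10^{-3}\,\mathrm{mm^2/s}$, and the quasi-Newton polish carries
  a weak tether to $f_0$ scaled to the expected noise SSE. Signals are
  first debiased with the second-moment Rician correction
  $\hat\nu = \sqrt{\max(S^2 - 2\sigma^2, \epsilon)}$.

Convergence uses a relative objective tolerance of $10^{-10}$ with at most
500 iterations. No spatial regularization is applied — the fit is strictly
voxelwise, which is a documented limitation relative to regularized
implementations: voxels whose tissue is nearly isotropic carry an
unavoidable $f$/diffusivity trade-off, which is why the recovery guarantee
in the tests is a *median* error over a grid (median $|\hat f - f| \le
0.02$ noiseless; mean bias $\le 0.05$ at Rician SNR 30 with 32 directions,
$b = 1000\,\mathrm{s/mm^2}$).

Corrected scalars follow the standard tensor definitions on the sorted
eigenvalues of $D$: MDt the mean, AxDt $=\lambda_1$, RDt
$=(\lambda_2+\lambda_3)/2$, and
$\mathrm{FAt}=\sqrt{\tfrac32\,\sum_i(\lambda_i-\overline\lambda)^2 / \sum_i
\lambda_i^2}$.

## Tract features and quality control

`atlas_registry()` ships 48 named tracts in seven type groups (limbic,
association, projection, and transcallosal prefrontal / motor / parietal /
occipital); with five metrics this yields the 240-feature session block.
Feature extraction is a weight-normalized mean over in-mask, non-NaN
voxels; probabilistic masks are weights and binary masks the weight-1
special case.

The outlier filter regresses each feature's baseline value on baseline age
and excludes a participant — all of their sessions — when any standardized
residual exceeds 5 SD. Two decisions the procedure leaves open were fixed
as follows: baseline-session values are used (rather than all-session
values), and residual SDs can be frozen from a first pass (the `frozen`
argument), which makes repeated filtering idempotent by construction.

## Longitudinal ComBat

Per feature $v$, observation $j$ of subject $i$ in batch $b$:

$$y_{ivj} = \alpha_v + x_{ivj}^\top\beta_v + \gamma_{bv} + \eta_{iv} +
\varepsilon_{ivj}, \qquad \varepsilon \sim N(0, \delta^2_{bv}\sigma^2_v),$$

with a subject random intercept $\eta$ and the preserve design $x$
defaulting to age, age², sex, baseline diagnosis, and age × converter /
age² × converter. Estimation is feature-wise REML (lme4) with batch as a
fixed effect recentred to $\sum_b n_b\gamma_b = 0$; residuals standardized
by $\sigma_v$ retain the batch signal, whose location and scale are then
shrunk across features by parametric empirical Bayes (normal prior on
$\gamma$, inverse-gamma on $\delta^2$, method-of-moments hyperparameters,
iterated conditional posterior means). Shrinkage needs at least 5 features;
below that, unshrunken estimates are used. The adjustment is
$y^* = \sigma_v(z - \gamma^*)/\delta^* + \hat\alpha + x^\top\hat\beta +
\hat\eta$.

Two numerical choices go beyond the textbook formulation:

* **Scale preservation.** Each feature's $\delta^2$ estimates are
  constrained to an observation-weighted mean of 1 — the multiplicative
  analogue of the location constraint. Without it, harmonization would
  globally inflate residuals (BLUP shrinkage makes raw standardized
  residual variances systematically below 1), breaking both the
  no-batch-effect identity and idempotence.
* **EB on sufficient statistics.** The posterior-mean iteration uses
  $\sum_j (z_j-\gamma)^2 = n_b\hat\delta^2 + n_b(\hat\gamma-\gamma)^2$ on
  the normalized scale, keeping prior and likelihood on the same scale.

**Limitation.** The model corrects batch effects on the *residual* scale.
A multiplicative scanner gain that rescales the biology itself (e.g. a
batch whose feature values are 2× spread) also rescales covariate slopes
within that batch, and no residual-scale adjustment can restore those.
The covariate-preservation guarantee in the test suite is therefore stated
under moderate batch spreads (additive shifts within ±0.25 SD, scale
factors within 0.85–1.15 — the generator's defaults), while the
batch-mean-gap and residual-variance checks use deliberately extreme
injections (a 2.5 SD shift, a 2× scale).

## Association scans

Cross-sectional models are per-feature OLS of (optionally z-scored)
cognition on the z-scored baseline feature plus covariates (age scaled and
centred, education, sex, race/ethnicity, baseline diagnosis, APOE ε4/ε2;
references CU, female, non-carrier). Longitudinal models add interval,
baseline age × interval and WM × interval with a per-participant random
intercept and interval slope, and report the WM × interval term. Inference
is large-sample Wald $z$ (Satterthwaite degrees of freedom are available
via `model_spec(satterthwaite = TRUE)`); non-converging fits are retried
with a diagonal random-effect covariance before being flagged. The
baseline WM main effect is always included (model hierarchy), as are all
lower-order terms of any interaction. FDR is Benjamini–Hochberg within one
scan family — all tract × metric combinations for one domain and one term,
the narrowest defensible family.

Demographic comparisons route through the conventional decision tree:
Shapiro–Wilk per group, then Levene (mean-centred) for normal variables,
choosing ANOVA / Welch ANOVA / Kruskal–Wallis; categorical variables get
χ² or Fisher's exact test when any expected count is below 5.

## Bootstrapped variance partitioning

Marginal $R^2$ is Nakagawa–Schielzeth with the random-slope extension: the
fixed-prediction variance over fixed + average random-effect + residual
variance, the random-effect contribution averaged over observations via
$\mathrm{diag}(Z \Sigma Z^\top)$. ΔR² is the full-minus-base difference in
percentage points, where the base model is covariate-only and the full
model adds baseline WM and WM × interval.

The resampling unit is the participant (all visits move together),
stratified by cohort to preserve the design composition; CIs are
percentile, matching the asymmetric intervals such analyses report.
Non-converged replicates are dropped and counted, with a warning (or an
error in strict mode) above 20%. Treating bootstrap replicates as
independent observations in the follow-up ANOVA and pairwise Welch tests
is anticonservative; the report object carries that caveat and the ranking
by mean ΔR² is the primary output. In-sample ΔR² of a nested larger model
is non-negative up to numerical noise, so small positive means under a
null effect are expected and the null-calibration bound (±0.5 percentage
points at 500 participants) is asymmetric in spirit.

## The synthetic study generator

`generate_study()` emulates the structure the analyses assume, not any
real cohort: seven cohorts at the scale of the major aging studies (ADNI,
BLSA, BIOCARD, NACC, ROS/MAP/MARS, VMAP, WRAP; 830, 757, 127, 974, 1160,
326, 293 participants, 4467 total), with matching baseline-age means/SDs,
mean visit counts and baseline diagnosis mixes; Poisson extra visits with
gamma-jittered intervals (a schedule model chosen for realism, since only
summary means and SDs are available); one imaging batch per cohort by
default. Cognition follows

$$y_{dij} = \alpha_d + x_i^\top\beta + w_d\,\beta_{\rm wm} W_i + b_{0i} +
\left(s_0 + s_a(\mathrm{age}_{i0}-74) + b_{1i} + w_d(\theta +
\textstyle\sum_e \phi_e E_{ie}) W_i\right) t_{ij} + \varepsilon_{dij}$$

with $W_i$ the standardized noise-free baseline value of a designated
driving feature (fornix FW by default), domain weights $w_d$ = (1, 0.7,
0.7) making memory the most affected domain, and defaults
$\beta_{\rm wm} = -0.3$, $\theta = -0.15$ z-units/year per SD (a strong
effect of the kind reported for fornix free water), random-effect
SDs 0.5 (intercept) and 0.05/yr (slope), residual SD 0.25. Diagnosis
shifts baseline cognition and white matter but — deliberately — not the
slope directly: decline operates through white matter and age, so the
fitted WM × interval coefficient is the generating $\theta$ without
omitted-variable contamination.

Features share variance through per-subject tract-type and tract latent
factors (loadings 0.5 / 0.55), so tracts of a type are correlated — this
is what lets a fornix-driven effect surface across the limbic group in the
head-to-head ranking. Batch effects enter as
$\mu + \sigma[\gamma_b + \delta_b(z_{\rm true} + \text{noise})]$ on each
feature's SD scale: the scanner gain multiplies signal and measurement
noise alike, so the scale effect is visible in residual variance where the
harmonization model operates. Endophenotypes couple to the limbic latent
factor (hippocampal volume negatively, SPARE-AD positively), and
amyloid/tau positivity are thresholded latent Gaussians (35% / 25%
positive).

What passing these tests does **not** show about real data: the generator
draws Gaussian noise, has no site-specific acquisition differences beyond
location/scale, no missing-not-at-random dropout (only an optional
monotone hazard, off by default), no item-level cognitive structure, and
its effect sizes are injected — so recovery demonstrates the estimators
are calibrated under the assumed model, not that the model is right for
any particular cohort.

## Problem sizes

The test suite and acceptance script run at sizes chosen to make
Monte-Carlo error small relative to the tolerances they check: a 216-voxel
noiseless phantom grid (f 0–0.8 × FA 0.1–0.8 × 3 orientations), 72 noisy
voxels at SNR 30, harmonization at 2–3 batches × 120–250 subjects,
slope-recovery at 800 participants × 3 visits, bootstrap null calibration
at 500 participants × 200 replicates, and a 100-replicate
covariate-preservation loop at 120 subjects per replicate. The synthetic
demo pipeline (`fwtrace demo`) runs the default cohorts at 5% scale.
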