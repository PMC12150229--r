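# fwtrace

Tools for studying white-matter microstructure and cognition in aging and
Alzheimer's-disease cohorts. The package implements, as a tested R pipeline,
the full analysis chain used in large multi-cohort free-water studies:

1. **Free-water quantification** — a per-voxel single-shell bi-tensor fit
   separating an isotropic free-water (FW) compartment from the tissue
   tensor, with FW-corrected scalars (FAt, MDt, AxDt, RDt).
2. **Tract features and QC** — mean microstructure over a packaged registry
   of 48 white-matter tracts in 7 type groups (240 features per session),
   with the ±5 SD age-regressed outlier exclusion.
3. **Longitudinal ComBat harmonization** — removal of additive and
   multiplicative imaging-batch effects with empirical-Bayes shrinkage,
   preserving age, age², sex, diagnosis and age × converter structure and
   subject-specific trajectories.
4. **Association scans** — per-tract cross-sectional regressions
   (standardized β) and longitudinal mixed-effects models of cognitive
   decline with BH-FDR control, plus white-matter × endophenotype
   interaction models (hippocampal volume, SPARE-AD, APOE ε4, amyloid/tau
   positivity, diagnosis).
5. **Bootstrapped head-to-head comparisons** — cluster-bootstrap
   distributions of the marginal-R² gain (ΔR²) a feature adds beyond a
   covariate-only model, with ANOVA/post-hoc rankings by metric, tract type
   and tract.
6. **A synthetic multi-cohort study generator** — seven cohorts with
   realistic sizes, visit schedules, batch effects and known ground truth,
   used throughout the test suite for parameter-recovery and calibration
   checks.

It is written for imaging-biostatistics practitioners who need a
transparent, fully scriptable version of this analysis that can be
validated end-to-end on data with known truth.

## Models

**Bi-tensor signal model.** For gradient direction *g* at b-value *b*,

    S(g, b) = S0 [ (1 − f) exp(−b gᵀ D g) + f exp(−b d_w) ],

with free-water fraction *f*, tissue tensor *D* (eigenvalues constrained to
[1 × 10⁻⁴, 2.9 × 10⁻³] mm²/s), and fixed water diffusivity
d_w = 3.0 × 10⁻³ mm²/s. The single-shell fit is ill-posed for isotropic
tissue; the fitter resolves the exact ridge by the minimal-free-water
convention on noiseless data and anchors noisy fits at a mixture-inversion
initialization (see the methods vignette).

**Longitudinal ComBat.** Per feature *v*, subject *i*, batch *b*:

    y_ivj = α_v + xᵀβ_v + γ_bv + η_iv + ε_ivj,   Var(ε) = δ²_bv σ²_v,

estimated feature-wise by REML with batch fixed effects, followed by
empirical-Bayes shrinkage of (γ, δ) across features and the adjustment
y* = σ (z − γ*)/δ* + fitted biology.

**Decline models.** Cognition over visits is modelled with fixed effects
(covariates, baseline WM, interval, baseline age × interval,
WM × interval) and a per-participant random intercept and interval slope;
inference is on the WM × interval term (Wald z). Marginal R² follows the
Nakagawa–Schielzeth definition with the random-slope extension.

## Worked example

```r
library(fwtrace)

# a desk-scale synthetic study: 7 cohorts, 240 features, known truth
st <- generate_study(default_cohort_configs(scale = 0.1), truth_params(),
                     seed = 7)
st
#> <study_table> 449 participants, 903 visits, 7 cohorts, 240 feature columns

# harmonize a feature block across imaging batches
cm <- fit_longcombat(st, feature_cols = c("fornix.FW", "cingulum.FW",
                                          "SLF.FW", "ILF.FW", "IFOF.FW"))
cm
#> <combat_model> 5 features, 7 batches, EB-shrunken
h <- apply_longcombat(st, cm)

# scan for associations with memory decline
res <- longitudinal_scan(h, features = c("fornix.FW", "cingulum.FW",
                                         "SLF.FW", "ILF.FW", "IFOF.FW"),
                         spec = model_spec("memory"))
res
#> <scan_result> 5 models (0 non-converged), term 'wm:interval', domain 'memory'
#>   q < 0.05: 2 of 5
head(as.data.frame(res)[order(res$p), c("tract", "metric", "beta", "z", "p", "q")], 3)
#>      tract metric    beta      z        p        q
#> 1   fornix     FW -0.1024 -13.33 1.47e-40 7.34e-40
#> 2 cingulum     FW -0.0238  -2.36 1.84e-02 4.60e-02
#> 5     IFOF     FW -0.0184  -1.78 7.49e-02 1.25e-01

# how much variance does fornix FW add beyond covariates?
bootstrap_delta_r2(h, "fornix.FW", model_spec("memory"), n_boot = 50, seed = 7)
#> <boot_r2> fornix.FW ~ memory: dR2 = 26.51% (95% CI 18.13-34.20), base R2 = 42.38%, n_boot = 50 (0 dropped)
```

The generator injects a negative effect of fornix free water on the memory
slope (with correlated limbic tracts), so the scan recovers exactly that
structure: fornix FW strongest, its limbic neighbour next, unrelated tracts
null.

The whole pipeline (simulate → QC → harmonize → scans → bootstrap →
interactions) can be run in one call:

```r
run_pipeline(pipeline_config(out_dir = "runs/demo", seed = 7))
```

or from a shell via the thin wrapper `inst/scripts/fwtrace`
(`fwtrace demo --seed 7 --out-dir runs/demo`).

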