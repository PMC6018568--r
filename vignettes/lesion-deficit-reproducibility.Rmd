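---
title: "Methods: simulating the reproducibility of lesion-deficit mapping"
author: "lesionboot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating the reproducibility of lesion-deficit mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

`lesionboot` studies one question: if a lesion-deficit effect of modest
size exists in a large stroke cohort, what do typical sample sizes do to
its reproducibility? The analysis object is the squared partial correlation
$R^2$ between ROI lesion load and a behavioural target score given five
covariates (four other behavioural scores plus total lesion size), and the
experimental instrument is the bootstrap: resampling a fixed cohort at
sizes 30–360 and watching how significance rates, effect-size estimates
and effect directions behave.

The statistical conventions, used consistently everywhere:

* partial correlation with $k$ covariates carries $df = n - 2 - k$
  (validated against the closed-form significance floors printed by
  `critical_r2()`: 0.16 at $n=30$, 0.05 at $n=90$, 0.02 at $n=180$ for
  $\alpha = .05$, and 0.38 at $n=30$ for $\alpha = .001$);
* the Fisher-z standard error of a partial correlation is
  $1/\sqrt{n - k - 3}$;
* resample significance uses the two-sided p value; the sign of the
  estimate is tracked separately rather than folded into the test.

## The synthetic cohort generator

No patient-level data are available, so the generator *is* the study
population. Its defaults are the study conditions and are not tuning
knobs:

| parameter | default | unit | why |
|---|---|---|---|
| `n_patients` | 360 | patients | full-cohort size whose even divisors give the resample sizes |
| `target_partial_r2` | 0.11 | fraction | the full-sample lesion-load effect the study revolves around |
| `effect_sign` | −1 | — | more damage, lower score |
| `score_mean`, `score_sd` | 50, 10 | T-score | behavioural scores are T-scores by construction |
| `score_clip` | [10, 90] | T-score | ±4 SD; clipping this far out changes SDs by < 2% |
| lesion size | lognormal, mean 85.7, SD 87.6 | cm³ | positive, heavy right tail; moment-matched then clipped to [1.5, 386.2] |
| `grid_shape`, `voxel_size_mm` | 40×48×40, 4 mm | voxels | desk-scale grid; 2 mm is configurable |
| `binary_threshold` | 0.3 | fraction | fuzzy level that counts as "lesioned"; the real toolbox value is unpublished, so this is configurable |
| `covariate_share` | 0.3 | fraction | variance of the target score carried by the covariates |

The joint model is a six-dimensional Gaussian copula over (latent lesion
load, four nuisance scores, lesion-size latent). Latent lesion load is the
probability transform of its Gaussian coordinate — Uniform[0,1] marginally,
which guarantees a healthy fraction of patients above the binary threshold
so the designated ROI stays discoverable — with default correlation 0.5 to
lesion size and −0.2 to the nuisance scores. The inter-score correlation
(0.4 among scores, −0.3 score-vs-size) is a plausible default, *not* an
estimate of any empirical covariance: no such covariance is published, and
none of the package's conclusions depend on it beyond the calibrated
partial $R^2$.

The target score is then

$$Y = 50 + 10\left(\sqrt{w}\,G + s\sqrt{\rho^2(1-w)}\,\frac{U}{\mathrm{sd}(U)}
      + \sqrt{(1-\rho^2)(1-w)}\,\varepsilon\right)$$

where $G$ is a unit-variance combination of the standardized covariates,
$U$ the population residual of lesion load on the covariates, $s$ the
effect sign and $w$ the covariate share. Residualizing $Y$ on the
covariates removes $G$ exactly, so the population partial $R^2$ is
$\rho^2$ by construction. The one quantity without a closed form after the
marginal transforms — the population regression of load on the covariates
and its residual SD — is estimated once at calibration time from a
2×10⁵-draw Monte-Carlo sample on a dedicated sub-seed, and reused for all
cohorts from that configuration. Calibration is verified empirically: at
$n = 10^5$ the sample partial $R^2$ lands within ±0.005 of targets 0.11
and 0.50.

### Pinning the in-sample effect

The bootstrap resamples one *fixed* cohort, so what matters is the
*in-sample* $R^2$, not the population value. `fix_sample_partial_r2()`
decomposes the covariate-residualized lesion load into its component along
the residualized target and the orthogonal remainder, rescales the two so
the sample correlation is exactly the requested value (machine precision),
and re-maps into [0,1] by an increasing affine map — which leaves the
partial correlation untouched. Requesting the sample's own $R^2$ returns
the input unchanged.

### Lesion volumes

Each patient's lesion is a single smooth blob: abnormality 1 inside a core
radius, Gaussian decay (width 8 mm) outside. Two constraints pin its
geometry: the thresholded (binary) volume must reproduce the patient's
lesion size — the core radius is iterated a few steps so the *discrete*
voxel count matches despite voxelisation and grid-edge truncation — and
the mean fuzzy value over the designated true ROI must reproduce the
latent lesion load, achieved by placing the blob at the distance where its
decay profile equals the load and then applying a small clipped uniform
shift inside the ROI (tolerance 0.01). A patient with latent load exactly
zero gets an empty volume.

What the generator does **not** emulate: real lesion anatomy (vascular
territories, white-matter tracts), spatially correlated multi-focal
damage, registration error, or the fuzzy-clustering segmentation that
produces real abnormality maps. Passing tests therefore demonstrate the
statistical pipeline's behaviour under a known ground truth — not that the
pipeline is robust to the messiness of real imaging.

## ROI discovery

The voxel-wise fit is ordinary least squares of fuzzy abnormality on the
seven design columns, sharing one hat matrix across voxels. Family-wise
error is controlled by Freedman–Lane max-statistic permutation: residuals
of the reduced model (all columns but the tested score) are permuted, the
full model is refit, and the maximum statistic over the mask forms the
null; the observed maximum joins the null distribution, preserving test
validity. Bonferroni is the deterministic fallback. Random-field-theory
correction is deliberately not implemented: it would require smoothness
estimation that contributes nothing to the questions the package asks,
and permutation provides exact FWE control for these designs (measured
false-positive rate 0.06 over 200 null cohorts at nominal 0.05 in the test
suite).

The voxel contrast is one-tailed in the hypothesised negative direction by
default — the direction is declared by the effect model — with a two-tailed
flag; under Bonferroni the one-tailed threshold uses
$\alpha/n_{\mathrm{vox}}$ directly. Degenerate voxels (zero residual
variance, which only arises in noise-free synthetic data) get $t = 0$ or a
±10⁶ sentinel, are flagged, and are excluded from any ROI.

## Effect size, credible interval, power

The flat-prior credible interval is built on the Fisher-z scale: posterior
$z \sim N(\mathrm{atanh}\,\hat r,\ 1/(n-k-3))$, equal-tailed interval
mapped through $\tanh$ and squared; an interval straddling zero maps to a
lower $R^2$ bound of 0. The construction reproduces the anchor interval
(0.06–0.18 for $R^2 = 0.11$ at $n = 360$) at two decimals and attains
0.944–0.958 empirical coverage at nominal 0.95 for $n \ge 60$ in
simulation. The analytic power and sign-error calculators use the same
approximation; power agrees with 10⁴-replicate simulation within 0.013
across $\rho^2 \in \{0.05, 0.11, 0.3\}$ and $n \in \{30, 90, 180\}$. An
exact noncentral-F treatment is a documented non-goal: the Fisher-z forms
are transparent, closed-form, and accurate to well inside Monte-Carlo
noise at these problem sizes.

## The bootstrap study

Defaults: B = 6000 resamples per size, sizes {30, 60, 90, 120, 180, 360},
drawn with replacement from the fixed cohort (without-replacement mode is
available and agrees within 3 percentage points on significance rates for
sizes ≤ 180; at size 360 it degenerates to the full-sample estimate).
RNG provenance: one master seed streams per-size seed vectors, and every
record stores its own sub-seed, so any single replicate is reproducible in
isolation.

Decile-representative resamples are selected by nearest rank (no
interpolation) — the study reports *actual* resamples, not interpolated
values — with ties in $R^2$ broken by the lowest replicate index. The ROI
power summary computes, for the patients of one selected resample, each
ROI voxel's observed effect size $t^2/(t^2+df)$ and its analytic power at
the Bonferroni-corrected alpha; "sufficient" means power ≥ 0.80. This is a
defined, documented proxy — the power-map algorithm used with real data is
not published — so cross-study power percentages should be read
qualitatively.

## Numerical choices and degenerate inputs

* Exact-pin tolerance of `fix_sample_partial_r2`: 10⁻¹⁰ (achieved at
  machine precision; the affine re-map cannot disturb it).
* Rank-deficient bootstrap draws are redrawn; more than 1% redraws aborts
  with a diagnostic (with continuous synthetic scores this only happens
  when covariates are exactly collinear in the source cohort).
* Constant residual vectors raise "degenerate sample" rather than
  returning NaN.
* Report tables round to 2 decimals for display and dash out empty cells;
  full precision is retained in the record CSVs.

## Problem sizes

The shipped test-suite and acceptance workloads are sized for a laptop
core: calibration Monte-Carlo 2×10⁵, large-n verification 10⁵, B = 6000
bootstrap (the full six-size study takes a few seconds), 200-cohort FWE
calibration on an 8×8×8 grid with 500 permutations, and imaging tests on
12³–16³ grids at 8 mm with 120–360 patients. The default 4 mm grid with
360 patients runs the full imaging pipeline in well under a minute and
~0.5 GB.

## Known limitations

* The Gaussian-copula population and single-blob lesions are idealised;
  effect-size calibration, not anatomical realism, is the design goal.
* The flat-prior interval is the Fisher-z construction; a different exact
  posterior could differ in the third decimal at these n.
* Cluster-extent inference, anatomical labelling and multivariate
  lesion-symptom mapping are out of scope.
* The clipped lognormal reproduces the mean lesion size but its SD is
  shrunk by the clip (~74 vs 87.6 cm³); the resampling conclusions do not
  depend on the size distribution's tail.
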