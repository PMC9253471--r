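---
title: "Lesion-derived disconnectome mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion-derived disconnectome mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(disconnectome)
```

## The problem

In multiple sclerosis (MS), T2-hyperintense lesions sever white-matter
fibers that pass through them, so the functional footprint of a lesion
extends far beyond its visible boundary. *Lesion network mapping* infers
that footprint without patient tractography: a patient's binary lesion
mask is intersected with normative streamline reconstructions from healthy
controls, and every voxel traversed by a lesion-crossing fiber is marked
as potentially disconnected. Because only lesion masks are required from
patients, the approach works across heterogeneous multicenter MRI
protocols. This package implements that pipeline end to end and relates
the resulting disconnection burden to serum neurofilament light chain
(NfL), a blood biomarker of axonal damage, cross-sectionally and over a
two-visit follow-up.

## The disconnectome model

For one subject with lesion mask $L$ and $N$ control tractograms, the
disconnectome value at voxel $v$ is

$$p(v) = \frac{1}{N}\sum_{c=1}^{N} \mathbf{1}\!\left[\,\exists\,
  \text{streamline } s \in T_c:\ s \cap L \neq \emptyset
  \ \wedge\ v \in \mathrm{vox}(s)\,\right],$$

the fraction of controls in which some fiber both crosses the lesion and
visits $v$. Values lie on $\{0, 1/N, \dots, 1\}$ and read as a probability
of disconnection from 0 to 100%. Three reading choices deserve note:

* **Seeding as filtering.** Rather than seeding a tractography engine
  from the lesion, whole-brain normative streamlines are *filtered* by
  lesion intersection. The selection criterion — fibers passing through
  the lesion — is identical, and no diffusion model is needed.
* **"Normalised" visitation maps.** Per-control visitation counts are
  binarised before averaging. This is the only reading under which the
  across-control average is a fraction of controls, i.e. a probability;
  averaging raw counts would give a quantity with no 0–100% scale.
* **Threshold.** Maps are thresholded at probability $> 0.5$ (strict) by
  default: a voxel is kept when more than half the controls support
  disconnection there. With an even number of controls the boundary case
  (exactly half) is excluded by the strict rule; `threshold_map(strict =
  FALSE)` implements the "at least half" reading, since the two verbal
  descriptions of the rule differ and both are defensible. The cutoff
  itself is a parameter.

The **white-matter analysis mask** is the union of the nonzero supports of
the cohort's individual (thresholded) disconnectome maps — the mask is
defined by the data, not by an anatomical atlas, so every voxel in it is
disconnectable by some observed lesion. The **global disconnectome (GD)**
of a subject is the mean of the thresholded map over that mask. Sub-mask
zeros stay in the denominator: GD deliberately mixes the *proportion* of
affected white matter with the *severity* (probability) at affected
voxels, giving a scalar in $[0,1]$ per subject and visit. Lesion volume
(T2LV, ml) is voxel count times voxel volume.

### Geometry and numerics

* Voxel membership of a streamline is by point sampling: the polyline is
  resampled at a step enforced to be at most half the smallest voxel
  dimension (default one quarter), and a voxel is visited if it contains a
  sample point. The contract is exactly "contains a sampled point": a
  sliver where a fiber clips a voxel corner over a chord shorter than the
  step may be missed, which the tests bound explicitly against a
  dense-sampling oracle.
* World-to-voxel mapping rounds half away from zero, so results do not
  depend on the platform's round-half-to-even behaviour.
* Spherical synthetic lesions use voxel-centre-in-sphere membership
  (non-strict), which is orientation-free and unambiguous.
* GD of the phantom reproduces a brute-force voxel average to 1e-12; no
  accumulation tricks are needed at these problem sizes.

## Statistical models

All continuous variables (and by default the response) are z-scored, so
reported coefficients are standardized betas. Reference levels are
treatment "none", center "Barcelona", phenotype "CIS"; phenotype is coded
CIS/RRMS/PMS with primary- and secondary-progressive MS merged into PMS.

* **Cross-sectional (baseline):** OLS of GD or T2LV on NfL, disease
  duration, age, sex, phenotype, treatment and center, with two-sided
  t-tests per coefficient and no multiple-testing correction across terms.
* **Longitudinal:** a linear mixed model over both visits with a subject
  random intercept; center enters as a fixed effect by default (the
  reported-model variant) or as a second random intercept
  (`center = "random"`). Timepoint is coded 0/1 (baseline/follow-up), so
  the NfL-by-timepoint interaction is the change in the NfL slope at
  follow-up. Fitting is REML via `lme4`; inference is Wald with a normal
  approximation (CI = estimate ± 1.96 SE), matching the convention of
  reporting t and p without classical denominator degrees of freedom.
  Whether NfL should be re-standardized within visit is not settled;
  here it is z-scored once across all records, which keeps the
  interaction interpretable on a single NfL scale.
* **Robust refit:** iteratively reweighted least squares around the REML
  fit, with Huber weights on conditional residuals standardized by a
  MAD-based scale. The default tuning constant is 3 robust
  SDs: the refit is a guard against gross outliers that leaves clean
  Gaussian data essentially untouched, which is the behaviour the
  conventional-model cross-check requires (at 1.345, the classical
  95%-efficiency choice, roughly one observation in eight is
  downweighted even on clean data and small within-subject coefficients
  drift visibly from the REML fit); 1.345 remains available through the
  `huber_c` argument, and
  `huber_c = Inf` recovers the conventional fit exactly. This is a
  pragmatic robustification of the mean structure, not a robust
  estimating-equation treatment of the variance components. When the two
  fits are compared on clean data, per-coefficient agreement is judged
  relative to `max(|estimate|, SE)`: a drift far below a coefficient's
  standard error is statistically unresolvable no matter how large it
  looks against a near-zero point estimate.
* **NfL outliers:** values above mean + 3 SD of the full sample are
  removed in one pass before the voxel-wise GLM and the conventional
  LMM (robust fits keep them by design). The rule is one-sided and
  deliberately not iterated; re-applying it to the kept values could
  remove more, which is a property of the rule, not a bug.
* **EDSS change** between visits is classified worsening / stable /
  improving by the standard clinical half-point rules. The printed rules
  leave some grid cells uncovered (for example an unchanged EDSS of 6.0);
  these are labelled `unclassified` rather than silently binned, because
  any binning would be an invented claim.

## Voxel-wise inference

The per-voxel GLM tests the NfL association across subjects' baseline
disconnectome maps with age, sex, disease duration and the observed
phenotype-by-treatment combinations (dummy-coded, empty combinations
dropped, rank checked) as covariates. Inference is by permutation:

* **Freedman–Lane scheme:** residuals of the nuisance-only model are
  permuted and added back to the nuisance fit, preserving the covariate
  structure under the null. It is the default scheme of the standard
  mass-univariate tools and the natural choice when none is specified.
* **TFCE:** each t-map is enhanced by
  $\mathrm{tfce}(v) = \sum_{h = dh, 2dh, \dots}^{t(v)} e(h, v)^{E}\,
  h^{H}\, dh$ with the standard 3-D parameters $H = 2$, $E = 0.5$,
  $dh = 0.1$ and 26-connectivity (all configurable). Negative effects are
  enhanced on the negated map separately. The discrete sum is implemented
  exactly (C++ union of connected components per threshold level) and is
  tested against a brute-force oracle.
* **FWER:** the null distribution is the maximum TFCE value over the mask
  per permutation; $p(v) = (1 + \#\{\text{perm max} \ge \text{obs}(v)\})
  / (1 + n_\text{perm})$, never zero by construction. Both the positive
  and the negative NfL contrast are tested, each reported at the 0.05
  level (the two-one-sided reading of a two-tailed 0.05 threshold);
  Bonferroni across the two contrasts is a caller-side choice of alpha.
  When all relabelings can be enumerated the full permutation group
  replaces random sampling.

## What the synthetic generator emulates — and what it does not

The generator exists so every downstream stage is testable with no
patient data. It emulates the *statistical structure* of the study
population:

* a small RAS+ isotropic template (default 32³ voxels at 1 mm) instead of
  true template dimensions — the pipeline is resolution-agnostic, and
  tests should run in seconds;
* controls as jittered rigid copies of shared bundle geometry (the
  per-bundle fiber scatter is anatomy, drawn once; the per-control
  translation stands in for registration and inter-individual
  variability, and `jitter = 0` gives identical controls);
* demographics, phenotype, treatment and center frequencies at the
  published cohort margins (71% female, age 42.9 ± 9.9, four centers at
  18/30/22/28%, treatments 30/44/26%);
* right-skewed lognormal serum NfL (mean ≈ 8.9, SD ≈ 7 pg/ml) with
  optional injected outliers to exercise the 3-SD rule;
* a standardized GD response generated by exactly the mixed model the
  longitudinal module fits, with planted defaults matching the reported
  standardized magnitudes (NfL +0.03, timepoint −0.04, interaction −0.01,
  center shifts −0.29/−0.41/+0.44, subject-intercept SD 0.92, residual SD
  0.05). The variance budget sums to ≈ 1 so that z-scoring the response
  at fit time is close to the identity and planted and recovered
  coefficients live on the same scale;
* T2LV as a lognormal monotone transform of the subject intercept
  (mean ≈ 8.5, SD ≈ 11 ml), which induces the strong, slightly curved
  GD–T2LV association the quadratic fit targets;
* EDSS trajectories mixing improving/stable/worsening at roughly
  19/65/16%.

It does **not** attempt realistic lesion morphology, MRI contrast,
scanner effects beyond center intercept shifts, attrition between visits,
or a literature-calibrated lesion count/size distribution (none is
published for this cohort; the spherical-lesion parameters are a
simulator choice, not a cohort claim). Passing tests therefore
demonstrate that the *algorithms* are correct and the *estimators*
recover what was planted — not that the synthetic data resemble real
images. The generated `gd` column lives on the standardized model scale
and is not bounded to $[0,1]$; bounded GD values arise only from actual
disconnectome maps, as in the pipeline's imaging path, which replaces the
generator's latent GD/T2LV with measured ones.

## Problem sizes used in the checks

The self-checks use deliberately small configurations chosen to exercise
every code path at desk scale: the hand-enumerable phantom (16³ grid, 10
two-bundle controls), 20 random 16³ maps for the TFCE oracle, 200 null
datasets of 40 subjects × 500 voxels × 500 permutations for FWER
calibration, 200 replicate cohorts of 300 subjects × 2 visits for
parameter recovery, and an end-to-end pipeline of 20 subjects, 5
controls and 60 permutations for determinism. Estimates from these sizes
carry the quoted Monte-Carlo tolerances; they are self-consistency
checks of the implementation, not re-analyses of any patient cohort.

## Known limitations

* The robust refit approximates, and is not, the DAStau-type robust
  mixed-model estimator; its fidelity argument is the agreement with the
  conventional fit on clean data plus better resistance under
  contamination.
* Point-sampled voxelisation can miss sub-step corner clips (bounded in
  the tests); an exact ray-traversal backend would remove this at some
  complexity cost.
* The tractogram readers implement documented subsets of the TCK-style
  and TRK-style formats (world-mm coordinates, no per-point scalars or
  per-track properties).
* Permutation inference assumes exchangeable errors under the null; with
  two visits per subject only baseline maps are analysed voxel-wise, so
  no block structure is needed.
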