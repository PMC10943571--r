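---
title: "Quantifying white-matter enlarged perivascular spaces: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying white-matter enlarged perivascular spaces: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perivasc)
```

## The problem

Enlarged perivascular spaces (ePVS) are MRI-visible, CSF-isointense channels
that follow small vessels through the brain parenchyma. In small-vessel
diseases such as CADASIL they are a candidate marker of impaired perivascular
fluid dynamics, but counting and measuring them by eye is slow and
unreliable: a single hemisphere can carry dozens of sub-3-mm tubular
cavities. `perivasc` implements a semiautomated quantification pipeline for
ePVS restricted to cerebral white matter (WM), together with the statistical
design used to relate ePVS burden to imaging, cognitive and plasma-proteomic
measures, and a synthetic phantom/cohort generator that provides ground
truth for every stage.

The package assumes preprocessed inputs: a T1-weighted volume, a T2-weighted
volume registered into T1 space, and GM/WM/CSF tissue probability maps on
the same grid. Bias correction, registration and tissue segmentation are
upstream of this package; `assert_coregistered()` enforces their outcome
(equal grid shape, equal spacing within a relative tolerance of 1e-3, which
absorbs header rounding).

## The segmentation model

The pipeline composes eight stages; each is exported and individually
testable.

**WM mask.** Voxels with WM probability at or above 0.90 (`binarize_wm()`).
The boundary is inclusive — a "90% mask" conventionally includes the
threshold itself — and configurable.

**Tissue intensity model.** `fit_intensity_model()` computes per-modality
WM/GM/CSF mean intensities over each tissue's binarized map, WM-normalized
tissue profiles, and linear coefficients regressing WM-normalized intensity
on CSF probability (predictor) with GM probability as nuisance. All
downstream intensity reasoning is relative to the WM means, which makes the
entire report invariant to global intensity scaling — a property the test
suite asserts exactly.

**Candidate detection.** A WM voxel is CSF-like when its T1 intensity falls
below $k_1 \cdot \mu_{T1}^{WM}$ and its T2 intensity rises above
$k_2 \cdot \mu_{T2}^{WM}$. The defaults $k_1 = 0.7$, $k_2 = 1.3$ sit between
the WM and CSF means for conventional contrast; no published values exist
for these cuts, so they are exposed in `pipeline_config()`.

**Correlation filtering.** The published description of the multimodal
model is ambiguous about its fitting domain (per voxel versus per region).
We fit per candidate component: the observed WM-normalized (T1, T2)
intensities of each 26-connected component are correlated with the
model-predicted CSF profile, and components with correlation at or above
`min_corr` (default 0.5) are retained. This reading matches the
description of correlation coefficients computed from fluid-filled regions
with high positive values kept as true ePVS. Components of a single voxel,
where correlation is undefined, would otherwise be silently dropped and
bias small-ePVS counts; they pass when their relative distance to the CSF
profile is within `max_rel_dist` (default 0.25).

**Sato vesselness.** At each scale $\sigma$ the volume is Gaussian-smoothed,
the Hessian is scale-normalized by $\sigma^2$, and its eigenvalues
$\lambda_1 \ge \lambda_2 \ge \lambda_3$ are computed analytically per voxel.
A tube has two large negative eigenvalues (the cross-section) and one near
zero (the axis), giving the line measure

$$ s = |\lambda_3|\,(\lambda_2/\lambda_3)^{\gamma_{23}}
      \left(1 + \frac{\lambda_1}{|\lambda_2|}\right)^{\gamma_{12}}
      \quad (\lambda_2 \le \lambda_1 \le 0), $$

with the $\lambda_1 > 0$ branch damped by $\alpha$ (default 0.25). CSF-dark
tubes on T1 are handled by negating the input. Scales default to
$\{0.5, 1.0, 1.5\}$ mm: the filter parameters used in the original study are
unpublished, and these bracket the radii of sub-3-mm tubes at 1 mm voxels.
The per-voxel maximum over scales is normalized to [0, 1] per volume (with a
rounding-noise floor so constant volumes map to exact zeros).

**Tubularity filtering.** Components are summarized by the 90th percentile
of member-voxel vesselness and must reach `min_vesselness` (default 0.15).
During development we measured that this summary alone cannot separate
ovoid cavities from tubes: boundary-shell voxels of a dark sphere carry
genuinely tube-like Hessian signatures, and true 5 mm spheres scored inside
the tube range on the phantom. The filter therefore adds a scale-free shape
index, component volume divided by the cube of its maximal inscribed-sphere
diameter. A sphere scores $\pi/6 \approx 0.52$ at any size; a tube of
length $L$ and radius $r$ scores $(\pi/8)(L/r)$, large even when strongly
curved. With the default cut of 4, phantom ovoids score at most about 2.6
and tubes at least about 5 across seeds. Components failing either test are
routed to a lacune-candidate mask rather than discarded; `min_vesselness =
0` disables the filter entirely.

**Density clustering.** Voxels within `linkage_mm` of each other (physical
coordinates) are density-reachable and share a cluster; clusters below
`min_voxels` are dropped as noise. Defaults: `linkage_mm` = 1.5 × the
largest voxel dimension (connects diagonal tube voxels), `min_voxels` = 3
(suppresses single-voxel noise). No clustering parameters were published.

**Classification and volumetrics.** Cluster volume is voxel count × voxel
volume, exactly. The diameter estimate is the maximal inscribed-sphere
diameter from the in-cluster Euclidean distance transform — robust for
curved tubes, where a bounding-box diameter would be meaningless. Because
centre-to-centre distances overestimate the continuous inscribed radius by
about half a voxel per side, one mean voxel dimension is subtracted.
Clusters with diameter at or below 3 mm are classed `ePVS`, larger ones
`perforated/lacune`; the 3.0 mm boundary itself goes to ePVS (the size rule
as printed leaves exactly 3 mm unassigned). Totals aggregate the ePVS class
only. An optional exclusion mask emulates manual review: clusters whose
overlap fraction exceeds 0.5 are removed whole (whether human review
removed voxels or whole clusters is unstated; cluster-level removal is
assumed).

## Morphometry

Brain parenchymal fraction is (GM + WM) / (GM + WM + CSF) with volumes as
probability-weighted voxel sums times voxel volume — standard for SPM-style
maps; a binarized mode is available. Whether the study's intracranial
volume included further compartments is unstated; GM + WM + CSF is assumed.
WMH segmentation is out of scope; WMH masks enter as inputs through
`mask_volume()`.

## The statistical layer

`compare_groups()` maps continuous variables to the Welch t-test, ordinal
(few-valued numeric) variables to the Wilcoxon rank-sum test, and
categorical variables to chi-square. Welch is the default because the
published group-comparison p-values are reproduced by the Welch form from
the printed summaries (a pooled-variance mode is provided; the publication
does not say which was used). `t_test_summary()` recomputes tests from
printed means/SDs/sizes, and the suite asserts it agrees with `t.test()` on
raw samples to numerical precision.

`fit_linear()` and `fit_interaction()` are ordinary least squares with
t-based 95% CIs. The interaction model codes status 0 = control, 1 = case,
so the interaction sign matches the published direction, and reports
per-group fitted lines plus partial residuals for interaction plots. In the
no-covariate case the interaction coefficient equals the difference of
per-group slopes, which the suite checks to 1e-10 as an oracle.

Variance inflation factors are computed from the model matrix
($1/(1-R^2_j)$) and cross-checked against `car::vif()` in the tests; a
warning fires when any *covariate* VIF reaches 5. The focal predictor and
interaction terms are excluded from the warning — an interaction is
intrinsically correlated with its main effects, and the published check
concerned the covariates.

BH-FDR (`bh_fdr()`, a validated wrapper over `p.adjust`) is applied within
each results family (one table, or one per-outcome screen); the publication
does not enumerate families, so membership is explicit at the call site.
P-values between 0.05 and 0.10 are flagged marginal.

## The proteomic screen

`screen()` fits one model per analyte, `outcome ~ analyte`, after log
transformation (RFU distributions are right-skewed) and column
standardization; both are configurable since the original description says
only "standardized". Covariates are projected out of both sides
(Frisch–Waugh) with degrees of freedom adjusted, keeping thousands of fits
vectorized; the tests verify exact agreement with a per-analyte `lm()`
oracle. Significance is raw `p <= alpha` with BH-adjusted values reported
alongside, and direction splits follow the slope sign. Probes are analysed
individually; protein-level sets deduplicate by symbol.

`pca_outliers()` reproduces the PCA outlier step with a deterministic rule:
robust Mahalanobis distance of the first two score dimensions, flagged
beyond the chi-square 0.999 quantile. The robust centre/covariance is a
one-step reweighted estimate (classical fit, chi-square 0.975 trim, re-fit)
— deterministic by construction, where resampling-based robust estimators
would make the flag set depend on RNG state. The published criterion
("extreme loadings") was visual; this is a reproducible stand-in.

Network arithmetic (`degree_and_hubs()`, `enrichment_vs_expected()`,
`overlap_sets()`) operates on supplied edge lists only: querying interaction
databases, and their internal enrichment statistics, are out of scope. The
reported enrichment p is a Poisson upper tail on the observed edge count
given the supplied expectation — a documented stand-in, not a reproduction
of any database's test. Hubs default to the top two degrees, mirroring how
highly connected proteins are singled out.

## The phantom and cohort generators

`generate_phantom()` emulates what the pipeline consumes, not MRI physics:
concentric compartments (CSF shell, GM ribbon, WM core — the shell/ribbon
interfaces exercise the same boundary false positives that sulci do),
tubular objects with bounded-curvature random-walk centrelines and
constant radius drawn strictly below 3 mm, ovoid cavities with axes above
3 mm, WMH-like patches with their own contrast, and additive Gaussian noise
(default SD 15 at WM means of 600/300, i.e. SNR ≈ 40/20). Default
conditions: 128³ voxels at 1 mm isotropic, 20 tubes, 3 ovoids, 2 WMH
patches. Everything is deterministic given the seed (base R
Mersenne-Twister). What the phantom does **not** model: partial-volume
mixing beyond rasterization, Rician noise, bias fields, anatomy. Passing
tests therefore demonstrate correctness of the algorithmic chain under
known truth, not clinical performance on real MRI.

`generate_cohort()` mirrors the study design: 24 cases and 24 controls by
default, ages around 51 ± 12, two-thirds female, lower education in cases,
lognormal ePVS volumes with no group difference, WMH an order of magnitude
higher in cases, and outcomes generated from exactly the linear/interaction
models the statistics layer fits (planted interaction slopes of 0.52 for
CDR-SB, −1.49 for MMSE, and so on). Outcomes are deliberately unclipped
linear-Gaussian, so planted coefficients are recoverable and CI coverage is
nominal; occasional tail values outside physiological ranges are accepted.
Analytes are lognormal with a stated subset constructed to correlate 0.8
with the ePVS z-score.

## Problem sizes and numerical choices

The test and acceptance runs use a 64³ phantom with 6 tubes for stage-level
checks and the full 128³ default phantom for the acceptance criteria;
recovery simulations use 200 replicates of the 48-subject cohort for CI
coverage and 100 replicates of 50 null analytes for the type-I rate —
sizes at which the Monte-Carlo error is a small fraction of the tested
bands. Ties and degenerate inputs resolve as follows: empty candidate masks
yield a count of 0 (not an error); zero-variance component profiles get
correlation 0; the inscribed diameter is floored at one voxel; distance
transforms treat outside-the-volume as background.

## Known limitations

Only white-matter ePVS are quantified (no basal ganglia or hippocampus,
no lobar maps); FLAIR-based WMH segmentation, Fazekas rating and regional
statistics are out of scope. The correlation-model reading (per component)
is one interpretation of an ambiguous published description, and the Sato
scales, detection cuts and clustering parameters are this package's own
defaults, not the original authors'. The phantom validates the algorithm,
not scanner realism.
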