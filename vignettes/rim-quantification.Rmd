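---
title: "Quantifying peritumoral ICG fluorescence rims: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying peritumoral ICG fluorescence rims: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rimquant)
```

## The measurement problem

Indocyanine green (ICG) given intravenously before liver surgery is cleared
by healthy hepatocytes but lingers in the compressed, immature parenchyma
immediately around colorectal liver metastases. On near-infrared images of
bread-loaf slices of the resected specimen this appears as a fluorescent
rim around a dark tumor core, over a noisy parenchymal background.
`rimquant` turns such an image plus its tumor/tissue annotations into four
scalar parameters:

* **MSFI** — mean signal fluorescence intensity: the mean over the rim
  band, defined as all tissue within 3 mm of the tumor;
* **MBFI** — mean background fluorescence intensity: the mean over tissue
  at least 5 mm from the tumor;
* **SBR** — the signal-to-background ratio MSFI / MBFI, the quantity that
  determines whether the rim is visible to a surgeon;
* the **maximum intensity**, by default over the analyzed loaf's tissue.

Tissue between 3 and 5 mm belongs to neither band. It is kept as an
explicit *gap* class rather than silently discarded so that the four
classes (tumor, rim, gap, background) always partition the tissue exactly
— an auditable invariant the test suite enforces.

## Distance and band construction

Distance is the Euclidean distance between pixel centers, with the tumor
treated as its rasterized pixel set rather than its polygon outline. This
convention is deliberate: it is well defined on the raster, independent of
vertex density, and exactly checkable against a brute-force all-pairs
oracle (which the tests do, on hundreds of random instances). The distance
transform itself is an exact Euclidean distance map; physical distance is
pixel distance times the pixel size (85 µm on the imaging system this
workflow targets).

Both band thresholds are inclusive: rim is distance ≤ 3 mm, background is
distance ≥ 5 mm. When a caller sets the two thresholds equal, a pixel at
exactly the shared value satisfies both definitions; the rim wins, keeping
the bands disjoint and the partition exact.

Polygon rasterization uses pixel-center sampling with the even-odd rule: a
pixel belongs to a region iff its center (column + 0.5, row + 0.5 with
0-based indices, origin top-left, y down) lies inside the polygon union.
This matches how common annotation viewers display masks and makes
axis-aligned rectangles exact (a 10 × 10 box covers exactly 100 pixels).

## Recalculation and exclusion rules

Three data-quality rules from the ex vivo workflow are implemented as
explicit, flagged operations rather than silent edits:

* **Stasis override.** Pooled ICG (stasis) in a slice inflates the
  background estimate. If the operator drew a representative background
  region, MBFI is recomputed over that region intersected with tissue at
  background distance; otherwise, if stasis polygons exist, stasis pixels
  are subtracted from the background band. Either path sets a
  `stasis_override` flag and recomputes the SBR.
* **Background pooling.** If the analyzed loaf offers less than 100 mm² of
  background tissue, background pixels from the specimen's other loaves
  (their own ≥ 5 mm regions) are appended in manifest order until the
  cumulative area reaches 100 mm²; MBFI becomes the pooled pixel mean
  (area-weighted by construction). The threshold is applied to the
  background region because that is the "healthy" tissue actually used for
  MBFI.
* **Exclusion.** If all loaves together still fall short, the lesion is
  flagged `excluded_insufficient_tissue`, MBFI and SBR are withheld, and
  the cohort layer drops the lesion with a logged reason. Exclusions are
  always reported, never silent.

The analyzed loaf is the one with the largest rasterized tumor
cross-section — the standard surrogate for "the slice through the center
of the tumor" for a roughly ellipsoidal lesion; ties break to the lowest
loaf index so the choice is deterministic.

The maximum-intensity scope is configurable (`tissue`, `image`, `rim`)
because "the maximum of the fluorescent image" is genuinely ambiguous;
the default is the analyzed loaf's tissue, which avoids counting
calibration artifacts or reflections outside the specimen.

## Clinical covariates

* **RECIST 1.1 (single lesion).** Percent change of the longest diameter
  against baseline: disappearance is a complete response, a decrease of at
  least 30% a partial response, an increase of at least 20% progressive
  disease, anything between stable disease. Exact threshold values go to
  PR/PD — the "at least" wording of those categories is taken to dominate
  the overlapping "maximum" wording of stable disease. The formal RECIST
  5-mm absolute growth minimum is not applied; only the percentage rule is
  used here. Multi-lesion sum-of-diameters scoring is out of scope: each
  tumor is scored separately.
* **Brunt steatosis.** none < 5%, mild 5–<34%, moderate 34–<67%, severe
  ≥ 67%. The printed bins (5–33, 34–66) leave 33–34 and 66–67 unassigned;
  the scheme is contiguous, so each gap folds into the lower grade.
* **Pretreatment** means the last chemotherapy cycle started within three
  months before surgery, operationalized as 90 days (inclusive). Whether
  the original analysis used calendar months or a day count is unknowable
  from the published rule; 90 days is documented as the package's
  convention.

## Statistical layer

Group comparisons follow the reporting style of the field: parameters
summarized as mean ± SD are compared by pooled-variance one-way ANOVA
(with two groups, F is exactly the squared pooled t), parameters
summarized as median [IQR] by the Mann–Whitney U test. The default map —
maximum intensity, age, BMI, diameter by ANOVA; MSFI, MBFI, SBR by
Mann–Whitney — is configurable per parameter, since no normality-testing
procedure is part of the published workflow. `anova_from_summary()`
computes the identical F and p from per-group mean/SD/n alone, which makes
published summary tables independently checkable.

Numerical conventions, fixed so results are reproducible to the digit:

* Quantiles (medians, IQRs) use linear interpolation (R type 7).
* Mann–Whitney: for combined n ≤ 12 the exact null is enumerated over all
  group assignments with tie-averaged ranks (so tied data are exact too;
  two identical groups give p = 1 by symmetry); larger samples use the
  normal approximation with tie and continuity corrections.
* Chi-square is Pearson's statistic without continuity correction; on a
  2 × 2 table it equals the closed form N(ad − bc)² / (r₁r₂c₁c₂).
  On the published pretreatment-by-sex table (3:7 vs 16:6) this gives
  χ² ≈ 5.203, p ≈ 0.0226 — a likelihood-ratio variant would give ≈ 0.022;
  Pearson is retained as the named default.
* Kruskal–Wallis uses the tie-corrected H with the χ² approximation.
* Spearman is Pearson on tie-averaged ranks with the two-sided t
  approximation on n − 2 degrees of freedom.
* Regression is ordinary least squares of each fluorescence parameter on
  pretreatment (0/1), superficiality (capsular = 1) and tumor size in cm,
  with per-coefficient t tests on n − 4 degrees of freedom; rank-deficient
  designs are an error naming the collinear columns.
* No multiple-testing correction is applied, and the reporting threshold
  is 0.05; p values display half-up-rounded to three decimals with
  "<0.001" below that.
* The RECIST stratification is emitted as descriptive summaries only —
  response subgroups of a 32-patient cohort are far too small to test.

## The synthetic phantom: what it emulates

`generate_phantom()` paints, on a pixel grid, a tumor ellipse at a low
core level, tissue as a larger ellipse, and outside the tumor the
noise-free intensity

$$ I(d) = b + a\,e^{-d/\lambda}, $$

with $d$ the distance to the tumor in mm, plus optional stasis blobs and
additive Gaussian noise truncated at zero. The exponential profile is a
modeling choice, not a measured fact — published images show rims but no
profile — chosen because it yields a closed-form discrete band average,
$b + a\,\langle e^{-d/\lambda}\rangle$, that serves as an exact oracle:
with zero noise the pipeline must reproduce it to 1 part in 10⁹, and it
does. The annotations are generated as polygons and rasterized by the
pipeline's own rasterizer before painting, so the ground truth refers to
exactly the pixels the pipeline later measures; there is no boundary
mismatch term.

Defaults (280 × 380 grid of 85 µm pixels, i.e. a 23.8 × 32.3 mm slice;
4 × 3 mm tumor in a 14 × 10.5 mm tissue ellipse; b = 0.104 a.u.;
a = 2.2 a.u.; λ = 1 mm; noise SD 0.02 a.u.) were chosen once so that the
untreated phantom lands near the magnitudes reported for untreated
patients — rim-band mean ≈ 0.65–0.7 a.u., background ≈ 0.104 a.u., maximum
≈ 2.3 a.u. The true rim width and decay in patients are unknown beyond
"up to a few mm"; the truth manifests label these as placeholder
parameters. Noise is additive truncated-Gaussian, not Poisson, because the
exported images are post-processed device outputs in arbitrary units, not
photon counts.

`generate_multi_loaf_specimen()` varies the tumor cross-section
elliptically across loaves (maximal at the designated central loaf), and
can shrink one loaf's tissue so its background falls below 100 mm² — the
constructions needed to exercise central-loaf selection, pooling and
exclusion end to end.

What the phantom does *not* emulate: spatial autocorrelation of parenchymal
texture, vascular structures, illumination falloff, specular reflections,
partial-volume effects at the tumor boundary, and registration error
between white-light and NIR channels. Passing phantom tests therefore
validates the geometry and arithmetic of the pipeline, not its robustness
to real-tissue appearance.

## The synthetic cohort: planted effects

`generate_cohort()` draws covariates with the study cohort's structure
(chemotherapy prevalence 10/32, capsular 22/32, diameters normal with mean
29.9 mm and SD 15.4 mm left-truncated at 5 mm by rejection, steatosis
grades 9:19:4:0) and fluorescence outcomes as log-normal baselines
(untreated medians: MSFI 0.65, MBFI 0.104, SBR 6.08 a.u.; maximum 1.9 a.u.
before the size effect) plus exactly linear planted effects — chemotherapy
−0.36 on MSFI, −3.8 on SBR, −0.72 on maximum intensity; +0.25 on maximum
per cm of tumor — plus Gaussian residuals. The log-normal scale respects
the skew implied by median/IQR reporting of the real parameters.

Outcomes are deliberately *not* truncated at zero: truncation would bend
the planted linear model and bias least-squares recovery, which is the
property the cohort exists to test. The cost is that the deep null tail
can dip below zero, which a physical intensity cannot. Recovery is scored
by whether each planted coefficient lies within ±2 reported SE of its
estimate across 100 seeded replicates of n = 200 cohorts; the skewed
baselines cost roughly a point of coverage relative to Gaussian residuals,
which the 93% acceptance margin is there to absorb.

## Problem sizes and determinism

The test suite builds everything it needs in code: phantoms on 140 × 180
grids of 170 µm pixels (the same physical geometry at a quarter the pixel
count), oracle checks on random masks up to 64 × 64, cohorts of 32–200
patients with 100-replicate recovery runs, and a three-patient file-based
pipeline round-trip. All random draws are seeded; phantom and cohort
generation restore the caller's RNG state, and rerunning the pipeline on
identical inputs produces byte-identical result tables (the audit log
records the package version and a configuration hash alongside per-lesion
band pixel counts, flags and pooling order).

## Known limitations

* The rim/background thresholds assume co-registered white-light and NIR
  frames as produced by the imaging system; no registration is performed.
* Sub-pixel distance (polygon-outline distance) is not implemented; on
  85 µm pixels the raster convention differs from it by at most one pixel
  diagonal, far below the 3 mm band width.
* One lesion per patient is assumed in the statistics layer; mixed-effects
  extensions for multi-lesion cohorts are out of scope.
* TIFF output is 16-bit integer with an explicit intensity scale recorded
  in the truth manifest; 32-bit float export is not supported by the
  underlying writer.
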