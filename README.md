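# rimquant

Quantification of the indocyanine-green (ICG) fluorescence rim around
colorectal liver metastases in ex vivo near-infrared images, with the
cohort-level statistics used to relate that rim to patient and tumor
characteristics.

## The problem

ICG injected before liver surgery is cleared by healthy hepatocytes but is
retained in the compressed parenchyma around a metastasis, so on NIR images
of bread-loaf slices of the resected specimen each lesion shows a bright
peritumoral rim over a dim parenchymal background. The strength of that rim
— and its contrast against background — is what makes fluorescence-guided
surgery work, and it varies strongly between patients (notably with
neoadjuvant chemotherapy). `rimquant` makes the rim measurable and the
cohort comparisons reproducible, for surgeons and imaging researchers
running ex vivo back-table workflows.

From a NIR image (grayscale TIFF, 85 µm/pixel by default) and tumor/tissue
polygon annotations (GeoJSON), the package builds distance-banded masks and
computes four parameters:

- **MSFI** — mean intensity over the *rim*: tissue within 3 mm of the tumor
  (Euclidean distance between pixel centers, tumor taken as its raster
  region);
- **MBFI** — mean intensity over the *background*: tissue ≥ 5 mm from the
  tumor (the 3–5 mm band is an explicit, unassigned gap);
- **SBR** = MSFI / MBFI;
- **maximum intensity**, by default over the analyzed loaf's tissue.

The workflow's data-quality rules are first-class operations: background
recalculation when ICG stasis contaminates a slice (operator override
region, or stasis subtraction), pooling of background pixels across bread
loaves when the analyzed slice offers < 100 mm² of healthy tissue, and
flagged exclusion when pooling still falls short. The analyzed loaf is the
one with the maximal tumor cross-section. A clinical layer derives RECIST
1.1 response classes, Brunt steatosis grades and 90-day pretreatment
status, and a statistics layer reproduces the standard battery: one-way
ANOVA / Mann–Whitney U group comparisons, Pearson chi-square,
Kruskal–Wallis across steatosis grades, Spearman correlation with tumor
size, and multiple linear regression of each fluorescence parameter on
pretreatment, superficiality and tumor size.

Because patient images cannot be shipped, the package includes synthetic
generators with exact ground truth: phantoms with an exponential rim
profile `b + a·exp(−d/λ)` (closed-form band averages make the pipeline
exactly checkable) and cohorts with planted covariate effects (chemotherapy
−0.36 MSFI, −3.8 SBR, −0.72 maximum; +0.25 maximum per cm of tumor) for
regression-recovery experiments.

## Worked example

```r
library(rimquant)

# a synthetic bread loaf: 4 x 3 mm tumor in a 14 x 10.5 mm slice, 85 um px
ph <- generate_phantom(phantom_spec(seed = 7))
shape <- dim(ph$image$pixels)
bm <- build_band_masks(rasterize(ph$annotations$tumor, shape),
                       rasterize(ph$annotations$tissue, shape),
                       ph$image$pixel_size_um)
bm
#> <band_masks> rim <= 3 mm, background >= 5 mm (85 um px)
#>   tumor         5208 px     37.63 mm^2
#>   rim          12952 px     93.58 mm^2
#>   gap          13060 px     94.36 mm^2
#>   background   32672 px    236.06 mm^2

quantify_loaf(ph$image, bm)
#> <lesion_result>
#>   MSFI 0.6985 a.u. | MBFI 0.1076 a.u. | SBR 6.491 | max 2.174 a.u.
#>   background area 236.06 mm^2; loaves: phantom-1
#>   flags: none
```

The measured MSFI (0.6985 a.u.) is the rim-band mean of the phantom's known
profile (analytic value 0.6987 a.u.; the gap is the planted noise), the
background recovers the parenchymal level 0.104 a.u. up to noise, and the
SBR ≈ 6.5 is the contrast a surgeon would see for an untreated lesion.

Cohort level, on a synthetic 32-patient cohort with planted effects:

```r
co  <- generate_cohort(cohort_spec(seed = 7))
rep <- run_paper_analyses(co$records)
rep$by_pretreatment$msfi_au
#> msfi_au: pretreated 0.17 [0.10, 0.60] vs untreated 0.64 [0.54, 0.83] | mann_whitney_u (stat 51, p 0.029)
rep$ols$max_intensity_au
#> <regression_fit> max_intensity_au ~ pretreatment + superficiality + size_cm (n = 32)
#>   intercept         2.0592 (SE 0.3187)  p <0.001
#>   pretreatment     -0.6763 (SE 0.2128)  p 0.004
#>   superficiality   -0.1816 (SE 0.1896)  p 0.346
#>   size_cm           0.2384 (SE 0.0831)  p 0.008
```

The pretreated arm shows the planted loss of rim signal (median MSFI 0.17
vs 0.64 a.u.), and the regression recovers the planted maximum-intensity
effects (−0.72 per pretreatment, +0.25 per cm) within sampling error.

A file-based pipeline (`run_pipeline()` over a directory of
`<patient>__<loaf>.tif` / `.geojson` pairs plus a covariate CSV, or the
`inst/scripts/rimquant` front-end with subcommands `quantify / cohort /
simulate / run`) writes `results.csv`, `report.json` and an `audit.json`
with per-lesion band pixel counts, flags, pooling order and a
configuration hash; identical inputs give byte-identical results.

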