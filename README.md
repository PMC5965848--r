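# petresp

PET-based treatment-response analysis for preclinical xenograft studies.

## The problem

In small-animal oncology studies, response to therapy is tracked two
ways: caliper measurements of the subcutaneous tumor, and PET imaging of
tracer uptake ([¹⁸F]FDG for glycolysis, [¹⁸F]FLT for proliferation).
Relating the two requires a chain of non-trivial steps — delineating the
lesion in a noisy, low-resolution PET volume, quantifying its uptake,
classifying the volumetric response, and asking whether an uptake-change
score can discriminate responders. `petresp` implements that chain as
tested, reusable R functions, for imaging scientists running
longitudinal treatment studies in mouse models.

## The methods at its core

**Segmentation** is a seeded random walker on the voxel lattice. With
voxel intensities $g_i$ min–max normalized over the region of interest,
edges carry weights $w_{ij} = \exp(-\beta (g_i - g_j)^2)$; every
unlabeled voxel gets the probability that a random walk from it reaches
a target seed (lesion core) before a background seed. The probability
field solves the combinatorial Dirichlet problem on the weighted
lattice, and thresholding it at $p$ (default 0.5) yields the lesion
mask.

**Quantification** over the mask: SUVmax, SUVmean, metabolic tumor
volume MTV (mm³), and total lesion glycolysis/proliferation
TLG/TLP = SUVmean × MTV, with SUV = concentration × body weight /
injected activity (uniform whole-body distribution ⇒ SUV = 1).
Longitudinal change of any metric is 100 × (post − pre)/pre.

**Response classification**: caliper volume V = L·l²/2; tumor volume
response TVR = 100 × (post − pre)/pre; PR if TVR ≤ −30, PD if
TVR > +20, SD between — a volume-adapted RECIST score, with cohort
summaries per baseline size stratum (< 150 mm³ vs larger).

**Responder discrimination**: empirical ROC of a score (e.g. ΔSUVmax,
responders low) against responder status (PR vs SD∪PD); trapezoidal AUC
(provably the Mann–Whitney pair-ordering fraction), two-sided
permutation p-value against chance, and the Youden-optimal cutoff with
its sensitivity and specificity.

A synthetic-data module (`make_phantom()`, `make_cohort()`,
`run_study()`) generates PET phantoms and cohorts with known ground
truth, so the whole chain is validated end to end. See the methods
vignette (`vignettes/pet-response-methods.Rmd`) for models, parameters
and design choices.

## Worked example

Segment and quantify a noisy digital phantom (8:1 lesion contrast, 1 mm
PSF, Gaussian noise):

```r
library(petresp)
sp <- phantom_spec(c(24, 24, 24),
                   lesions = list(list(center = c(12, 12, 12),
                                       semi_axes = 4, uptake_contrast = 8)),
                   psf_fwhm = 1, noise = "gaussian", noise_scale = 0.4)
ph  <- make_phantom(sp, seed = 7)
seg <- segment_lesion(ph$volume, mask_bbox(ph$truth, pad = 4))
seg
#> Random-walker segmentation
#>   ROI: [4,4,4) -> [21,21,21)  beta = 90, p = 0.5, 6-connected
#>   seeds: 58 target, 1538 background
#>   mask: 257 voxels (257 mm^3)
lesion_metrics(ph$volume, seg$mask)
#> Lesion metrics (FDG, baseline)
#>   SUVmax     9.012
#>   SUVmean    7.591
#>   MTV          257 mm^3
#>   TLG         1951 SUV*mm^3  (257 voxels)
```

The recovered mask has exactly the 257 voxels of the ground-truth
sphere (radius 4 mm at 1 mm spacing), and SUVmean 7.59 sits ~5% below
the true lesion SUV of 8 — the partial-volume bias of the 1 mm PSF.

Classify the packaged 13-animal response table and summarize by
stratum:

```r
t1  <- published_response_table()
tab <- tvr_table(t1$animal_id, t1$pre_volume_mm3, t1$post_volume_mm3)
summary(tab)
#> Response-category fractions by baseline size stratum (%):
#>         PR SD PD
#>   small 33 17 50
#>   large 29 43 29
```

(Animal `mouse04`, printed TVR +21.0, is classified PD here because
+21.0 exceeds the +20 progression bound; its published label is SD —
see the vignette for the three pinned discrepancies in the published
table.)

Run a full synthetic study — cohort generation, phantom rendering,
segmentation, quantification, response classification, ROC:

```r
st <- run_study(cohort_spec(n_animals = 13), seed = 42)
st
#> Synthetic PET treatment-response study, 13 animals
#>   TVR classes (true): PR=4 SD=5 PD=4
#>   TVR class recovery: 100%
#>   dSUVmax ROC: AUC = 1.000 (p = 0.0028), cutoff -18.4
```

All 13 generated TVR classes are recovered exactly, and the measured
ΔSUVmax separates responders perfectly (exact permutation p = 2/715).

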