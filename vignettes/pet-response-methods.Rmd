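---
title: "Methods: random-walker PET segmentation and volume-adapted response analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: random-walker PET segmentation and volume-adapted response analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petresp)
```

## What the package computes

`petresp` analyzes treatment response in small-animal PET studies of
subcutaneous tumors (the motivating setting is a triple-negative breast
cancer xenograft model under taxane chemotherapy, imaged with
[^18^F]FDG and [^18^F]FLT). Four analysis stages are chained:

1. **Lesion delineation** by a seeded random walker on the voxel lattice.
2. **Uptake quantification**: SUVmax, SUVmean, metabolic tumor volume
   (MTV) and total lesion glycolysis/proliferation (TLG/TLP), with
   longitudinal percentage changes.
3. **Response classification** of caliper tumor volumes via a
   volume-adapted RECIST score, the tumor volume response (TVR).
4. **Responder discrimination**: ROC analysis of an uptake-change score
   (typically ΔSUVmax) against the TVR classes, with a permutation test
   and Youden-optimal cutoff.

A synthetic-data module generates digital phantoms and cohorts with known
ground truth so that every stage, and the chain as a whole, can be
validated quantitatively.

## The random-walker model

The PET volume is viewed as a lattice graph: voxels are nodes, adjacent
voxels (6-connected by default) are joined by edges. Voxel intensities
$g_i$, min–max normalized over the region of interest, define edge
weights

$$w_{ij} = \exp\!\big(-\beta\,(g_i - g_j)^2\big),$$

so a strong intensity gradient is a barrier to the walk. Given *seed*
voxels labeled target (the hot lesion core) or background, every
unlabeled voxel is assigned the probability that a random walk started
there, stepping to neighbor $j$ with probability
$w_{ij}/\sum_k w_{ik}$, reaches a target seed before a background seed.
This probability field solves the combinatorial Dirichlet problem on the
weighted lattice: it is harmonic at every unlabeled voxel (each value is
the weighted mean of its neighbors) with boundary values 1 on target and
0 on background seeds. Because there are two labels, the background
probability is the complement, and one linear solve suffices. The binary
lesion mask keeps voxels with target probability above a threshold $p$.

The harmonic structure gives the solution a maximum principle (all
probabilities lie in $[0,1]$, and no unlabeled voxel exceeds its
neighborhood extremes) and makes the mask monotone in $p$: raising the
threshold can only shrink the mask. Both properties are enforced by
tests, along with equivalence to an independent dense absorbing-chain
solution on small random instances.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `beta` | 90 | edge-weight sharpness (dimensionless; scale-free because intensities are normalized to $[0,1]$ over the ROI) |
| `prob_threshold` | 0.5 | probability cut; the symmetric choice for two labels |
| `connectivity` | 6 | lattice stencil (6, 18 or 26 neighbors) |
| `auto_target_fraction` | 0.90 | auto-seeding: voxels at ≥ 90% of the ROI max become target seeds |
| `auto_background_shell` | 1 | ROI boundary shell (voxels) used as background seeds |
| `solver_tolerance` | 1e-8 | relative residual of the iterative solver |

The automatic seeding rule is this package's convention (target seeds
from the ROI intensity peak, background seeds from the ROI boundary
shell); published descriptions of random-walker PET delineation leave
the seeding protocol open, and any `seed_map` can be supplied instead.
One connected lesion per ROI box is assumed; multiple lesions are
handled by calling the segmentation once per ROI.

### Numerical notes

The Dirichlet system is symmetric positive definite and sparse. It is
solved by a direct sparse factorization up to $10^5$ unknowns and by
Jacobi-preconditioned conjugate gradients above that, after symmetric
diagonal scaling in both cases. The scaling matters at large `beta`: a
voxel whose incident edges are all nearly zero leaves the raw system
arbitrarily ill-conditioned even though its probability is a perfectly
well-behaved weighted average of its neighbors.

There is a genuine information limit here: across an intensity barrier
with weight $e^{-\beta}$, the solution depends on ratios of numbers of
that magnitude. Once the weakest relevant edge drops below roughly
$e^{-20}$ of the strongest, those ratios fall under double-precision
resolution and *no* solver — sparse, dense, or otherwise — can pin the
probabilities down. On real PET images at the default `beta = 90` this
regime is confined to the lesion boundary (which the threshold decision
is robust to); it becomes pervasive only on adversarial inputs such as
i.i.d. random voxel values. The solver-vs-oracle equivalence tests
therefore draw their random instances with `beta` in $[1, 12]$ — five
orders of magnitude of weight contrast, but safely inside the
determinate regime — and assert agreement to $10^{-6}$.

Degenerate inputs are defined, not errors: a constant ROI yields all
weights 1 (isotropic walk); a fully seeded volume returns the seed
indicator; an unlabeled region disconnected from every seed (impossible
on a box ROI, which is a connected lattice, but possible with exotic
hand-made seed maps on disconnected domains) would receive probability 0
with a warning.

## Quantification

SUV normalizes tissue activity concentration by injected dose per unit
body mass,
$\mathrm{SUV} = C \,[\mathrm{kBq/mL}] \cdot W\,[\mathrm{g}] / (A\,[\mathrm{MBq}] \times 1000)$,
with the conventional 1 g ≈ 1 mL tissue density, so uniform whole-body
distribution gives SUV = 1. No decay correction is applied (assumed done
by the scanner pipeline) and no partial-volume correction is attempted.
Conversion is lazy — raw volumes stay inspectable until
`to_suv()` is called.

Per-lesion metrics over the segmented mask: SUVmax and SUVmean are the
maximum and arithmetic mean over mask voxels (SUVmax is VOI-restricted,
not a fixed-size peak sphere); MTV is the voxel count times the voxel
volume in mm³; TLG (FDG) or TLP (FLT) is SUVmean × MTV, an exact
identity by construction. Longitudinal change of any metric is
$100 \times (\mathrm{post} - \mathrm{pre})/\mathrm{pre}$, defined only
for positive baselines; an empty mask gives MTV = 0 with flagged SUV
fields rather than an error.

## Volume-adapted response (TVR)

Caliper tumor volume uses the standard prolate-ellipsoid approximation
$V = L \times l^2 / 2$ (mm³) from the long and short sides. TVR is the
percentage change in caliper volume over treatment, computed per animal
from its own pre/post pair. Classification:

* **PR** (partial response): TVR ≤ −30
* **SD** (stable disease): −30 < TVR ≤ +20
* **PD** (progressive disease): TVR > +20

The boundary convention (−30 inclusive to PR, +20 inclusive to SD)
follows the usual RECIST sign logic; both cuts are exposed as
parameters. Classification always uses the unrounded TVR; printing
rounds to one decimal, half away from zero. Cohorts are summarized per
baseline size stratum (small < 150 mm³ ≤ large) as whole-percent
category fractions.

The package carries the 13-animal published response table as a
regression fixture (`published_response_table()`). Recomputing TVR from
its printed volume pairs reproduces the printed value for 11 of 13 rows:
one row prints −56.3 where its own pre/post pair gives −56.8 (most
plausibly a transcribed baseline volume), and one prints −84.3 where the
pair gives −84.2487 (a final-digit rounding difference). One row with
TVR +21.0 is labeled SD in print although it exceeds the +20 bound;
whether the original classification used a different convention for that
animal is undeterminable from the published material. The tests pin all
three discrepancies explicitly rather than smoothing them over.

## ROC responder discrimination

Responder means PR; non-responders pool SD and PD. For a score where
responders are expected low (ΔSUVmax: deeper uptake decline in
responders), a case is called positive when score ≤ threshold, the
threshold sweeping the distinct observed scores. The AUC is the
trapezoidal area of the empirical curve and equals, on every instance,
the Mann–Whitney fraction of correctly ordered responder/non-responder
pairs with ties counted ½ — the test suite checks this identity against
exhaustive pair counting. Significance against AUC = 0.5 is a two-sided
label-permutation test: exact (full enumeration of labelings) when
feasible, seeded Monte-Carlo with the add-one estimator otherwise. The
operating cutoff maximizes Youden's $J = \mathrm{sens} + \mathrm{spec} - 1$,
with ties broken toward higher sensitivity and then the more negative
threshold; it is reported as the midpoint between the adjacent distinct
scores straddling the chosen threshold, making the reported number
deterministic and documented rather than a datum value.

## The synthetic-data generator

**Phantoms** (`make_phantom()`): hot ellipsoidal lesions on a uniform
low background, with the noiseless pre-blur voxel values exactly
`background_suv` outside and `background_suv × uptake_contrast` inside
(a voxel is inside when its center satisfies the ellipsoid inequality,
the same center-counting convention MTV uses). An isotropic Gaussian
PSF (separable convolution, kernel truncated at 3.5σ, edges replicated)
emulates scanner resolution, followed by additive Gaussian noise or
scaled-Poisson noise (Poisson with mean value/scale, multiplied back by
scale — a monotone count-statistics approximation). Noise is applied
after blur. Acquisition metadata defaults to 10 MBq injected and 25 g
body weight — typical mouse-scan values chosen once as conventions,
inert because only their ratio enters SUV.

**Cohorts** (`make_cohort()`): true TVR values are drawn strictly inside
per-class intervals — defaults PR (−90, −30), SD (−30, +20], PD
(+20, +200], bounding the span observed in the treated xenografts
(−84.3% to +181.3%) — so classification recovers the generating class
for every animal, with no boundary values emitted. Class counts are
apportioned by largest remainder (13 animals at the published fractions
give exactly 4 PR / 5 SD / 4 PD). Baseline volumes are log-uniform over
40–580 mm³, spanning both size strata; baseline SUVmax is uniform over
6–12. The uptake response is coupled to the volume response linearly
(slope 1, Gaussian noise of SD 10 percentage points by default, clamped
above −99% since uptake cannot go negative); the slope and noise are the
generator's own study conditions, chosen to mirror the qualitative
pattern that uptake decline tracks volumetric response closely in
responders and loosely elsewhere.

**End-to-end study** (`run_study()`): each animal's two scans are
rendered as phantoms whose sphere radius matches the caliper volume and
whose lesion uptake matches the true SUVmax (floored just above the
blood-pool background — uptake below background is not physical), on a
32³ grid at 1 mm spacing with 1 mm PSF and SUV-scale Gaussian noise of
SD 0.2. The chain segment → quantify → delta → respond → ROC then runs
exactly as it would on real data. These problem sizes (24–32 voxels per
axis, 13 animals, 20 phantom replicates) were chosen as the smallest
scales at which partial-volume blur, noise and class structure all
express themselves clearly.

What the phantoms deliberately do **not** model: attenuation, scatter,
randoms, reconstruction artifacts, respiratory motion, necrotic cores,
irregular lesion shapes, and background heterogeneity (organs, bladder).
Passing the recovery tests therefore demonstrates the correctness of the
algorithmic chain under controlled conditions, not clinical-grade
robustness on real scans; on real data the ROI placement and the
`beta`/`p` choices matter and should be reviewed per study.

## Design choices where the ground was open

* **Weight function**: the Gaussian-on-intensity-differences weight with
  ROI min–max normalization is the standard random-walker construction;
  normalization makes `beta` transferable across intensity scales.
* **`p = 0.5` default**: the symmetric two-label choice.
* **6-connectivity default**: the smallest lattice stencil, matching the
  plain-lattice formulation; 18/26 available.
* **SUVmax inside the segmented VOI**: published usage does not state
  whether a wider field was searched; VOI-restricted is this package's
  documented choice.
* **Per-animal TVR**: the response statistic is computed from each
  animal's own volume pair (the published per-animal table plainly does
  this), not from group medians.
* **Classification boundaries**: the inline published threshold
  definitions are internally inconsistent; the convention here (PR at
  ≤ −30, PD at > +20) matches standard RECIST sign logic and 12 of the
  13 published labels, and both cuts are parameters.
* **Permutation p-value**: the original analysis software and test are
  unstated; a label-permutation test is assumption-free and exactly
  reproducible from a seed.
* **DICOM scope**: only axis-aligned, single-series, uncompressed
  little-endian slices are read, and oblique geometries are rejected
  rather than resampled — silent resampling hides errors in preclinical
  pipelines. NIfTI is the native format; metadata travels in a JSON
  sidecar because no standard preclinical DICOM convention exists for
  injected dose and body weight in this setting.

## Known limitations

* The random walker is two-label only; multi-lesion scans need one ROI
  per lesion.
* No partial-volume correction: SUVmean under blur is biased low near
  the boundary (the phantom tests quantify this at ≈ 6% for a 4 mm
  radius sphere at 8:1 contrast and 1 mm PSF).
* Permutation p-values at very small cohorts have a resolution floor of
  $2/\binom{n}{n_+}$.
* The caliper formula assumes a prolate ellipsoid; markedly flat or
  irregular tumors violate it.
* Reported AUCs and cutoffs from the original study cannot be
  reproduced here because the underlying per-animal uptake values were
  not published; the package validates the machinery on synthetic
  cohorts with known truth instead.
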