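---
title: "Atlas-based landmark annotation and its evaluation: methods"
author: "multiatlas package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atlas-based landmark annotation and its evaluation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Geometric morphometrics quantifies shape through the coordinates of
anatomical landmarks, traditionally digitized by a trained observer on
each 3D volume (e.g. a microCT scan of a mouse mandible). Manual
annotation is slow and carries intra- and inter-observer error, which
limits the sample sizes that phenotyping and genetic-mapping studies can
reach. Atlas-based annotation replaces most of the manual work with
image registration: a small set of carefully annotated reference volumes
("templates") carries its landmarks onto unannotated "targets" through
deformable transforms. This package implements three such pipelines and
the statistical machinery to judge whether the landmarks they produce
support the same morphometric conclusions as expert annotation:

* **Single atlas** — an unbiased population average image is built,
  annotated once, and its landmarks are back-projected to every sample
  by reversing each sample-to-atlas transform.
* **Improved single atlas** — instead of annotating the constructed
  atlas directly, the manual landmarks of the templates are warped into
  atlas space and averaged; back-projection is unchanged.
* **Multi-atlas (MAAP)** — every template is registered directly to
  each target; its landmarks, rasterized as small spherical labels, are
  warped onto the target and fused into a consensus label map whose
  per-label centroids are the final landmarks. Because each landmark
  arrives with one estimate per template, outliers can be detected by
  the spread of those estimates — something structurally impossible in
  the single-atlas routes.

## Data model and conventions

Volumes are 3D scalar grids with per-axis spacing (mm) and a world
origin; the internal world frame is LPS with 0-based voxel indices and
the voxel-center convention, so `world = origin + index * spacing`.
Slicer `.fcsv` files, which store RAS coordinates, have their x and y
axes negated on read and write. Displacement transforms are dense
per-voxel fields on the fixed grid in the pull-back convention: the
field value at a fixed-space point is the offset to the corresponding
moving-space point. Landmark warping is exact point mapping through the
interpolated field and therefore free of resampling error; to carry
points the other way the field is inverted by fixed-point iteration
(round-trip residual below 0.05 voxel at 99% of voxels, checked and
reported on every inversion).

Landmarks become label maps by rasterizing a sphere of radius 2 voxels
around each landmark (the radius used for annotation label maps; the
coarser 4-voxel variant mentioned for atlas annotation overviews is a
config option). Sphere membership is evaluated in voxel units for
isotropic grids and in world distance otherwise; overlapping spheres
resolve to the nearest landmark with exact ties to the lower index, a
deterministic rule chosen because the annotation sources are silent on
it. Label maps are warped by interpolating each label's indicator
linearly and taking the arg-max, which avoids the label erosion of
nearest-neighbour resampling; ties prefer background and then the
lowest label.

## Registration engine

The reference implementation of this style of pipeline uses a
feature-based deformable registration system (attribute vectors plus
mutual-saliency weighting). Re-implementing that system is out of
scope here; what the pipelines require is the *contract* — a dense,
invertible displacement field with a reported similarity. The built-in
engine is multi-resolution symmetric-force demons:

* Intensities are normalized to [0, 1]; a Gaussian image pyramid is
  built by factor-2 block averaging, capped so the coarsest level keeps
  at least ~12 voxels along the shortest axis.
* Each iteration warps the moving image, computes the symmetric demons
  force `-(w - f) * grad / (|grad|^2 + (w - f)^2)` capped at
  `max_step` (2 voxels), smooths the update ("fluid" sigma, 1 voxel),
  adds it to the field and smooths the field ("diffusion" sigma,
  1 voxel).
* Iterations per level default to 100/60/30 (coarse to fine) with
  early stopping when the mean-squared error stalls; the best-so-far
  field is kept, and a monotone, substantive increase in the objective
  raises a divergence error with the metric trace attached.
* The optimizer contains no stochastic step, so results are bit
  reproducible without seeds.
* A center-of-mass translation initializes the coarsest level.

Two optional fidelity features echo the feature-based design in
simplified form: an attribute mode that averages the demons force over
an intensity + gradient-magnitude channel stack, and a saliency mode
that down-weights updates where the local residual variance is large
relative to the local gradient energy. Both default to off and are
exercised by tests only for convergence, not accuracy claims.

On the synthetic study the engine recovers known warps with median
landmark error well under 1 voxel, which is the property the pipelines
need; no claim is made of numerical equivalence with any external
registration package. An external engine can be substituted by
constructing `displacement_transform` objects from fields it writes
(`read_transform()` reads 4D NRRD vector images).

## Unbiased atlas construction

`build_atlas()` iterates: register all samples to the current
reference; average the warped intensities; move the reference by the
voxelwise mean displacement (small-deformation correction, i.e. the
mean image is resampled through the negated mean field); repeat. At
the fixed point the per-sample deformations into atlas space average
to zero, so the atlas sits at the deformation centroid of the
population and is unbiased with respect to the initializing sample —
verified by building atlases from different initial samples and
comparing their probability-surface masks (Dice) and mean intensities
(correlation), both ≥ 0.99 on the synthetic study.

Convergence is measured as the mean magnitude of the average field
over the *foreground* (voxels above half the maximum mean intensity):
outside the object the field is an arbitrary smooth extension with no
data support, and including it would mask convergence. The default
tolerance is 0.5 voxel with at most 10 iterations. The engine's
regularization imposes a sub-voxel floor (empirically ~0.3 voxel) on
this quantity, so tighter tolerances would spin without converging;
half a voxel means the atlas is within half a voxel of the population
centroid everywhere it matters, which is below the annotation noise.
The iteration log is stored and is monotone decreasing up to small
terminal oscillation.

Because a constructed average image has no fixed tissue-intensity
interpretation, surfaces for annotating the atlas are defined
probabilistically: each sample is binarized (the threshold is a
required, study-specific argument), warped into atlas space, and
averaged, giving per-voxel foreground frequencies that are exact
multiples of 1/n; the p-level surface is the boundary of the ≥ p mask.
Masks nest in p by construction. RMS surface distances between levels
are computed via Euclidean distance transforms in both directions with
the larger value reported and both logged, since the directionality is
otherwise ambiguous.

## Label fusion

Three fusers share one contract (inputs on a common grid, same label
alphabet):

* **Shape-based averaging (SBA)** — per class (background included by
  default), the signed Euclidean distance map of each input is
  averaged; each voxel takes the class of minimal mean signed
  distance, ties resolving to background then lowest label. An
  `include_background = FALSE` variant assigns background only where
  every label's mean distance is positive. The background-included
  default is the faithful reading of the method; note it implies that
  raters whose spheres are pairwise disjoint lose the label (the sum
  of center-to-sphere distances exceeding the radius is forced by
  disjointness), so SBA degrades gracefully only while inputs at least
  touch.
* **Majority vote (MV)** — the per-voxel modal label, ties to
  background then lowest label. A landmark whose label wins nowhere is
  *reported* lost rather than raised, so the caller can flag it; this
  is the known failure mode when warped labels overlap insufficiently.
* **STAPLE** — per landmark label, a binary
  expectation–maximization estimate of the hidden true segmentation
  and each rater's sensitivity/specificity, run inside a 3-voxel
  dilated bounding box of the label's union with the box's foreground
  fraction as prior, initialized at p = q = 0.99, tolerance 1e-6, at
  most 100 iterations, probabilities clamped to [1e-6, 1 − 1e-6]. The
  log-likelihood trace is returned and is non-decreasing (EM
  guarantee, asserted in tests).

In the high-agreement regime (pairwise input Dice ≥ 0.99) all three
give centroids within a voxel of each other, which is why the choice
of fuser matters little for low-variation populations; SBA is the
default for its smooth consensus labels.

## Template selection, gating, and outlier QC

Templates are chosen by k-means on the voxel-intensity vectors of the
samples warped into atlas space; within each cluster the member closest
to the cluster mean becomes a template, so the library spans the
population's variation instead of duplicating its mode. The
registration-quality gate for fusion keeps templates whose
post-registration correlation with the target passes either an absolute
threshold (default 0.9) or a keep-top-m rule; the applied rule and the
surviving template ids are recorded in every result, because the
published description of this gate names the statistic but not the
cutoff. Removing a gated-out template cannot change the fused result,
by construction.

For each landmark of each target, the per-template point estimates
(warped exact landmark points, not label centroids — point warping is
resampling-free, and the ambiguity between the two readings is noted
here deliberately) are compared to the final fused location; if at
least 2 of the k distances exceed a user threshold (default 5 voxels,
0.172 mm at 34.42 µm spacing) the landmark is flagged for manual
review. When a reference annotation is available the report also
counts correct flags, missed outliers and false hits.

## The synthetic study

Real microCT populations for this problem are not publicly deposited,
so the package ships a generator that makes the whole pipeline testable
with known ground truth. It emulates:

* a "mandible-like" base shape — an elongated body, an ascending ramus
  plate and condylar/coronoid/angular processes composed from
  ellipsoidal lobes, binarized and Gaussian-blurred (σ = 1.2 voxels)
  to mimic partial-volume smoothness; 16 landmarks sit at lobe poles,
  junctions and two curvature loci standing in for "type III"
  landmarks;
* inter-individual variation — per-sample random displacement fields:
  control-point displacements drawn N(0, sd²) with sd = 2 voxels on a
  4×5×4 grid, trilinearly upsampled and Gaussian-smoothed (σ = 15% of
  the shortest grid axis), rejection-sampled until the Jacobian
  determinant of id + u stays above 0.05 everywhere (no folding).
  Because smoothing attenuates the control-point amplitude, the
  realized field s.d. is ≈ 0.7 voxel, and binarized samples overlap at
  mean pairwise Dice > 0.9 on the default 64×96×64 grid — the
  "subtle variation" regime of a single-strain population;
* observer noise — isotropic Gaussian per landmark, two attempts per
  sample, averaged into the gold standard (GS). The per-landmark s.d.
  vector follows the characteristic error pattern of manual
  digitization (most landmarks precise; landmarks 7, 10, 12 and 16
  noisier, as curvature-defined points are), scaled by the single
  factor 0.36372 so that the *median* attempt-to-attempt distance is
  0.048 mm. The factor comes from the half-normal algebra: the
  distance between two attempts is √2·σ·χ₃, so per-landmark medians
  are √2·σ·1.5382 and the mixture median over the 16-landmark pattern
  is solved numerically once. The Gaussian form is an assumption and
  is flagged as such in the study manifest.
* ground truth — the truth landmarks of each sample are the exact
  images of the base landmarks under that sample's generating field,
  obtained by solving p + u(p) = q per point to 1e-10 voxels, and a
  conservation test re-derives them from the stored fields.

Defaults are n = 40 samples on a 64×96×64 grid at 0.03442 mm isotropic
spacing. What the generator does **not** emulate: scanner physics
(beam hardening, reconstruction artifacts, noise texture), anatomically
accurate mandible geometry, segmentation errors, and observer error
that is anisotropic or landmark-definition-dependent. Passing tests
therefore demonstrate the pipeline's correctness and its behavior
under controlled, realistic error magnitudes — not performance on any
particular real dataset.

The single-atlas arm needs an "expert" to annotate the atlas in
silico. The mechanism mirrors the real difficulty of that step: the
population-mean landmark positions are projected onto the chosen
probability surface (p90 by default) — a constructed surface that is
systematically offset from any individual's bone surface — and then
perturbed by observer noise over three averaged attempts. The
projection bias plus one back-projection registration is exactly why
the single-atlas route trails the others; the improved route replaces
the surface guess with averaged warped template landmarks, and the
multi-atlas route additionally replaces the shared atlas hop with
direct template-to-target registrations whose independent errors
average out in fusion. On the seeded synthetic study this ordering
(multi-atlas ≤ improved ≤ single, study-mean error) is reproduced
across seeds.

## Morphometric statistics

* **GPA** — configurations are centered, scaled to unit centroid size,
  and iteratively rotated to the evolving mean by SVD-based orthogonal
  Procrustes with reflections excluded (a biological-data default;
  a flag allows them), until the mean shape changes by < 1e-10.
* **Goodall F / Procrustes ANOVA** — after *joint* superimposition,
  F = [d²(mean_a, mean_b)/(1/n_a + 1/n_b)] /
  [Σ d²(xᵢ, group mean)/(n_a + n_b − 2)] with squared Euclidean
  distances in the aligned space. Significance by label permutation
  (one-sample mode) or by within-group bootstrap after translating
  both groups onto the grand mean (two-sample mode), p-values with the
  add-one convention (r + 1)/(B + 1) so they are never exactly zero.
  Reference analyses use 50,000 replicates; the test suite uses
  reduced replicate counts, which changes Monte-Carlo resolution, not
  validity. The null calibration (type-I rate within [0.03, 0.07] at
  α = 0.05) is checked by simulation.
* **EDMA form test** — mean inter-landmark distance matrices per
  group, their elementwise ratio, and T = max/min ratio; the null
  distribution of T permutes individuals between groups (the
  resampling unit is the individual configuration), and per-ratio
  bootstrap percentile intervals resample individuals within groups.
  A population against itself gives ratio ≡ 1 and T = 1; uniform
  scaling changes every ratio equally, leaving T at 1, which is the
  sense in which T measures localized form difference, not size.
* **Box M on PC scores** — with 36 samples against 48 coordinate
  variables a covariance test on raw coordinates is impossible, so
  covariance homogeneity is tested on principal-component scores of
  *separate* per-group Procrustes fits (separate, so that joint
  superimposition cannot leak covariance between groups), retaining
  components with ≥ 1% variance share. M = (N−k) ln|S_pooled| −
  Σ(nᵢ−1) ln|Sᵢ| with Box's chi-square scale factor and
  df = (k−1)p(p+1)/2 — 120 for p = 15, k = 2.
* **Paired rank test on digitization errors** — the published
  description conflates a Mann–Whitney U on paired error vectors with
  a Wilcoxon signed-rank test; the default here is the former with the
  latter behind a flag, and every report names which ran. The decision
  is three-way at α = 0.01: errors greater, less, or
  indistinguishable, per the tail the U statistic falls in.
* **Centroid-size agreement** — OLS regression of automated on
  reference centroid sizes (adjusted R²) plus a paired t test; the
  combination "R² ≈ 1 with significant t" is how a small systematic
  size bias shows up.

## Numerical choices and degenerate inputs

Ties in sphere rasterization, SBA and MV resolve deterministically
(background, then lowest label). Landmark voxel positions within 1e-6
of a grid point are snapped so symmetric spheres stay symmetric under
floating-point round-off. Field inversion refuses fields with
non-positive Jacobians beyond a 0.1% voxel fraction. STAPLE clamps
probabilities away from 0/1 to avoid EM degeneracy and refuses
all-foreground/all-background regions. Dice of two empty masks,
zero-variance correlations, empty probability surfaces, coincident
landmarks in EDMA, and n ≤ p groups in Box M all raise explicit
errors. Lost landmarks are carried as NA rows in error tables and
excluded from summaries rather than silently dropped.

## Problem sizes used by the test suite

The shipped validation runs at desk scale, chosen to exercise every
code path at meaningful accuracy: the method-ordering experiment uses
n = 14 samples on a 40×60×40 grid with k = 4 templates over three
seeds; initialization-insensitivity uses n = 10 on the same grid with
three initial samples; the Dice-regime check uses the full default
64×96×64 grid; statistical calibrations use 500 null simulations at
reduced replicate counts. The full-scale defaults (n = 40, 64×96×64)
and the real-data scale (≈200×600×300 voxels) run through the same
code paths unchanged.

## Known limitations

The demons engine assumes roughly matched intensity profiles and
overlapping fields of view; it is not a drop-in match for
attribute-based registration on low-contrast or truncated data. The
atlas update uses the small-deformation approximation, appropriate for
the subtle-variation regime but not for populations with large
morphological outliers. SBA loses labels whose warped spheres are
pairwise disjoint (see above); MV loses them earlier. The outlier
detector's false-hit rate is intrinsic to thresholding template spread
rather than error against truth — fused averages are often good even
when template estimates scatter. The synthetic generator's Gaussian
observer model and ellipsoid-composite geometry are idealizations;
conclusions about real scanners, segmentations or taxa require real
annotated data.
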