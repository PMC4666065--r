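# multiatlas

Automated anatomical landmark annotation for 3D volumetric images
(microCT and similar), with the statistics to judge whether the result
can replace expert annotation.

Geometric morphometrics needs landmark coordinates on every specimen,
and manual digitization of 3D volumes is the bottleneck: slow, and
burdened with observer error. `multiatlas` implements atlas-based
annotation, in which a small set of expert-annotated reference volumes
("templates") transfers its landmarks onto the remaining samples
through deformable image registration, and evaluates the transferred
landmarks the way a morphometrician would — against repeated manual
annotation, at the level of mean shape, size, and covariance structure.

## What is in the package

* **Pipelines** — three annotation routes, all built on dense
  displacement-field registration (multi-resolution symmetric demons,
  deterministic, Rcpp kernels):
  * *single atlas*: build an unbiased population average
    (`build_atlas()`), annotate it once (on a probability surface,
    `probability_atlas()` / `probability_surface()`), rasterize the
    landmarks as 2-voxel spheres and back-project them to each sample
    by reversing its transform (`annotate_single_atlas()`);
  * *improved single atlas*: estimate the atlas landmarks instead by
    warping template annotations into atlas space and averaging
    (`annotate_improved_atlas()`);
  * *multi-atlas* (`annotate_maap()`): register every template
    directly to the target, gate templates by post-registration
    correlation, fuse the warped label maps — shape-based averaging
    (`fuse_sba()`), majority vote (`fuse_mv()`) or STAPLE
    (`fuse_staple()`) — and take per-label centroids; template
    selection by k-means on atlas-space intensities
    (`select_templates_kmeans()`), per-landmark outlier QC from the
    spread of per-template estimates (`detect_outliers()`: flag when
    ≥ 2 of k estimates are further than 5 voxels from the fused
    location).
* **Morphometrics** — generalized Procrustes analysis (`gpa()`),
  centroid size, Goodall F / Procrustes ANOVA with permutation and
  bootstrap resampling (`goodall_f_test()`), the EDMA form-matrix test
  (`edma_form_test()`), Box M on principal-component scores
  (`box_m_test()`, `pc_scores()`), paired rank tests on digitization
  errors (`error_rank_test()`) and centroid-size regressions
  (`size_regression()`).
* **Synthetic studies** (`synth_study()`) — populations of
  mandible-like 3D shapes with smooth, folding-free random
  deformations, exact ground-truth landmarks, and simulated repeated
  manual annotation calibrated so the attempt-to-attempt median
  distance is 0.048 mm; every pipeline stage is testable without
  external data.
* **I/O** — NRRD / NIfTI-1 / MetaImage volumes, Slicer `.fcsv` and
  plain CSV landmarks (LPS mm internally, RAS↔LPS handled), dense
  fields as 4D NRRD; a thin CLI (`exec/multiatlas`) with `synth`,
  `register`, `warp`, `fuse` and `annotate` subcommands.

## Core model

Registration estimates, for fixed image F and moving image M, a dense
displacement field u on F's grid (pull-back: x ↦ x + u(x) lands in M's
space) by symmetric-force demons over an image pyramid. The unbiased
atlas A solves the fixed point "the deformations from A to every
sample average to zero", found by iterating register → average →
correct by the mean field. Landmark transfer is label-map warping plus
per-label centroids; fusion of k templates' maps is, by default,
the arg-min over classes of the across-template mean signed Euclidean
distance (shape-based averaging). Evaluation compares annotation
methods against the gold standard GS (average of repeated manual
attempts) via per-landmark error tables and, at study level, Goodall's

F = [d²(mean_A, mean_B) / (1/n_A + 1/n_B)] / [Σ_g Σ_i d²(x_gi, mean_g) / (n_A + n_B − 2)]

on jointly superimposed shapes, the EDMA form-ratio statistic
T = max(ratio)/min(ratio), and Box M on PC scores of separate fits.

## Worked example

```r
library(multiatlas)

spec  <- synth_study_spec(n = 8, grid = c(32, 48, 32))  # desk-scale study
study <- synth_study(spec, seed = 1)                    # volumes + GS

cmp <- compare_annotation_methods(study, k = 3, seed = 1,
                                  atlas_cfg = atlas_config(max_iter = 3))
round(cmp$study_means, 4)
#>   single_atlas improved_atlas           maap
#>         0.0516         0.0474         0.0446

head(attr(cmp$tables$maap, "summary"), 4)
#>   landmark         mean_mm  sd_mm
#> 1 incisor_tip       0.0289 0.0143
#> 2 body_ant_dorsal   0.0527 0.0129
#> 3 body_ant_ventral  0.0342 0.0115
#> 4 body_mid_dorsal   0.0556 0.0163

out <- detect_outliers(cmp$results$maap, threshold_voxels = 5,
                       spacing_mm = 0.03442,
                       gold = study$gs[cmp$target_ids])
attr(out, "summary")
#>      flagged correct_flag       missed    false_hit        total
#>            0            0            0            0           80

gs_pop   <- study$gs[cmp$target_ids]
maap_pop <- lapply(cmp$results$maap, function(r) r$estimate)
gf <- goodall_f_test(gs_pop, maap_pop, n_reps = 999, seed = 1)
#> Goodall F = 2.935, p = 0.014
```

Reading the numbers: study-mean landmark error drops from 0.052 mm
(single atlas) to 0.045 mm (multi-atlas) — the method ordering that
motivates the multi-atlas route — and all multi-atlas landmarks sit
within the 5-voxel QC threshold. With only k = 3 templates the Goodall
test still detects a small systematic mean-shape offset between
multi-atlas and gold-standard landmarks (shared template bias); larger
template libraries shrink it, and template count is the lever to watch
when adopting the method.

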