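#' Template library
#'
#' A set of annotated samples (volume + manual landmarks) used as
#' references for annotation.
#'
#' @param volumes list of template [volume()]s.
#' @param landmarks list of matching [landmark_set()]s (shared order).
#' @param ids integer sample ids of the templates within the study.
#' @param method how the templates were chosen
#'   (`"kmeans"`, `"manual"`, `"random"`).
#' @param seed RNG seed recorded for provenance.
#' @return A list of class `template_library`.
#' @export
template_library <- function(volumes, landmarks, ids,
                             method = c("manual", "kmeans", "random"),
                             seed = NA_integer_) {
  method <- match.arg(method)
  k <- length(volumes)
  if (k < 1) stop("template library needs >= 1 template")
  if (length(landmarks) != k || length(ids) != k)
    stop("volumes, landmarks and ids must have equal length")
  nm <- landmarks[[1]]$name
  for (l in landmarks) if (!identical(l$name, nm))
    stop("template landmark ordering is inconsistent")
  structure(list(volumes = volumes, landmarks = landmarks,
                 ids = as.integer(ids), method = method, seed = seed,
                 k = k),
            class = "template_library")
}

#' Select templates by k-means clustering in atlas space
#'
#' Samples are warped into atlas space with the atlas transforms,
#' flattened to voxel-intensity vectors and clustered with k-means
#' (Euclidean distance). Within each cluster the member closest to the
#' cluster mean becomes a template, so the library spans the population's
#' variation. Deterministic given `seed`.
#'
#' @param atlas an [build_atlas()] result for the study population.
#' @param samples the study's sample volumes (list).
#' @param landmarks per-sample manual [landmark_set()]s (same order).
#' @param k number of templates (<= number of samples).
#' @param seed RNG seed for the k-means initialization.
#' @param max_restarts restarts on an empty-cluster failure.
#' @return A `template_library` with `method = "kmeans"`.
#' @export
select_templates_kmeans <- function(atlas, samples, landmarks, k,
                                    seed = 1, max_restarts = 5) {
  n <- length(samples)
  if (k > n) stop("k must be <= number of samples")
  d <- dim(atlas$mean$data)
  X <- matrix(0, n, prod(d))
  for (i in seq_len(n)) {
    tf <- atlas$transforms[[i]]
    X[i, ] <- cpp_warp_by_field(as.numeric(samples[[i]]$data), d,
                                effective_field_vox(tf, samples[[i]]),
                                0, TRUE)
  }
  if (k == n) {
    ids <- seq_len(n)
  } else if (k == 1) {
    gm <- colMeans(X)
    ids <- which.min(rowSums(sweep(X, 2, gm)^2))
  } else {
    km <- NULL
    for (r in seq_len(max_restarts)) {
      set.seed(seed + r - 1)
      km <- tryCatch(stats::kmeans(X, centers = k, iter.max = 100,
                                   nstart = 3),
                     error = function(e) NULL,
                     warning = function(w) NULL)
      if (!is.null(km) && length(unique(km$cluster)) == k) break
      km <- NULL
    }
    if (is.null(km))
      stop("k-means failed to produce ", k, " nonempty clusters after ",
           max_restarts, " restarts")
    ids <- vapply(seq_len(k), function(c) {
      members <- which(km$cluster == c)
      dists <- rowSums(sweep(X[members, , drop = FALSE], 2,
                             km$centers[c, ])^2)
      members[which.min(dists)]
    }, integer(1))
    ids <- sort(ids)
  }
  template_library(samples[ids], landmarks[ids], ids,
                   method = "kmeans", seed = seed)
}

new_annotation_result <- function(estimate, per_template = NULL,
                                  correlations = NULL, lost = integer(0),
                                  target_id = NA, method = NA_character_,
                                  coords = NULL, names = NULL) {
  structure(list(estimate = estimate, per_template = per_template,
                 correlations = correlations, lost = lost,
                 target_id = target_id, method = method,
                 coords = coords, names = names),
            class = "annotation_result")
}

#' @export
print.annotation_result <- function(x, ...) {
  cat(sprintf("<annotation_result> %s, target %s, %d landmarks%s\n",
              x$method, as.character(x$target_id),
              length(x$names),
              if (length(x$lost)) paste0(", lost: ",
                                         paste(x$lost, collapse = ","))
              else ""))
  invisible(x)
}

#' Single-atlas annotation by back-projection
#'
#' The annotated atlas's landmarks are rasterized as spherical labels on
#' the atlas grid and projected back to each target by reversing the
#' target's sample-to-atlas transform; each transferred landmark is the
#' centroid of its warped label.
#'
#' @param atlas an [build_atlas()] result.
#' @param atlas_landmarks [landmark_set()] placed on the atlas (e.g. on
#'   a probability surface, averaged over repeated manual attempts).
#' @param target_ids indices of the samples to annotate.
#' @param radius sphere radius in voxels (2 by default; the coarser
#'   4-voxel label is also used in practice and available here).
#' @return A list of `annotation_result`, one per target.
#' @export
annotate_single_atlas <- function(atlas, atlas_landmarks, target_ids,
                                  radius = 2) {
  label_map <- rasterize_spheres(atlas_landmarks, atlas$mean, radius)
  L <- nrow(atlas_landmarks)
  lapply(target_ids, function(i) {
    inv <- invert(atlas$transforms[[i]])
    warped <- warp_labels(label_map, inv, n_labels = L)
    cc <- label_centroids(warped, L, names = atlas_landmarks$name)
    new_annotation_result(cc$landmarks, lost = cc$lost, target_id = i,
                          method = "single_atlas", coords = cc$coords,
                          names = atlas_landmarks$name)
  })
}

#' Improved single-atlas annotation
#'
#' Instead of annotating the atlas directly, the manual landmarks of the
#' template samples are warped into atlas space (exact point mapping
#' through the reversed transforms) and averaged with equal weights; the
#' averaged atlas landmarks are then back-projected to the targets
#' exactly as in [annotate_single_atlas()].
#'
#' @param atlas an [build_atlas()] result.
#' @param templates a [template_library()] whose ids index
#'   `atlas$transforms`.
#' @param target_ids indices of the samples to annotate.
#' @param radius sphere radius in voxels.
#' @return A list of `annotation_result`, one per target; the averaged
#'   atlas landmarks are attached as attribute `"atlas_landmarks"`.
#' @export
annotate_improved_atlas <- function(atlas, templates, target_ids,
                                    radius = 2) {
  warped <- lapply(seq_len(templates$k), function(j) {
    inv <- invert(atlas$transforms[[templates$ids[j]]])
    warp_landmarks(templates$landmarks[[j]], inv)
  })
  atlas_lms <- average_landmarks(warped)
  out <- annotate_single_atlas(atlas, atlas_lms, target_ids, radius)
  out <- lapply(out, function(r) { r$method <- "improved_atlas"; r })
  attr(out, "atlas_landmarks") <- atlas_lms
  out
}

#' Multi-atlas annotation of one target
#'
#' Every template is registered directly to the target; its landmark
#' label map is warped onto the target grid and the surviving maps are
#' fused (shape-based averaging by default). The final landmark is the
#' centroid of the fused label. Templates whose post-registration
#' image correlation with the target fails the gating rule are excluded
#' from fusion. The warped exact landmark points of each template are
#' retained as per-template estimates for outlier detection.
#'
#' @param templates a [template_library()].
#' @param target the target [volume()] (not in the library).
#' @param radius sphere radius in voxels.
#' @param fusion `"sba"`, `"mv"` or `"staple"`.
#' @param gating list: either `list(rule = "threshold", value = 0.9)`
#'   (keep templates with correlation >= value) or
#'   `list(rule = "top_m", value = m)` (keep the m best).
#' @param config a [registration_config()].
#' @param target_id optional identifier recorded in the result.
#' @return An `annotation_result` with per-template estimates,
#'   correlations, the applied gating recorded in
#'   `$gating`, and lost-landmark flags.
#' @export
annotate_maap <- function(templates, target, radius = 2,
                          fusion = c("sba", "mv", "staple"),
                          gating = list(rule = "threshold", value = 0.9),
                          config = registration_config(),
                          target_id = NA) {
  fusion <- match.arg(fusion)
  stopifnot_volume(target, "target")
  k <- templates$k
  tfs <- vector("list", k)
  corrs <- numeric(k)
  for (j in seq_len(k)) {
    tfs[[j]] <- register(target, templates$volumes[[j]], config)
    corrs[j] <- tfs[[j]]$similarity
  }
  keep <- switch(gating$rule,
                 threshold = which(corrs >= gating$value),
                 top_m = order(corrs, decreasing = TRUE)[
                   seq_len(min(gating$value, k))],
                 stop("unknown gating rule: ", gating$rule))
  if (length(keep) == 0)
    stop("annotate_maap: all templates gated out (max correlation ",
         signif(max(corrs), 4), " < ", gating$value, ")")
  L <- nrow(templates$landmarks[[1]])
  warped_maps <- lapply(keep, function(j) {
    lm_map <- rasterize_spheres(templates$landmarks[[j]],
                                templates$volumes[[j]], radius)
    warp_labels(lm_map, tfs[[j]], n_labels = L)
  })
  per_template <- lapply(seq_len(k), function(j)
    warp_landmarks(templates$landmarks[[j]], invert(tfs[[j]])))
  fused <- switch(fusion,
                  sba = fuse_sba(warped_maps, n_labels = L),
                  mv = fuse_mv(warped_maps, n_labels = L),
                  staple = fuse_staple(warped_maps,
                                       n_labels = L)$label_map)
  cc <- label_centroids(fused, L, names = templates$landmarks[[1]]$name)
  res <- new_annotation_result(cc$landmarks,
                               per_template = per_template,
                               correlations = corrs, lost = cc$lost,
                               target_id = target_id, method = "maap",
                               coords = cc$coords,
                               names = templates$landmarks[[1]]$name)
  res$gating <- c(gating, list(kept = templates$ids[keep]))
  res$fusion <- fusion
  res
}

#' Distance-threshold outlier detection for multi-atlas results
#'
#' For each landmark of each target, the distances from every
#' per-template estimate to the final fused location are compared to a
#' threshold; the landmark is flagged as potentially problematic when at
#' least `min_violations` distances exceed it. Requires per-template
#' estimates, which only the multi-atlas procedure provides: with a
#' single atlas there is just one estimate per landmark, so this
#' mechanism cannot be applied there.
#'
#' @param results list of `annotation_result`s from [annotate_maap()].
#' @param threshold_voxels distance threshold in voxels (5 by default).
#' @param spacing_mm voxel size used to convert the threshold to mm.
#' @param min_violations how many estimates must exceed the threshold
#'   (2 by default).
#' @param gold optional list of reference [landmark_set()]s (same order
#'   as `results`) for a flagged-vs-true confusion summary: correct
#'   flags, missed outliers and false hits.
#' @return A tibble of class `outlier_report` with per-(target,
#'   landmark) rows; study-level counts in attribute `"summary"`.
#' @export
detect_outliers <- function(results, threshold_voxels = 5,
                            spacing_mm = 0.03442, min_violations = 2,
                            gold = NULL) {
  rows <- list()
  for (r in seq_along(results)) {
    res <- results[[r]]
    if (is.null(res$per_template))
      stop("detect_outliers: no per-template estimates; single-atlas ",
           "results provide one estimate per landmark, so this outlier ",
           "detection cannot be applied to them")
    thr_mm <- threshold_voxels * spacing_mm
    est <- res$coords
    L <- length(res$names)
    dmat <- matrix(vapply(res$per_template, function(p)
      sqrt(rowSums((lm_coords(p) - est)^2)), numeric(L)), nrow = L)
    n_exceed <- rowSums(dmat > thr_mm, na.rm = TRUE)
    flagged <- n_exceed >= min_violations
    err_gold <- if (!is.null(gold))
      sqrt(rowSums((est - lm_coords(gold[[r]]))^2)) else NA_real_
    rows[[r]] <- tibble::tibble(
      target = res$target_id, landmark = res$names,
      n_estimates = length(res$per_template),
      n_exceeding = as.integer(n_exceed),
      threshold_voxels = threshold_voxels, threshold_mm = thr_mm,
      flagged = flagged, error_mm = err_gold)
  }
  out <- do.call(rbind, rows)
  if (!is.null(gold)) {
    true_out <- out$error_mm > out$threshold_mm
    summary <- c(flagged = sum(out$flagged),
                 correct_flag = sum(out$flagged & true_out),
                 missed = sum(!out$flagged & true_out),
                 false_hit = sum(out$flagged & !true_out),
                 total = nrow(out))
  } else {
    summary <- c(flagged = sum(out$flagged), total = nrow(out))
  }
  attr(out, "summary") <- summary
  class(out) <- c("outlier_report", class(out))
  out
}

#' Per-landmark annotation error table
#'
#' Euclidean distances (mm) between estimated and reference landmarks
#' for every sample, with per-landmark mean and s.d. summary rows — the
#' standard digitization-error layout.
#'
#' @param estimates list of [landmark_set()]s (or `annotation_result`s).
#' @param gold_standard list of reference [landmark_set()]s, same order
#'   and landmark ordering.
#' @param sample_ids optional ids for the rows.
#' @return A tibble with columns `sample`, `landmark`, `error_mm`;
#'   per-landmark summary in attribute `"summary"` (tibble of mean/sd).
#' @export
error_table <- function(estimates, gold_standard, sample_ids = NULL) {
  n <- length(estimates)
  if (length(gold_standard) != n)
    stop("estimates and gold_standard must have equal length")
  sample_ids <- sample_ids %||% seq_len(n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    est <- estimates[[i]]
    if (inherits(est, "annotation_result")) {
      # lost landmarks appear as NA rows, never silently dropped
      coords <- est$coords
      nm <- est$names
    } else {
      coords <- lm_coords(est)
      nm <- est$name
    }
    gs <- gold_standard[[i]]
    pos <- match(gs$name, nm)
    if (anyNA(pos))
      stop("landmark ordering mismatch at sample ", sample_ids[i],
           ": estimate lacks ",
           paste(setdiff(gs$name, nm), collapse = ", "))
    err <- sqrt(rowSums((coords[pos, , drop = FALSE] - lm_coords(gs))^2))
    rows[[i]] <- tibble::tibble(sample = sample_ids[i],
                                landmark = gs$name, error_mm = err)
  }
  out <- do.call(rbind, rows)
  agg_m <- stats::aggregate(error_mm ~ landmark, out, mean,
                            na.action = stats::na.omit)
  agg_s <- stats::aggregate(error_mm ~ landmark, out, stats::sd,
                            na.action = stats::na.omit)
  ord <- match(gold_standard[[1]]$name, agg_m$landmark)
  summary <- tibble::tibble(landmark = agg_m$landmark[ord],
                            mean_mm = agg_m$error_mm[ord],
                            sd_mm = agg_s$error_mm[ord])
  attr(out, "summary") <- summary
  out
}

#' Run and compare the three annotation pipelines on a synthetic study
#'
#' End-to-end driver: builds the population atlas, selects templates by
#' k-means, annotates every non-template target with the single-atlas,
#' improved single-atlas and multi-atlas procedures, and tabulates
#' errors against the study's gold standard. For the single-atlas arm
#' the atlas is "manually" annotated in silico: the population-mean
#' landmark positions are projected onto the chosen probability surface
#' (emulating the constructed-surface ambiguity of annotating an
#' averaged image) and perturbed by observer noise over
#' `atlas_attempts` averaged attempts.
#'
#' @param study a [synth_study()].
#' @param k number of templates.
#' @param seed RNG seed for template selection and atlas annotation
#'   noise.
#' @param radius sphere radius in voxels.
#' @param fusion fusion method for the multi-atlas arm.
#' @param surface_p probability level of the annotated atlas surface.
#' @param atlas_attempts number of simulated manual attempts on the
#'   atlas.
#' @param config a [registration_config()].
#' @param atlas_cfg an [atlas_config()].
#' @return A list with the atlas, template library, per-method result
#'   lists, per-method [error_table()]s versus GS, and a `study_means`
#'   named vector of mean errors (mm).
#' @export
compare_annotation_methods <- function(study, k = 10, seed = 1,
                                       radius = 2,
                                       fusion = "sba",
                                       surface_p = 0.9,
                                       atlas_attempts = 3,
                                       config = registration_config(),
                                       atlas_cfg = atlas_config(
                                         registration = config)) {
  n <- study$spec$n
  atlas <- build_atlas(study$samples, init_sample_id = 1, atlas_cfg)
  templates <- select_templates_kmeans(atlas, study$samples, study$gs,
                                       k = k, seed = seed)
  target_ids <- setdiff(seq_len(n), templates$ids)

  # in-silico manual annotation of the atlas on a probability surface
  prob <- probability_atlas(atlas, study$samples, binarize_threshold = 0.5)
  surf <- probability_surface(prob, surface_p)
  atlas_truth <- average_landmarks(lapply(seq_len(n), function(i)
    warp_landmarks(study$truth[[i]], invert(atlas$transforms[[i]]))))
  on_surface <- project_to_boundary(atlas_truth, surf)
  attempts <- simulate_observers(on_surface, study$spec$observer_sd_mm,
                                 n_attempts = atlas_attempts,
                                 seed = seed + 7L)
  atlas_lms <- average_landmarks(attempts)

  single <- annotate_single_atlas(atlas, atlas_lms, target_ids, radius)
  improved <- annotate_improved_atlas(atlas, templates, target_ids,
                                      radius)
  maap <- lapply(target_ids, function(i)
    annotate_maap(templates, study$samples[[i]], radius = radius,
                  fusion = fusion, config = config, target_id = i))

  gs_targets <- study$gs[target_ids]
  tables <- list(
    single_atlas = error_table(single, gs_targets, target_ids),
    improved_atlas = error_table(improved, gs_targets, target_ids),
    maap = error_table(maap, gs_targets, target_ids))
  study_means <- vapply(tables, function(t)
    mean(t$error_mm, na.rm = TRUE), numeric(1))
  list(atlas = atlas, templates = templates, target_ids = target_ids,
       atlas_landmarks = atlas_lms,
       results = list(single_atlas = single, improved_atlas = improved,
                      maap = maap),
       tables = tables, study_means = study_means)
}

# move each landmark to the nearest boundary voxel of a mask (the
# surface an annotator would click on)
project_to_boundary <- function(lms, mask) {
  bd <- which(boundary_mask(mask$data))
  d <- dim(mask$data)
  vox <- cbind((bd - 1) %% d[1],
               ((bd - 1) %/% d[1]) %% d[2],
               (bd - 1) %/% (d[1] * d[2]))
  world <- voxel_to_world(vox, mask)
  p <- lm_coords(lms)
  out <- p
  for (i in seq_len(nrow(p))) {
    j <- which.min(colSums((t(world) - p[i, ])^2))
    out[i, ] <- world[j, ]
  }
  lm_replace_coords(lms, out)
}
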