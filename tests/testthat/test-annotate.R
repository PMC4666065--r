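identity_atlas <- function(vols) {
  structure(list(mean = vols[[1]],
                 transforms = lapply(vols, function(v)
                   multiatlas:::zero_transform(v)),
                 init_id = 1, log = 0, converged = TRUE,
                 n = length(vols)),
            class = "atlas")
}

test_that("k-means template selection covers the degenerate cases", {
  study <- small_study(n = 5)
  atlas <- identity_atlas(study$samples)
  all_t <- select_templates_kmeans(atlas, study$samples, study$gs,
                                   k = 5, seed = 1)
  expect_equal(all_t$ids, 1:5)
  one <- select_templates_kmeans(atlas, study$samples, study$gs,
                                 k = 1, seed = 1)
  expect_length(one$ids, 1)
  # k = 1 picks the sample closest to the grand mean
  X <- t(vapply(study$samples, function(v) as.numeric(v$data),
                numeric(length(study$samples[[1]]$data))))
  gm <- colMeans(X)
  expect_equal(one$ids, which.min(rowSums(sweep(X, 2, gm)^2)))
  expect_error(select_templates_kmeans(atlas, study$samples, study$gs,
                                       k = 9, seed = 1), "<=")
})

test_that("k-means separates two well-separated morphs", {
  # bimodal population: base shape vs strongly dilated variant
  spec <- synth_study_spec(n = 6, grid = c(24, 36, 24),
                           deform_sd_voxels = 0.5)
  base <- make_base_shape(spec)
  pop <- sample_population(base, spec, seed = 3)
  morph_b <- lapply(4:6, function(i) {
    v <- pop[[i]]$volume
    volume(v$data[c(1, 1:23), , ] * 0.4, v$spacing, v$origin)
  })
  vols <- c(lapply(pop[1:3], `[[`, "volume"), morph_b)
  gs <- lapply(pop, `[[`, "truth")
  atlas <- identity_atlas(vols)
  hits <- vapply(1:10, function(s) {
    tl <- select_templates_kmeans(atlas, vols, gs, k = 2, seed = s)
    (any(tl$ids <= 3) && any(tl$ids >= 4))
  }, logical(1))
  expect_true(all(hits))
  # brute-force check of the medoid rule for one seed
  X <- t(vapply(vols, function(v) as.numeric(v$data),
                numeric(length(vols[[1]]$data))))
  tl <- select_templates_kmeans(atlas, vols, gs, k = 2, seed = 4)
  for (id in tl$ids) {
    grp <- if (id <= 3) 1:3 else 4:6
    ctr <- colMeans(X[grp, , drop = FALSE])
    d_all <- rowSums(sweep(X[grp, , drop = FALSE], 2, ctr)^2)
    expect_equal(id, grp[which.min(d_all)])
  }
})

test_that("single-atlas annotation is exact for identity transforms", {
  study <- small_study(n = 5)
  atlas <- identity_atlas(study$samples)
  res <- annotate_single_atlas(atlas, study$base$landmarks, 2)
  # identity transform: only rasterization error remains
  expect_lt(max(lm_err_vox(res[[1]]$estimate, study$base$landmarks)), 0.5)
})

test_that("zero-deformation studies are annotated almost perfectly", {
  study <- small_study(n = 4, grid = c(32, 48, 32), seed = 5,
                       deform_sd_voxels = 0, intensity_noise_sd = 0)
  atlas <- build_atlas(study$samples, 1,
                       atlas_config(max_iter = 2,
                                    registration = fast_reg()))
  res <- annotate_single_atlas(atlas, study$base$landmarks, 1:4)
  for (r in res)
    expect_lt(max(lm_err_vox(r$estimate, study$truth[[r$target_id]])), 1)
  # MAAP consensus: all templates identical to target
  tl <- template_library(study$samples[1:3], study$truth[1:3], 1:3)
  m <- annotate_maap(tl, study$samples[[4]], config = fast_reg(),
                     target_id = 4)
  expect_lt(max(lm_err_vox(m$estimate, study$truth[[4]])), 1)
  # per-template estimates coincide under zero deformation
  spread <- sapply(seq_len(16), function(l) {
    pts <- t(sapply(m$per_template, function(p)
      unlist(p[l, c("x", "y", "z")])))
    max(dist(pts)) / test_spacing
  })
  expect_lt(max(spread), 0.5)
})

test_that("MAAP with a duplicate of the target is near-exact", {
  study <- small_study(n = 4)
  i <- 2
  tl <- template_library(list(study$samples[[i]]), list(study$truth[[i]]),
                         i)
  res <- annotate_maap(tl, study$samples[[i]], config = fast_reg(),
                       target_id = i)
  expect_lt(max(lm_err_vox(res$estimate, study$truth[[i]])), 0.5)
})

test_that("improved-atlas averaging reduces to its degenerate forms", {
  study <- small_study(n = 5)
  atlas <- identity_atlas(study$samples)
  # identical templates: the average equals any one of them
  tl <- template_library(study$samples[c(1, 1)],
                         study$gs[c(1, 1)], c(1, 2))
  res <- annotate_improved_atlas(atlas, tl, 3)
  expect_landmarks_equal(attr(res, "atlas_landmarks"), study$gs[[1]],
                         tol = 1e-9)
  # one template with identity transforms reduces to single-atlas
  tl1 <- template_library(study$samples[1], study$gs[1], 1)
  ri <- annotate_improved_atlas(atlas, tl1, 4)
  rs <- annotate_single_atlas(atlas, study$gs[[1]], 4)
  expect_landmarks_equal(ri[[1]]$estimate, rs[[1]]$estimate, tol = 1e-9)
})

test_that("the outlier rule flags exactly >= min_violations exceedances", {
  mk_result <- function(dists_vox) {
    # one landmark, k estimates at given distances from the final point
    k <- length(dists_vox)
    final <- c(1, 1, 1)
    per <- lapply(seq_len(k), function(j) {
      off <- c(dists_vox[j] * test_spacing, 0, 0)
      landmark_set("a", matrix(final + off, 1))
    })
    multiatlas:::new_annotation_result(
      landmark_set("a", matrix(final, 1)), per_template = per,
      target_id = 1, method = "maap", coords = matrix(final, 1),
      names = "a")
  }
  rep0 <- detect_outliers(list(mk_result(rep(1, 10))), 5)
  expect_false(rep0$flagged)
  rep1 <- detect_outliers(list(mk_result(c(6, rep(1, 9)))), 5)
  expect_false(rep1$flagged)  # exactly 1 beyond: not flagged
  rep2 <- detect_outliers(list(mk_result(c(6, 7, rep(1, 8)))), 5)
  expect_true(rep2$flagged)   # exactly 2 beyond: flagged
  single <- multiatlas:::new_annotation_result(
    landmark_set("a", matrix(0, 1, 3)), per_template = NULL,
    method = "single_atlas", coords = matrix(0, 1, 3), names = "a")
  expect_error(detect_outliers(list(single), 5), "single-atlas")
})

test_that("the outlier rule equals a brute-force recount on random cases", {
  set.seed(99)
  for (rep in 1:25) {
    k <- sample(3:12, 1)
    L <- sample(2:6, 1)
    final <- matrix(stats::rnorm(L * 3), L)
    nm <- paste0("L", seq_len(L))
    per <- lapply(seq_len(k), function(j)
      landmark_set(nm, final + matrix(stats::rnorm(L * 3, 0, 0.1), L)))
    res <- multiatlas:::new_annotation_result(
      landmark_set(nm, final), per_template = per, target_id = rep,
      method = "maap", coords = final, names = nm)
    thr <- stats::runif(1, 1, 4)
    min_v <- sample(1:3, 1)
    rep_out <- detect_outliers(list(res), thr, spacing_mm = test_spacing,
                               min_violations = min_v)
    brute <- vapply(seq_len(L), function(l) {
      d <- vapply(per, function(p)
        sqrt(sum((unlist(p[l, c("x", "y", "z")]) - final[l, ])^2)),
        numeric(1))
      sum(d > thr * test_spacing) >= min_v
    }, logical(1))
    expect_identical(rep_out$flagged, brute)
  }
})

test_that("outlier confusion counts against a reference are computed", {
  final <- matrix(c(0, 0, 0), 1)
  per <- lapply(1:5, function(j)
    landmark_set("a", matrix(c(0.5, 0, 0), 1)))
  res <- multiatlas:::new_annotation_result(
    landmark_set("a", final), per_template = per, target_id = 1,
    method = "maap", coords = final, names = "a")
  gold <- list(landmark_set("a", matrix(c(1, 0, 0), 1)))
  rep <- detect_outliers(list(res), 5, spacing_mm = test_spacing,
                         gold = gold)
  s <- attr(rep, "summary")
  # flagged (all 5 estimates 0.5 mm off) and truly wrong (1 mm > 0.172)
  expect_equal(unname(s["flagged"]), 1)
  expect_equal(unname(s["correct_flag"]), 1)
  expect_equal(unname(s["missed"]), 0)
})

test_that("error tables match hand arithmetic and half-normal theory", {
  gs <- list(landmark_set(c("a", "b"), rbind(c(0, 0, 0), c(1, 1, 1))))
  est_same <- gs
  t0 <- error_table(est_same, gs)
  expect_true(all(t0$error_mm == 0))
  est <- list(landmark_set(c("a", "b"),
                           rbind(c(0.03, 0.04, 0), c(1, 1, 1))))
  t1 <- error_table(est, gs)
  expect_equal(t1$error_mm, c(0.05, 0))
  expect_error(error_table(list(landmark_set("x", matrix(0, 1, 3))), gs),
               "mismatch")
  # mean 3D Gaussian distance: sigma * 2 * sqrt(2/pi); attempts vs truth
  spec <- synth_study_spec(n = 36, grid = c(24, 36, 24),
                           observer_sd_mm = rep(0.03, 16))
  base <- make_base_shape(spec)
  atts <- lapply(1:36, function(i)
    simulate_observers(base$landmarks, spec$observer_sd_mm, 1,
                       seed = 400 + i)[[1]])
  tab <- error_table(atts, rep(list(base$landmarks), 36))
  expect_equal(mean(tab$error_mm), 0.03 * 2 * sqrt(2 / pi),
               tolerance = 0.1)
})
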