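test_that("base shape provides 16 on-support landmarks", {
  spec <- synth_study_spec(n = 2, grid = c(32, 48, 32))
  base <- make_base_shape(spec)
  expect_equal(nrow(base$landmarks), 16)
  # every landmark lies on or inside the blurred support
  vx <- round(world_to_voxel(
    as.matrix(base$landmarks[, c("x", "y", "z")]), base$volume)) + 1
  vals <- base$volume$data[vx]
  expect_true(all(vals > 0.01))
  expect_error(make_base_shape(spec, lobes = list()), "at least one lobe")
  bad <- matrix(c(-3, 0, 0, 5, 5, 5, 6, 6, 6), 3, byrow = TRUE,
                dimnames = list(c("oops", "p2", "p3"), NULL))
  expect_error(make_base_shape(spec, landmarks = bad), "outside")
})

test_that("single-lobe sphere puts pole landmarks on the surface", {
  spec <- synth_study_spec(n = 2, grid = c(24, 24, 24), blur_sigma = 0,
                           n_landmarks = 6,
                           observer_sd_mm = rep(0.01, 6))
  ctr <- c(11.5, 11.5, 11.5); r <- 8
  poles <- rbind(ctr + c(r, 0, 0), ctr - c(r, 0, 0),
                 ctr + c(0, r, 0), ctr - c(0, r, 0),
                 ctr + c(0, 0, r), ctr - c(0, 0, r))
  rownames(poles) <- paste0("pole", 1:6)
  base <- make_base_shape(spec,
                          lobes = list(list(center = ctr,
                                            radii = rep(r, 3))),
                          landmarks = poles)
  expect_equal(nrow(base$landmarks), 6)
  vx <- world_to_voxel(as.matrix(base$landmarks[, c("x", "y", "z")]),
                       base$volume)
  d2 <- sqrt(rowSums(sweep(vx, 2, ctr)^2))
  expect_lt(max(abs(d2 - r)), 1e-9)
})

test_that("zero deformation and noise reproduce the base exactly", {
  spec <- synth_study_spec(n = 2, grid = c(24, 36, 24),
                           deform_sd_voxels = 0, intensity_noise_sd = 0)
  base <- make_base_shape(spec)
  pop <- sample_population(base, spec, seed = 5)
  expect_identical(pop[[1]]$volume$data, base$volume$data)
  expect_landmarks_equal(pop[[1]]$truth, base$landmarks, tol = 1e-9)
})

test_that("population generation is reproducible from the seed", {
  spec <- synth_study_spec(n = 3, grid = c(24, 36, 24))
  base <- make_base_shape(spec)
  a <- sample_population(base, spec, seed = 9)
  b <- sample_population(base, spec, seed = 9)
  expect_identical(a[[2]]$volume$data, b[[2]]$volume$data)
  expect_identical(lm_err_vox(a[[3]]$truth, b[[3]]$truth), rep(0, 16))
  c <- sample_population(base, spec, seed = 10)
  expect_false(identical(a[[1]]$volume$data, c[[1]]$volume$data))
})

test_that("generating deformation maps base landmarks onto stored truth", {
  spec <- synth_study_spec(n = 2, grid = c(24, 36, 24))
  base <- make_base_shape(spec)
  pop <- sample_population(base, spec, seed = 13, keep_fields = TRUE)
  for (s in pop) {
    # p + u(p) must return the base landmark (the defining equation)
    p_vox <- world_to_voxel(as.matrix(s$truth[, c("x", "y", "z")]),
                            base$volume)
    u <- multiatlas:::cpp_field_at_points(
      multiatlas:::field_vox(s$field), dim(base$volume$data), p_vox)
    back <- voxel_to_world(p_vox + u, base$volume)
    expect_lt(max(abs(back -
                        as.matrix(base$landmarks[, c("x", "y", "z")]))),
              1e-6)
    # fields are folding-free
    jd <- multiatlas:::cpp_jacobian_det(multiatlas:::field_vox(s$field),
                                        dim(base$volume$data))
    expect_gt(min(jd), 0)
  }
})

test_that("deformed populations stay in the subtle-variation regime", {
  spec <- synth_study_spec(n = 6, grid = c(64, 96, 64))
  base <- make_base_shape(spec)
  pop <- sample_population(base, spec, seed = 21)
  b <- lapply(pop, function(p) binarize(p$volume, 0.5))
  dc <- utils::combn(6, 2, function(ij) dice(b[[ij[1]]], b[[ij[2]]]))
  expect_gt(mean(dc), 0.9)
})

test_that("observer simulation matches its noise model", {
  spec <- synth_study_spec(n = 2, grid = c(24, 36, 24))
  base <- make_base_shape(spec)
  # zero noise reproduces truth
  att0 <- simulate_observers(base$landmarks, rep(0, 16), 2, seed = 1)
  expect_landmarks_equal(att0[[1]], base$landmarks, tol = 1e-12)
  # averaging two attempts shrinks the error by sqrt(2) per axis
  sdv <- rep(0.05, 16)
  set.seed(31)
  errs_gs <- replicate(200, {
    att <- simulate_observers(base$landmarks, sdv, 2,
                              seed = sample.int(1e6, 1))
    gs <- average_landmarks(att)
    as.matrix(gs[, c("x", "y", "z")]) -
      as.matrix(base$landmarks[, c("x", "y", "z")])
  })
  expect_equal(stats::sd(errs_gs), 0.05 / sqrt(2), tolerance = 0.05)
})

test_that("default observer noise recovers the 0.048 mm median", {
  # 36 samples x 16 landmarks, two attempts each, as in a full study
  spec <- synth_study_spec(n = 36, grid = c(24, 36, 24))
  base <- make_base_shape(spec)
  set.seed(77)
  d_all <- unlist(lapply(1:36, function(i) {
    att <- simulate_observers(base$landmarks, spec$observer_sd_mm, 2,
                              seed = 1000 + i)
    sqrt(rowSums((as.matrix(att[[1]][, c("x", "y", "z")]) -
                    as.matrix(att[[2]][, c("x", "y", "z")]))^2))
  }))
  expect_equal(stats::median(d_all), 0.048, tolerance = 0.15)
})

test_that("a study directory contains volumes, landmarks and manifest", {
  spec <- synth_study_spec(n = 2, grid = c(16, 24, 16))
  study <- synth_study(spec, seed = 3)
  dir <- withr::local_tempdir()
  write_study(study, dir)
  expect_true(file.exists(file.path(dir, "sample_01.nrrd")))
  expect_true(file.exists(file.path(dir, "sample_02_gs.fcsv")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$seed, 3)
  expect_equal(man$n, 2)
  gs <- read_landmarks(file.path(dir, "sample_01_gs.fcsv"))
  expect_landmarks_equal(gs, study$gs[[1]], tol = 1e-6)
})
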