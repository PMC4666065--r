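test_that("volume construction enforces its invariants", {
  expect_error(volume(matrix(1, 2, 2)), "3D")
  expect_error(volume(array(1, c(2, 2, 2)), spacing = c(1, 0, 1)),
               "positive")
  expect_error(volume(array(2, c(2, 2, 2)), kind = "binary"), "\\{0, 1\\}")
  expect_error(volume(array(1.5, c(2, 2, 2)), kind = "probability"),
               "\\[0, 1\\]")
  v <- volume(array(0.5, c(2, 3, 4)), kind = "probability")
  expect_identical(dim(v), c(2L, 3L, 4L))
})

test_that("volume files round-trip data, spacing and origin", {
  set.seed(1)
  v <- volume(array(rnorm(5 * 5 * 5), c(5, 5, 5)),
              spacing = rep(test_spacing, 3), origin = c(1, 2, 3))
  bin <- volume(array(sample(0:1, 125, TRUE), c(5, 5, 5)),
                spacing = rep(test_spacing, 3), kind = "binary")
  for (ext in c(".nrrd", ".mha", ".nii.gz")) {
    p <- withr::local_tempfile(fileext = ext)
    write_volume(v, p)
    v2 <- read_volume(p)
    expect_lt(max(abs(v2$data - v$data)), 1e-12)
    expect_lt(max(abs(v2$spacing - v$spacing)), 1e-7)
    expect_lt(max(abs(v2$origin - v$origin)), 1e-7)
    # integer payloads survive exactly
    p2 <- withr::local_tempfile(fileext = ext)
    write_volume(bin, p2)
    expect_equal(read_volume(p2)$data, bin$data, ignore_attr = TRUE)
  }
  # integer dtypes on disk
  p <- withr::local_tempfile(fileext = ".nrrd")
  write_volume(bin, p, dtype = "uint8")
  expect_identical(read_volume(p)$data,
                   array(as.integer(bin$data), dim(bin$data)))
  # ascii encoding
  p <- withr::local_tempfile(fileext = ".nrrd")
  multiatlas:::write_nrrd(v, p, encoding = "ascii")
  expect_lt(max(abs(read_volume(p)$data - v$data)), 1e-12)
})

test_that("non-3D volume files are rejected with a clear error", {
  p <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(matrix(1:4, 2)), p)
  expect_error(read_volume(p), "not a 3D volume")
  expect_error(read_volume(withr::local_tempfile(fileext = ".xyz")),
               "not found|cannot guess")
})

test_that("landmark files round-trip and fcsv applies the RAS/LPS flip", {
  lms <- landmark_set(paste0("LM", 1:16), matrix(rnorm(48), 16))
  for (ext in c(".csv", ".fcsv")) {
    p <- withr::local_tempfile(fileext = ext)
    write_landmarks(lms, p)
    expect_landmarks_equal(read_landmarks(p), lms, tol = 1e-6)
  }
  # a RAS point (-1, -2, 3) on disk is LPS (1, 2, 3) internally
  p <- withr::local_tempfile(fileext = ".fcsv")
  writeLines(c("# Markups fiducial file version = 4.11",
               "# CoordinateSystem = RAS",
               "id1,-1,-2,3,0,0,0,1,1,1,0,apex,,"), p)
  got <- read_landmarks(p)
  expect_equal(unname(unlist(got[1, c("x", "y", "z")])), c(1, 2, 3))
  expect_equal(got$name, "apex")
})

test_that("malformed landmark files raise errors", {
  expect_error(landmark_set(c("a", "a"), matrix(0, 2, 3)), "duplicate")
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,x,y,z", "a,1,2", "b,1,2,3"), p)
  expect_error(read_landmarks(p), "4 columns")
  writeLines(c("a,1,2,oops"), p)
  expect_error(read_landmarks(p), "non-numeric")
})

test_that("voxel/world conversions are exact inverses", {
  v <- volume(array(0, c(10, 10, 10)), spacing = rep(test_spacing, 3))
  expect_equal(voxel_to_world(c(0, 0, 0), v), c(0, 0, 0))
  # 5 voxels at 34.42 um is 0.172 mm
  expect_equal(round(voxel_to_world(c(5, 0, 0), v)[1], 3), 0.172)
  expect_equal(world_to_voxel(c(test_spacing, 0, 0), v), c(1, 0, 0))
  set.seed(2)
  pts <- matrix(runif(30, -5, 15), 10)
  v2 <- volume(array(0, c(10, 10, 10)), spacing = c(0.5, 1, 2),
               origin = c(-3, 2, 7))
  expect_lt(max(abs(world_to_voxel(voxel_to_world(pts, v2), v2) - pts)),
            1e-9)
})

test_that("sphere rasterization obeys radius, bounds and tie rules", {
  ref <- volume(array(0, c(21, 21, 21)), spacing = rep(1, 3))
  ctr <- landmark_set("c", matrix(c(10, 10, 10), 1))
  expect_equal(sum(rasterize_spheres(ctr, ref, 0)$data == 1), 1)
  lab2 <- rasterize_spheres(ctr, ref, 2)
  expect_equal(sum(lab2$data == 1), 33)  # lattice points with r^2 <= 4
  expect_error(rasterize_spheres(
    landmark_set("o", matrix(c(-5, 0, 0), 1)), ref, 2), "outside grid")
  expect_warning(rasterize_spheres(
    landmark_set(c("a", "b"), rbind(c(10, 10, 10), c(10.4, 10, 10))),
    ref, 2), "closer than 1 voxel")
  # overlap: voxel goes to the nearest landmark, exact tie to lower index
  two <- suppressWarnings(rasterize_spheres(
    landmark_set(c("a", "b"), rbind(c(9, 10, 10), c(12, 10, 10))),
    ref, 2))
  expect_equal(two$data[9 + 1, 11, 11], 1)
  expect_equal(two$data[12 + 1, 11, 11], 2)
  # midpoint voxel between centers 3 apart belongs to neither sphere
  # fully; tie case via centers 4 apart
  tie <- suppressWarnings(rasterize_spheres(
    landmark_set(c("a", "b"), rbind(c(8, 10, 10), c(12, 10, 10))),
    ref, 2))
  expect_equal(tie$data[10 + 1, 11, 11], 1)
})

test_that("label centroids invert rasterization to within half a voxel", {
  ref <- volume(array(0, c(24, 24, 24)), spacing = rep(test_spacing, 3),
                origin = c(4, 5, 6))
  # symmetric sphere at a grid point recovers the center exactly
  p <- voxel_to_world(c(12, 12, 12), ref)
  lab <- rasterize_spheres(landmark_set("c", matrix(p, 1)), ref, 3)
  expect_lt(max(abs(label_centroid(lab, 1) - p)), 1e-9)
  # property: random in-bounds landmarks (non-overlapping spheres),
  # radii 1..4
  set.seed(42)
  for (r in 1:4) {
    for (rep in 1:5) {
      vox <- matrix(runif(3, 9, 14), 1)
      lms <- landmark_set("L1", voxel_to_world(vox, ref))
      lab <- rasterize_spheres(lms, ref, r)
      err_vox <- sqrt(sum((label_centroid(lab, 1) -
                             voxel_to_world(vox[1, ], ref))^2)) /
        test_spacing
      expect_lt(err_vox, 0.5)
    }
  }
  # two voxels at (0,0,0) and (2,0,0) with 1 mm spacing -> (1,0,0)
  lm <- volume(array(0L, c(5, 5, 5)), spacing = rep(1, 3))
  lm$data[c(1, 3), 1, 1] <- 1L
  expect_equal(label_centroid(lm, 1), c(1, 0, 0))
  expect_error(label_centroid(lm, 2), "lost in fusion")
})

test_that("displacement transforms round-trip through NRRD vector files", {
  set.seed(3)
  tf <- multiatlas:::new_transform(matrix(rnorm(60), 20, 3),
                                   c(5, 2, 2), rep(test_spacing, 3),
                                   c(1, 2, 3))
  p <- withr::local_tempfile(fileext = ".nrrd")
  write_transform(tf, p)
  tf2 <- read_transform(p)
  expect_equal(tf2$field, tf$field)
  expect_equal(tf2$dim, tf$dim)
  expect_equal(tf2$spacing, tf$spacing)
  expect_equal(tf2$origin, tf$origin)
})
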