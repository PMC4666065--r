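test_that("an atlas of identical volumes is that volume", {
  v <- blob_volume(c(24, 30, 24), spacing = rep(test_spacing, 3))
  atlas <- build_atlas(list(v, v, v), 1,
                       atlas_config(max_iter = 3,
                                    registration = fast_reg()))
  expect_lt(max(abs(atlas$mean$data - v$data)), 0.02)
  for (tf in atlas$transforms)
    expect_lt(mean(sqrt(rowSums(multiatlas:::field_vox(tf)^2))), 0.1)
  expect_true(atlas$converged)
})

test_that("the atlas of two translated copies sits midway", {
  spec <- synth_study_spec(n = 2, grid = c(32, 48, 32))
  base <- make_base_shape(spec)
  arr <- base$volume$data
  sh <- function(k) {
    out <- array(0, dim(arr))
    if (k > 0) out[(1 + k):dim(arr)[1], , ] <- arr[1:(dim(arr)[1] - k), , ]
    else out[1:(dim(arr)[1] + k), , ] <- arr[(1 - k):dim(arr)[1], , ]
    volume(out, base$volume$spacing, base$volume$origin)
  }
  a <- sh(2); b <- sh(-2)
  atlas <- build_atlas(list(a, b), 1,
                       atlas_config(max_iter = 4,
                                    registration = fast_reg()))
  com_of <- function(v) {
    g <- multiatlas:::base_grid(dim(v$data))
    w <- pmax(as.numeric(v$data) - 0.1, 0)
    colSums(g * w) / sum(w)
  }
  expect_lt(max(abs(com_of(atlas$mean) - com_of(base$volume))), 0.5)
})

test_that("probability atlas values are exact sample-frequency multiples", {
  v <- blob_volume(c(20, 24, 20), spacing = rep(test_spacing, 3))
  atlas <- build_atlas(list(v, v), 1,
                       atlas_config(max_iter = 2,
                                    registration = fast_reg()))
  prob <- probability_atlas(atlas, list(v, v), binarize_threshold = 0.5)
  expect_true(all(abs(prob$data * 2 - round(prob$data * 2)) < 1e-12))
  expect_error(probability_atlas(atlas, list(v, v),
                                 binarize_threshold = 99), "range")
  # hand-built case: 1 of 2 foreground -> 0.5, all background -> 0
  m1 <- volume(array(0, c(4, 4, 4))); m1$data[2, 2, 2] <- 1
  id <- multiatlas:::zero_transform(m1)
  fake <- structure(list(mean = m1, transforms = list(id, id), n = 2),
                    class = "atlas")
  m2 <- volume(array(0, c(4, 4, 4))); m2$data[2, 2, 2] <- 1
  m2$data[3, 3, 3] <- 1
  pr <- probability_atlas(fake, list(m1, m2), binarize_threshold = 0.5)
  expect_equal(pr$data[2, 2, 2], 1)
  expect_equal(pr$data[3, 3, 3], 0.5)
  expect_equal(pr$data[1, 1, 1], 0)
})

test_that("probability surfaces nest and reject empty masks", {
  set.seed(8)
  pr <- volume(array(runif(27), c(3, 3, 3)), kind = "probability")
  m5 <- probability_surface(pr, 0.5)
  m7 <- probability_surface(pr, 0.7)
  m9 <- probability_surface(pr, 0.9)
  expect_true(all(m9$data <= m7$data))
  expect_true(all(m7$data <= m5$data))
  one <- volume(array(0.2, c(3, 3, 3)), kind = "probability")
  expect_error(probability_surface(one, 0.9), "no voxels")
  expect_error(probability_surface(pr, 0), "in \\(0, 1\\]")
  ident <- volume(array(1, c(3, 3, 3)), kind = "probability")
  expect_equal(sum(probability_surface(ident, 1)$data), 27)
})

test_that("dice matches its definition and degenerate contracts", {
  a <- volume(array(0, c(4, 4, 4)), kind = "binary")
  a$data[1:2, 1, 1] <- 1
  b <- volume(array(0, c(4, 4, 4)), kind = "binary")
  b$data[2:3, 1, 1] <- 1
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, b), 2 * 1 / (2 + 2))
  disj <- volume(array(0, c(4, 4, 4)), kind = "binary")
  disj$data[4, 4, 4] <- 1
  expect_equal(dice(a, disj), 0)
  empty <- volume(array(0, c(4, 4, 4)), kind = "binary")
  expect_error(dice(empty, empty), "both masks empty")
  # |A|=|B|=4, overlap 2 -> 0.5
  a4 <- volume(array(0, c(4, 4, 4)), kind = "binary")
  a4$data[1:4, 1, 1] <- 1
  b4 <- volume(array(0, c(4, 4, 4)), kind = "binary")
  b4$data[3:4, 1, 1] <- 1; b4$data[1:2, 2, 1] <- 1
  expect_equal(dice(a4, b4), 0.5)
})

test_that("intensity correlation matches closed forms", {
  v <- blob_volume(c(12, 12, 12))
  expect_equal(intensity_correlation(v, v), 1)
  neg <- volume(-v$data + 3, v$spacing, v$origin)
  expect_equal(intensity_correlation(v, neg), -1)
  set.seed(4)
  shuf <- volume(array(sample(v$data), dim(v$data)), v$spacing, v$origin)
  expect_lt(abs(intensity_correlation(v, shuf)), 0.1)
  flat <- volume(array(1, c(12, 12, 12)))
  expect_error(intensity_correlation(v, flat), "zero variance")
})

test_that("surface RMS distance matches brute-force box geometry", {
  mk <- function(lo, hi, d = c(28, 28, 28)) {
    m <- array(0, d)
    m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1
    volume(m, rep(1, 3), c(0, 0, 0), kind = "binary")
  }
  cube <- mk(c(5, 5, 5), c(24, 24, 24))
  expect_equal(as.numeric(surface_rms_distance(cube, cube)), 0)
  # dilation by 1: faces dominate at distance 1
  dil <- mk(c(4, 4, 4), c(25, 25, 25))
  rms <- as.numeric(surface_rms_distance(cube, dil))
  expect_equal(rms, 1, tolerance = 0.2)
  # translation of a 20^3 box by t: faces normal to t at distance t
  tr <- mk(c(8, 5, 5), c(27, 24, 24))
  dirs <- attr(surface_rms_distance(cube, tr), "directions")
  brute <- function(a, b) {
    ba <- which(multiatlas:::boundary_mask(a$data), arr.ind = TRUE)
    bb <- which(multiatlas:::boundary_mask(b$data), arr.ind = TRUE)
    d2 <- vapply(seq_len(nrow(ba)), function(i)
      min(colSums((t(bb) - ba[i, ])^2)), numeric(1))
    sqrt(mean(d2))
  }
  expect_equal(unname(dirs["a_to_b"]), brute(cube, tr), tolerance = 1e-9)
  expect_equal(unname(dirs["b_to_a"]), brute(tr, cube), tolerance = 1e-9)
})

test_that("atlases from different initial samples agree", {
  study <- small_study(n = 5)
  cfg <- atlas_config(max_iter = 3, registration = fast_reg())
  a1 <- build_atlas(study$samples, 1, cfg)
  a2 <- build_atlas(study$samples, 3, cfg)
  cmp <- compare_atlases(list(a1, a2), study$samples,
                         binarize_threshold = 0.5, p = 0.5)
  expect_gt(cmp$table$dice[1], 0.98)
  expect_gt(cmp$table$correlation[1], 0.98)
})
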