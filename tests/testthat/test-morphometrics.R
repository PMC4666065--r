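rand_config <- function(L = 6, sd = 0.1, base = NULL) {
  if (is.null(base)) base <- matrix(stats::rnorm(L * 3), L)
  base + matrix(stats::rnorm(L * 3, 0, sd), L)
}

rigid_copy <- function(X, scale = 1, angle = 0.7, t = c(3, -2, 5)) {
  R <- rbind(c(cos(angle), -sin(angle), 0),
             c(sin(angle), cos(angle), 0),
             c(0, 0, 1))
  sweep(scale * X %*% R, 2, t, `+`)
}

test_that("GPA removes similarity transforms exactly", {
  set.seed(10)
  X <- rand_config(8)
  pop0 <- array(0, c(2, 8, 3))
  pop0[1, , ] <- X
  pop0[2, , ] <- rigid_copy(X, scale = 2.5)
  fit <- gpa(pop0)
  expect_lt(max(fit$distances), 1e-9)
  # invariance: transforming one input does not change the fit
  Y <- rand_config(8)
  pop1 <- array(0, c(3, 8, 3)); pop2 <- array(0, c(3, 8, 3))
  Z <- rand_config(8)
  pop1[1, , ] <- X; pop1[2, , ] <- Y; pop1[3, , ] <- Z
  pop2[1, , ] <- rigid_copy(X, 0.3); pop2[2, , ] <- Y; pop2[3, , ] <- Z
  f1 <- gpa(pop1); f2 <- gpa(pop2)
  expect_lt(max(abs(f1$distances - f2$distances)), 1e-9)
})

test_that("two-triangle alignment matches independent oracles", {
  A <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  B <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  pop <- array(0, c(2, 3, 3)); pop[1, , ] <- A; pop[2, , ] <- B
  fit <- gpa(pop, tol = 1e-14, max_iter = 500)
  d_pkg <- sqrt(sum((fit$aligned[1, , ] - fit$aligned[2, , ])^2))
  # oracle 1: brute-force minimization over the planar rotation angle
  pre <- function(X) {
    Xc <- sweep(X, 2, colMeans(X)); Xc / sqrt(sum(Xc^2))
  }
  a <- pre(A); b <- pre(B)
  thetas <- seq(0, 2 * pi, length.out = 2e5)
  dd <- vapply(thetas, function(th) {
    R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0),
               c(0, 0, 1))
    sum((a %*% R - b)^2)
  }, numeric(1))
  expect_equal(d_pkg, sqrt(min(dd)), tolerance = 1e-4)
  # oracle 2: vegan's two-configuration Procrustes (rotation only);
  # only comparable when vegan picks a proper rotation, since it also
  # searches reflections
  skip_if_not_installed("vegan")
  pv <- vegan::procrustes(b, a, scale = FALSE)
  if (det(pv$rotation) > 0)
    expect_equal(d_pkg, sqrt(pv$ss), tolerance = 1e-6)
})

test_that("centroid size follows its closed forms", {
  expect_equal(centroid_size(matrix(c(1, 1, 0, 1, -1, 0, -1, 1, 0,
                                      -1, -1, 0), 4, byrow = TRUE)),
               sqrt(8))
  expect_equal(centroid_size(matrix(5, 4, 3)), 0)
  set.seed(11)
  X <- rand_config(7)
  expect_equal(centroid_size(3.7 * X), 3.7 * centroid_size(X))
})

test_that("Goodall F is null-calibrated and detects planted offsets", {
  set.seed(12)
  base <- rand_config(5, sd = 0)
  mk <- function(n, shift = 0) {
    arr <- array(0, c(n, 5, 3))
    for (i in seq_len(n))
      arr[i, , ] <- base + matrix(stats::rnorm(15, 0, 0.05), 5) +
        shift * matrix(c(1, rep(0, 14)), 5)
    arr
  }
  a <- mk(10)
  same <- goodall_f_test(a, a, n_reps = 99, seed = 1)
  expect_lt(same$F, 1e-10)
  expect_gt(same$p, 0.95)
  shifted <- goodall_f_test(mk(10), mk(10, shift = 0.6), n_reps = 199,
                            seed = 1)
  expect_lt(shifted$p, 0.01)
  # both resampling modes are seed-reproducible and use add-one p-values
  ga <- mk(8); gb <- mk(8)
  for (mode in c("one_sample_permutation", "two_sample_bootstrap")) {
    r1 <- goodall_f_test(ga, gb, mode = mode, n_reps = 49, seed = 5)
    r2 <- goodall_f_test(ga, gb, mode = mode, n_reps = 49, seed = 5)
    expect_equal(r1$p, r2$p)
    expect_gte(r1$p, 1 / 50)
  }
})

test_that("EDMA form ratios behave under identity, scaling and shifts", {
  set.seed(13)
  arr <- array(0, c(8, 5, 3))
  base <- rand_config(5, sd = 0)
  for (i in 1:8) arr[i, , ] <- base + matrix(rnorm(15, 0, 0.03), 5)
  self <- edma_form_test(arr, arr, n_reps = 49, seed = 1)
  expect_true(all(abs(self$ratio[upper.tri(self$ratio)] - 1) < 1e-12))
  expect_equal(self$T, 1)
  # uniform scaling: all ratios 0.5, T = 1 (pure size difference)
  sc <- edma_form_test(arr, arr * 2, n_reps = 49, seed = 1)
  expect_true(all(abs(sc$ratio[upper.tri(sc$ratio)] - 0.5) < 1e-12))
  expect_equal(sc$T, 1)
  # localized difference concentrates CI exclusions on one landmark
  arr2 <- arr
  arr2[, 2, 1] <- arr2[, 2, 1] + 0.8
  loc <- edma_form_test(arr, arr2, n_reps = 199, seed = 1)
  excl <- loc$ci[loc$ci$excludes_1, ]
  expect_gt(nrow(excl), 0)
  expect_true(all(excl$landmark_1 == "LM2" | excl$landmark_2 == "LM2"))
  expect_lt(loc$p, 0.05)
  # zero interlandmark distances are rejected
  bad <- arr; bad[1, 2, ] <- bad[1, 1, ]
  expect_error(edma_form_test(bad, arr, n_reps = 9), "coincident")
})

test_that("Box M matches its closed forms and the df formula", {
  expect_equal(box_m_df(15, 2), 120)
  # brute-force df: free parameters of (k-1) covariance matrices
  for (p in 2:6) for (k in 2:4)
    expect_equal(box_m_df(p, k), (k - 1) * length(which(upper.tri(
      diag(p), diag = TRUE))))
  set.seed(14)
  A <- matrix(stats::rnorm(40 * 4), 40)
  same <- box_m_test(A, A)
  expect_equal(same$M, 0, tolerance = 1e-10)
  expect_error(box_m_test(A[1:3, ], A), "n > p")
})

test_that("PC scores respect the retention threshold and dimensions", {
  set.seed(15)
  base <- rand_config(6, sd = 0)
  arr <- array(0, c(20, 6, 3))
  for (i in 1:20) arr[i, , ] <- base + matrix(stats::rnorm(18, 0, 0.01), 6)
  fit <- gpa(arr)
  # similarity alignment leaves at most min(n-1, 3L-7) substantive
  # dimensions; the removed similarity directions reappear only as
  # second-order leakage far below this share threshold
  all_pcs <- pc_scores(fit, min_variance_fraction = 1e-4)
  expect_lte(ncol(all_pcs$scores), min(20 - 1, 3 * 6 - 7))
  expect_gte(pc_scores(fit, min_variance_fraction = 0)$retained,
             ncol(all_pcs$scores))
  dup <- pc_scores(list(fit, fit), min_variance_fraction = 0.01)
  expect_equal(abs(dup[[1]]$scores), abs(dup[[2]]$scores))
  expect_error(pc_scores(fit, min_variance_fraction = 0.99),
               "fewer than 2")
})

test_that("rank decisions match the tail convention and enumeration", {
  a <- c(1, 2, 3, 4, 5, 6)
  expect_equal(error_rank_test(a, a)$decision, "indistinguishable")
  expect_equal(error_rank_test(a + 100, a, alpha = 0.01)$decision,
               "greater")
  expect_equal(error_rank_test(a, a + 100, alpha = 0.01)$decision,
               "less")
  # U statistic equals exhaustive enumeration on a 5-vs-5 toy
  x <- c(1.1, 3.4, 2.2, 8.0, 4.4); y <- c(0.4, 5.5, 6.1, 7.2, 9.3)
  U <- error_rank_test(x, y)$U
  U_brute <- sum(outer(x, y, `>`))
  expect_equal(unname(U), U_brute)
  # exact p from enumeration of all C(10,5) labelings
  pooled <- c(x, y)
  combs <- utils::combn(10, 5)
  U_all <- apply(combs, 2, function(idx)
    sum(outer(pooled[idx], pooled[-idx], `>`)))
  p_exact <- mean(U_all >= U_brute)
  expect_equal(error_rank_test(x, y)$p_greater, p_exact,
               tolerance = 1e-10)
  expect_equal(error_rank_test(rep(1, 5), rep(1, 5))$decision,
               "indistinguishable")
})

test_that("size regressions separate bias from noise", {
  set.seed(16)
  cs <- stats::runif(36, 9, 11)
  idr <- size_regression(cs, cs)
  expect_equal(idr$slope, 1)
  expect_equal(idr$adj_r_squared, 1)
  expect_equal(idr$p_paired_t, 1)
  # tiny constant bias: near-perfect R^2 yet significant paired t
  bias <- 0.002 * mean(cs)
  br <- size_regression(cs + bias + stats::rnorm(36, 0, 1e-4), cs)
  expect_gt(br$adj_r_squared, 0.99)
  expect_lt(br$p_paired_t, 0.001)
  expect_equal(br$mean_difference, bias, tolerance = 0.1)
  # uncorrelated sizes: adjusted R^2 near zero
  ur <- size_regression(stats::runif(36, 9, 11), cs)
  expect_lt(abs(ur$adj_r_squared), 0.15)
})
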