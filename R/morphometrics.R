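#' Assemble a shape population array
#'
#' @param x a list of [landmark_set()]s with identical landmark order,
#'   or an n x L x 3 numeric array.
#' @return An n x L x 3 array with landmark names in `dimnames[[2]]`.
#' @export
as_shape_population <- function(x) {
  if (is.array(x) && length(dim(x)) == 3) return(x)
  if (!is.list(x) || length(x) < 1)
    stop("expected a list of landmark sets or an n x L x 3 array")
  nm <- x[[1]]$name
  for (s in x) if (!identical(s$name, nm))
    stop("landmark ordering differs between configurations")
  arr <- array(NA_real_, c(length(x), length(nm), 3),
               dimnames = list(NULL, nm, c("x", "y", "z")))
  for (i in seq_along(x)) arr[i, , ] <- lm_coords(x[[i]])
  if (anyNA(arr)) stop("missing landmarks are not allowed in shape tests")
  arr
}

#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared distances of the landmarks to
#' their centroid; the standard size measure of geometric
#' morphometrics. Scaling a configuration by c multiplies centroid size
#' by c.
#'
#' @param configuration an L x 3 matrix or a [landmark_set()].
#' @return Centroid size (mm).
#' @export
centroid_size <- function(configuration) {
  X <- if (inherits(configuration, "landmark_set"))
    lm_coords(configuration) else as.matrix(configuration)
  if (nrow(X) < 2) stop("centroid size needs >= 2 landmarks")
  Xc <- sweep(X, 2, colMeans(X))
  sqrt(sum(Xc^2))
}

kabsch <- function(X, Y, allow_reflection = FALSE) {
  # rotation R minimizing ||X R - Y||_F
  s <- svd(crossprod(X, Y))
  R <- s$u %*% t(s$v)
  if (!allow_reflection && det(R) < 0) {
    u <- s$u; u[, 3] <- -u[, 3]
    R <- u %*% t(s$v)
  }
  R
}

#' Generalized Procrustes analysis
#'
#' Superimposes landmark configurations on their centroids, scales each
#' to unit centroid size, and iteratively rotates all configurations to
#' their evolving mean by least squares (orthogonal Procrustes via SVD,
#' reflections excluded by default) until the mean stabilizes. Residual
#' differences after superimposition are shape.
#'
#' @param population list of [landmark_set()]s or n x L x 3 array.
#' @param allow_reflection permit improper rotations (default FALSE,
#'   appropriate for biological landmark data).
#' @param tol convergence tolerance on the change of the mean shape.
#' @param max_iter maximum alignment sweeps.
#' @return An object of class `procrustes_fit`: `aligned` (n x L x 3,
#'   unit centroid size, centered), `mean_shape` (L x 3), per-sample
#'   `centroid_sizes` (mm), `distances` to the mean, and the iteration
#'   log.
#' @export
gpa <- function(population, allow_reflection = FALSE, tol = 1e-10,
                max_iter = 100) {
  arr <- as_shape_population(population)
  n <- dim(arr)[1]; L <- dim(arr)[2]
  if (n < 2) stop("GPA needs >= 2 configurations")
  if (L < 3) stop("GPA needs >= 3 landmarks")
  cs <- numeric(n)
  aligned <- arr
  for (i in seq_len(n)) {
    X <- arr[i, , ]
    Xc <- sweep(X, 2, colMeans(X))
    cs[i] <- sqrt(sum(Xc^2))
    if (cs[i] < 1e-12 || qr(Xc)$rank < 2)
      stop("degenerate configuration at sample ", i)
    aligned[i, , ] <- Xc / cs[i]
  }
  mean_shape <- aligned[1, , ]
  log_delta <- numeric(0)
  for (iter in seq_len(max_iter)) {
    for (i in seq_len(n))
      aligned[i, , ] <- aligned[i, , ] %*%
        kabsch(aligned[i, , ], mean_shape, allow_reflection)
    new_mean <- apply(aligned, c(2, 3), mean)
    new_mean <- sweep(new_mean, 2, colMeans(new_mean))
    new_mean <- new_mean / sqrt(sum(new_mean^2))
    delta <- sqrt(sum((new_mean - mean_shape)^2))
    log_delta <- c(log_delta, delta)
    mean_shape <- new_mean
    if (delta < tol) break
  }
  distances <- vapply(seq_len(n), function(i)
    sqrt(sum((aligned[i, , ] - mean_shape)^2)), numeric(1))
  structure(list(aligned = aligned, mean_shape = mean_shape,
                 centroid_sizes = cs, distances = distances,
                 iterations = length(log_delta), log = log_delta,
                 converged = log_delta[length(log_delta)] < tol),
            class = "procrustes_fit")
}

#' @export
print.procrustes_fit <- function(x, ...) {
  cat(sprintf(paste0("<procrustes_fit> %d configurations, %d landmarks,",
                     " %d iterations, rms Procrustes distance %.4g\n"),
              dim(x$aligned)[1], dim(x$aligned)[2], x$iterations,
              sqrt(mean(x$distances^2))))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.procrustes_fit <- function(x, ...) {
  tibble::tibble(sample = seq_along(x$centroid_sizes),
                 centroid_size = x$centroid_sizes,
                 procrustes_distance = x$distances)
}

#' @export
glance.procrustes_fit <- function(x, ...) {
  tibble::tibble(n = dim(x$aligned)[1], n_landmarks = dim(x$aligned)[2],
                 iterations = x$iterations, converged = x$converged,
                 rms_distance = sqrt(mean(x$distances^2)))
}

#' Goodall F test for mean-shape difference
#'
#' Procrustes ANOVA: the F ratio of the squared Procrustes distance
#' between group mean shapes to the pooled within-group squared
#' distances, after joint superimposition of both groups. Significance
#' by label permutation (one-sample mode, assuming exchangeability) or
#' by within-group bootstrap resampling under the null of a common mean
#' (two-sample mode), with the add-one p-value convention
#' (r + 1) / (B + 1).
#'
#' @param group_a,group_b shape populations (lists of [landmark_set()]s
#'   or n x L x 3 arrays) with the same landmarks.
#' @param mode `"one_sample_permutation"` or `"two_sample_bootstrap"`.
#' @param n_reps resampling replicates (the reference analyses use
#'   50,000; reduce for quick runs).
#' @param seed RNG seed.
#' @return A list: `F`, `p`, `mode`, `n_reps`, group sizes.
#' @export
goodall_f_test <- function(group_a, group_b,
                           mode = c("one_sample_permutation",
                                    "two_sample_bootstrap"),
                           n_reps = 1000, seed = 1) {
  mode <- match.arg(mode)
  if (n_reps < 1) stop("n_reps must be >= 1")
  a <- as_shape_population(group_a); b <- as_shape_population(group_b)
  if (!identical(dim(a)[2:3], dim(b)[2:3]))
    stop("groups must share the landmark set")
  na <- dim(a)[1]; nb <- dim(b)[1]
  if (na + nb < 3) stop("too few configurations for residual df")
  joint <- array(0, c(na + nb, dim(a)[2], 3))
  joint[seq_len(na), , ] <- a
  joint[na + seq_len(nb), , ] <- b
  fit <- gpa(joint)
  X <- matrix(fit$aligned, na + nb)  # n x 3L
  grp <- rep(c(TRUE, FALSE), c(na, nb))
  f_obs <- goodall_f_stat(X, grp)
  set.seed(seed)
  if (mode == "one_sample_permutation") {
    stats_null <- replicate(n_reps,
                            goodall_f_stat(X, sample(grp)))
  } else {
    # center both groups on the grand mean so H0 holds, then resample
    # within groups with replacement
    Xa <- X[grp, , drop = FALSE]; Xb <- X[!grp, , drop = FALSE]
    gm <- colMeans(X)
    Xa0 <- sweep(Xa, 2, colMeans(Xa) - gm)
    Xb0 <- sweep(Xb, 2, colMeans(Xb) - gm)
    stats_null <- replicate(n_reps, {
      Xs <- rbind(Xa0[sample.int(na, na, replace = TRUE), , drop = FALSE],
                  Xb0[sample.int(nb, nb, replace = TRUE), , drop = FALSE])
      goodall_f_stat(Xs, grp)
    })
  }
  p <- (sum(stats_null >= f_obs) + 1) / (n_reps + 1)
  list(F = f_obs, p = p, mode = mode, n_reps = n_reps, n_a = na,
       n_b = nb)
}

goodall_f_stat <- function(X, grp) {
  na <- sum(grp); nb <- sum(!grp)
  ma <- colMeans(X[grp, , drop = FALSE])
  mb <- colMeans(X[!grp, , drop = FALSE])
  between <- sum((ma - mb)^2) / (1 / na + 1 / nb)
  within <- (sum(sweep(X[grp, , drop = FALSE], 2, ma)^2) +
               sum(sweep(X[!grp, , drop = FALSE], 2, mb)^2)) /
    (na + nb - 2)
  between / within
}

#' EDMA form-matrix test
#'
#' Computes the mean interlandmark distance matrix (form matrix) of each
#' group, their elementwise ratio, and the T statistic (max ratio over
#' min ratio, a coordinate-system-free measure of localized form
#' difference). Significance of T by permuting group labels; bootstrap
#' percentile confidence intervals for each pairwise-distance ratio.
#'
#' @param group_a,group_b shape populations with the same landmarks.
#' @param n_reps permutation replicates for the T null distribution
#'   (the reference analysis uses 100,000) and bootstrap replicates for
#'   the CIs.
#' @param seed RNG seed.
#' @param ci_level confidence level for the per-ratio intervals.
#' @return An object of class `form_matrix_result`: `form_a`, `form_b`
#'   (L x L), `ratio`, `T`, `p`, and `ci` (tibble of per-pair ratio
#'   intervals).
#' @export
edma_form_test <- function(group_a, group_b, n_reps = 1000, seed = 1,
                           ci_level = 0.95) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  a <- as_shape_population(group_a); b <- as_shape_population(group_b)
  if (!identical(dim(a)[2:3], dim(b)[2:3]))
    stop("groups must share the landmark set")
  L <- dim(a)[2]
  dist_rows <- function(arr) {
    t(vapply(seq_len(dim(arr)[1]), function(i) {
      dm <- as.matrix(stats::dist(arr[i, , ]))
      if (any(dm[upper.tri(dm)] < 1e-12))
        stop("coincident landmarks (zero interlandmark distance) in a ",
             "configuration")
      dm[upper.tri(dm)]
    }, numeric(L * (L - 1) / 2)))
  }
  Da <- dist_rows(a); Db <- dist_rows(b)
  t_stat <- function(fa, fb) {
    r <- fa / fb
    max(r) / min(r)
  }
  fa <- colMeans(Da); fb <- colMeans(Db)
  T_obs <- t_stat(fa, fb)
  na <- nrow(Da); nb <- nrow(Db)
  pooled <- rbind(Da, Db)
  grp <- rep(c(TRUE, FALSE), c(na, nb))
  set.seed(seed)
  T_null <- replicate(n_reps, {
    g <- sample(grp)
    t_stat(colMeans(pooled[g, , drop = FALSE]),
           colMeans(pooled[!g, , drop = FALSE]))
  })
  p <- (sum(T_null >= T_obs) + 1) / (n_reps + 1)
  ratios_boot <- replicate(n_reps, {
    colMeans(Da[sample.int(na, na, replace = TRUE), , drop = FALSE]) /
      colMeans(Db[sample.int(nb, nb, replace = TRUE), , drop = FALSE])
  })
  alpha <- (1 - ci_level) / 2
  ci_lo <- apply(ratios_boot, 1, stats::quantile, probs = alpha)
  ci_hi <- apply(ratios_boot, 1, stats::quantile, probs = 1 - alpha)
  pairs <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  nm <- dimnames(a)[[2]] %||% paste0("LM", seq_len(L))
  mat <- function(v) {
    m <- matrix(NA_real_, L, L, dimnames = list(nm, nm))
    m[upper.tri(m)] <- v
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  }
  structure(list(form_a = mat(fa), form_b = mat(fb),
                 ratio = mat(fa / fb), T = T_obs, p = p,
                 n_reps = n_reps,
                 ci = tibble::tibble(landmark_1 = nm[pairs[, 1]],
                                     landmark_2 = nm[pairs[, 2]],
                                     ratio = fa / fb,
                                     lower = ci_lo, upper = ci_hi,
                                     excludes_1 = ci_lo > 1 | ci_hi < 1)),
            class = "form_matrix_result")
}

#' @export
print.form_matrix_result <- function(x, ...) {
  cat(sprintf("<form_matrix_result> T = %.4g, p = %.4g (%d replicates)\n",
              x$T, x$p, x$n_reps))
  invisible(x)
}

#' Box M test for homogeneity of covariance matrices
#'
#' Likelihood-ratio-style comparison of within-group covariance
#' matrices (typically of principal-component scores), with Box's
#' chi-square approximation. Requires more observations than variables
#' in each group. Degrees of freedom are (k - 1) p (p + 1) / 2.
#'
#' @param group_a_scores,group_b_scores n_i x p score matrices.
#' @return A list: `M`, `chi2`, `df`, `p`.
#' @export
box_m_test <- function(group_a_scores, group_b_scores) {
  groups <- list(as.matrix(group_a_scores), as.matrix(group_b_scores))
  p <- ncol(groups[[1]])
  if (ncol(groups[[2]]) != p) stop("groups must have equal variable count")
  ns <- vapply(groups, nrow, integer(1))
  if (any(ns <= p))
    stop("each group needs n > p observations (got n = ",
         paste(ns, collapse = ", "), ", p = ", p, ")")
  k <- length(groups)
  N <- sum(ns)
  covs <- lapply(groups, stats::cov)
  pooled <- Reduce(`+`, Map(function(S, n) (n - 1) * S, covs, ns)) /
    (N - k)
  ldet <- function(S) {
    d <- determinant(S, logarithm = TRUE)
    if (d$sign <= 0) stop("singular within-group covariance matrix")
    as.numeric(d$modulus)
  }
  M <- (N - k) * ldet(pooled) -
    sum(mapply(function(S, n) (n - 1) * ldet(S), covs, ns))
  c1 <- (sum(1 / (ns - 1)) - 1 / (N - k)) *
    (2 * p^2 + 3 * p - 1) / (6 * (p + 1) * (k - 1))
  chi2 <- M * (1 - c1)
  df <- (k - 1) * p * (p + 1) / 2
  list(M = M, chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Box M chi-square degrees of freedom
#'
#' @param p number of variables.
#' @param k number of groups.
#' @return `(k - 1) p (p + 1) / 2`.
#' @export
box_m_df <- function(p, k = 2) (k - 1) * p * (p + 1) / 2

#' Principal-component scores of aligned shapes
#'
#' PCA of the superimposed coordinates of each group's own Procrustes
#' fit (separate fits keep the groups' covariance patterns from
#' influencing each other). Components explaining at least
#' `min_variance_fraction` of the variation are retained.
#'
#' @param fits a single `procrustes_fit` or a list of them (one per
#'   group).
#' @param min_variance_fraction retention threshold on the per-component
#'   variance share (default 0.01, i.e. 1 percent).
#' @return For each fit: `scores` (n x m), `variance` tibble (share and
#'   cumulative share), `retained`. A single fit returns that list; a
#'   list of fits returns a list of lists.
#' @export
pc_scores <- function(fits, min_variance_fraction = 0.01) {
  one <- function(fit) {
    X <- matrix(fit$aligned, dim(fit$aligned)[1])
    pc <- stats::prcomp(X, center = TRUE)
    shares <- pc$sdev^2 / sum(pc$sdev^2)
    keep <- which(shares >= min_variance_fraction & pc$sdev > 1e-12)
    if (length(keep) < 2)
      stop("fewer than 2 principal components retained at threshold ",
           min_variance_fraction)
    list(scores = pc$x[, keep, drop = FALSE],
         variance = tibble::tibble(component = seq_along(shares),
                                   share = shares,
                                   cumulative = cumsum(shares),
                                   retained = seq_along(shares) %in% keep),
         retained = length(keep))
  }
  if (inherits(fits, "procrustes_fit")) one(fits) else lapply(fits, one)
}

#' Rank test on paired digitization errors
#'
#' Mann-Whitney U on two paired error samples (per-sample pairing is by
#' position), with a three-way decision at level `alpha`: `"greater"`
#' when the first sample's errors are stochastically larger, `"less"`
#' when smaller, `"indistinguishable"` when the U statistic is not in
#' either tail. A Wilcoxon signed-rank variant on the paired
#' differences is available since the two tests are often conflated for
#' paired error data; the output records which ran.
#'
#' @param errors_a,errors_b equal-length paired error vectors (n >= 5).
#' @param alpha decision level (default 0.01).
#' @param method `"mann_whitney"` (default) or `"wilcoxon_paired"`.
#' @return A list: `U`, `p_greater`, `p_less`, `decision`, `method`.
#' @export
error_rank_test <- function(errors_a, errors_b, alpha = 0.01,
                            method = c("mann_whitney",
                                       "wilcoxon_paired")) {
  method <- match.arg(method)
  if (length(errors_a) != length(errors_b))
    stop("paired error vectors must have equal length")
  if (length(errors_a) < 5) stop("need n >= 5 pairs")
  if (stats::sd(c(errors_a - errors_b)) == 0 &&
      all(errors_a == errors_b)) {
    return(list(U = NA_real_, p_greater = 1, p_less = 1,
                decision = "indistinguishable", method = method))
  }
  paired <- method == "wilcoxon_paired"
  wg <- suppressWarnings(stats::wilcox.test(errors_a, errors_b,
                                            alternative = "greater",
                                            paired = paired))
  wl <- suppressWarnings(stats::wilcox.test(errors_a, errors_b,
                                            alternative = "less",
                                            paired = paired))
  decision <- if (wg$p.value < alpha) "greater"
  else if (wl$p.value < alpha) "less" else "indistinguishable"
  list(U = unname(wg$statistic), p_greater = wg$p.value,
       p_less = wl$p.value, decision = decision, method = method)
}

#' Centroid-size agreement: regression and paired t test
#'
#' Ordinary least-squares regression of automated centroid sizes on the
#' gold-standard sizes (adjusted R-squared reported) together with a
#' paired t test on the differences — high R-squared with a significant
#' paired t indicates a small systematic size bias.
#'
#' @param cs_auto,cs_gs paired centroid-size vectors (mm), n >= 3.
#' @return A list: `slope`, `intercept`, `adj_r_squared`, `t`,
#'   `p_paired_t`, `mean_difference`.
#' @export
size_regression <- function(cs_auto, cs_gs) {
  if (length(cs_auto) != length(cs_gs))
    stop("paired size vectors must have equal length")
  if (length(cs_auto) < 3) stop("need n >= 3 pairs")
  if (stats::sd(cs_gs) == 0) stop("zero variance in gold-standard sizes")
  fit <- stats::lm(cs_auto ~ cs_gs)
  # a perfect fit (identical inputs) is a legitimate degenerate case
  sm <- suppressWarnings(summary(fit))
  if (stats::sd(cs_auto - cs_gs) == 0) {
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- stats::t.test(cs_auto, cs_gs, paired = TRUE)
  }
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       adj_r_squared = sm$adj.r.squared,
       t = unname(tt$statistic), p_paired_t = tt$p.value,
       mean_difference = mean(cs_auto - cs_gs))
}
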