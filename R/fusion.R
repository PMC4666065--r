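check_fusion_inputs <- function(inputs) {
  if (length(inputs) < 1) stop("need >= 1 input label map")
  ref <- inputs[[1]]
  for (m in inputs) {
    stopifnot_volume(m, "every input")
    if (!identical(dim(m$data), dim(ref$data)))
      stop("fusion: grid mismatch between input label maps")
  }
  invisible(ref)
}

#' Shape-based averaging label fusion
#'
#' For every label (including the background class by default) the
#' signed Euclidean distance map (negative inside the label, positive
#' outside, in mm) is computed for each input and averaged across
#' inputs; each voxel takes the label with minimal mean signed distance.
#' Ties go to background, then to the lowest label index. This yields
#' smooth consensus labels even when the inputs overlap imperfectly.
#'
#' @param inputs list of label-map [volume()]s on a common grid.
#' @param n_labels number of landmark labels L (defaults to the maximum
#'   across inputs).
#' @param include_background if `TRUE` (default) the background competes
#'   as a class of its own; if `FALSE` a voxel becomes background only
#'   when every label's mean signed distance is positive.
#' @return A fused label-map [volume()]. Labels that win no voxel are
#'   recorded in attribute `"lost"`.
#' @export
fuse_sba <- function(inputs, n_labels = NULL, include_background = TRUE) {
  ref <- check_fusion_inputs(inputs)
  n_labels <- n_labels %||% max(vapply(inputs, function(m) max(m$data),
                                       numeric(1)))
  d <- dim(ref$data)
  sp <- ref$spacing
  labels <- if (include_background) 0:n_labels else 1:n_labels
  mean_sd <- matrix(0, prod(d), length(labels))
  for (j in seq_along(labels)) {
    l <- labels[j]
    acc <- numeric(prod(d))
    for (m in inputs) acc <- acc + signed_distance(m$data == l, d, sp)
    mean_sd[, j] <- acc / length(inputs)
  }
  # minimal mean signed distance wins; the column order (background
  # first, then labels ascending) makes ties resolve to background and
  # then to the lowest label index
  best <- labels[max.col(-mean_sd, ties.method = "first")]
  if (!include_background) {
    mn <- mean_sd[, 1]
    for (j in seq_len(ncol(mean_sd))[-1]) mn <- pmin(mn, mean_sd[, j])
    best[mn > 0] <- 0L
  }
  out <- volume(array(as.integer(best), d), sp, ref$origin, kind = "label")
  attr(out, "landmark_names") <- attr(inputs[[1]], "landmark_names")
  attr(out, "lost") <- setdiff(seq_len(n_labels), unique(best))
  out
}

signed_distance <- function(mask, d, sp) {
  mask <- as.numeric(mask)
  if (sum(mask) == 0) {
    # absent label: far outside everywhere
    return(rep(sqrt(sum((d * sp)^2)), length(mask)))
  }
  d_out <- sqrt(cpp_edt_sq(mask, d, sp))
  d_in <- sqrt(cpp_edt_sq(1 - mask, d, sp))
  as.numeric(d_out - d_in)
}

#' Majority-vote label fusion
#'
#' Each voxel takes the modal label across inputs; ties go to background
#' and then to the lowest label index. A landmark label that wins no
#' voxel anywhere (insufficient overlap of the warped label maps) is
#' reported as lost in attribute `"lost"` rather than raising an error,
#' so callers can flag the landmark.
#'
#' @inheritParams fuse_sba
#' @return A fused label-map [volume()] with attribute `"lost"`.
#' @export
fuse_mv <- function(inputs, n_labels = NULL) {
  ref <- check_fusion_inputs(inputs)
  n_labels <- n_labels %||% max(vapply(inputs, function(m) max(m$data),
                                       numeric(1)))
  d <- dim(ref$data)
  counts <- matrix(0L, prod(d), n_labels + 1)
  for (m in inputs) {
    v <- as.integer(m$data)
    for (l in 0:n_labels)
      counts[, l + 1] <- counts[, l + 1] + (v == l)
  }
  # mode; ties -> background then lowest index. max.col("first") scans
  # columns in order background, 1, 2, ... so ties already resolve that
  # way.
  best <- max.col(counts, ties.method = "first") - 1L
  out <- volume(array(as.integer(best), d), ref$spacing, ref$origin,
                kind = "label")
  attr(out, "landmark_names") <- attr(inputs[[1]], "landmark_names")
  attr(out, "lost") <- setdiff(seq_len(n_labels), unique(best))
  out
}

#' STAPLE label fusion
#'
#' Simultaneous truth and performance level estimation: an EM algorithm
#' that alternates between estimating the voxelwise posterior
#' probability of the true (hidden) segmentation and the per-rater
#' sensitivity p and specificity q. Each landmark label is fused as an
#' independent binary problem within a dilated bounding box of the
#' label's union across raters, with the global foreground fraction of
#' that box as prior.
#'
#' @inheritParams fuse_sba
#' @param init initial sensitivity/specificity for every rater.
#' @param tol EM convergence tolerance on the maximum posterior change.
#' @param max_iter maximum EM iterations per label.
#' @param margin_voxels bounding-box dilation margin.
#' @return A list: `label_map` (fused [volume()], attribute `"lost"`),
#'   `estimates` (tibble of per-label per-rater p and q) and `traces`
#'   (per-label log-likelihood traces, non-decreasing).
#' @export
fuse_staple <- function(inputs, n_labels = NULL, init = 0.99, tol = 1e-6,
                        max_iter = 100, margin_voxels = 3) {
  ref <- check_fusion_inputs(inputs)
  if (length(inputs) < 2) stop("STAPLE needs >= 2 raters")
  n_labels <- n_labels %||% max(vapply(inputs, function(m) max(m$data),
                                       numeric(1)))
  d <- dim(ref$data)
  post_all <- matrix(0, prod(d), n_labels)
  est <- list(); traces <- list()
  lost <- integer(0)
  for (l in seq_len(n_labels)) {
    union_idx <- which(Reduce(`|`, lapply(inputs, function(m)
      m$data == l)))
    if (length(union_idx) == 0) { lost <- c(lost, l); next }
    box <- bounding_box(union_idx, d, margin_voxels)
    sel <- box_indices(box, d)
    D <- vapply(inputs, function(m)
      as.numeric(m$data[sel] == l), numeric(length(sel)))
    res <- staple_em(D, init = init, tol = tol, max_iter = max_iter)
    post_all[sel, l] <- res$posterior
    est[[l]] <- tibble::tibble(label = l, rater = seq_along(inputs),
                               sensitivity = res$p, specificity = res$q)
    traces[[l]] <- res$loglik
  }
  # assemble: label with highest posterior >= 0.5 wins
  best_post <- apply(post_all, 1, max)
  best_lab <- max.col(post_all, ties.method = "first")
  lab <- ifelse(best_post >= 0.5, best_lab, 0L)
  out <- volume(array(as.integer(lab), d), ref$spacing, ref$origin,
                kind = "label")
  attr(out, "landmark_names") <- attr(inputs[[1]], "landmark_names")
  lost <- sort(union(lost, setdiff(seq_len(n_labels), unique(lab))))
  attr(out, "lost") <- lost
  list(label_map = out,
       estimates = if (length(est)) do.call(rbind, est) else NULL,
       traces = traces)
}

staple_em <- function(D, init = 0.99, tol = 1e-6, max_iter = 100) {
  n_vox <- nrow(D); n_rat <- ncol(D)
  if (all(D == 1) || all(D == 0))
    stop("STAPLE: degenerate all-foreground or all-background region")
  clamp <- function(x) pmin(pmax(x, 1e-6), 1 - 1e-6)
  prior <- clamp(mean(D))
  p <- rep(init, n_rat); q <- rep(init, n_rat)
  W <- rep(prior, n_vox)
  loglik <- numeric(0)
  for (it in seq_len(max_iter)) {
    # E step
    la <- log(prior) + D %*% log(p) + (1 - D) %*% log(1 - p)
    lb <- log(1 - prior) + D %*% log(1 - q) + (1 - D) %*% log(q)
    mx <- pmax(la, lb)
    W_new <- as.numeric(exp(la - mx) / (exp(la - mx) + exp(lb - mx)))
    ll <- sum(mx + log(exp(la - mx) + exp(lb - mx)))
    loglik <- c(loglik, ll)
    delta <- max(abs(W_new - W))
    W <- W_new
    # M step
    sw <- sum(W); swc <- n_vox - sw
    p <- clamp(as.numeric(crossprod(D, W)) / max(sw, 1e-12))
    q <- clamp(as.numeric(crossprod(1 - D, 1 - W)) / max(swc, 1e-12))
    if (delta < tol && it > 1) break
  }
  list(posterior = W, p = p, q = q, loglik = loglik)
}

bounding_box <- function(idx, d, margin) {
  vox <- cbind((idx - 1) %% d[1],
               ((idx - 1) %/% d[1]) %% d[2],
               (idx - 1) %/% (d[1] * d[2]))
  lo <- pmax(apply(vox, 2, min) - margin, 0)
  hi <- pmin(apply(vox, 2, max) + margin, d - 1)
  list(lo = lo, hi = hi)
}

box_indices <- function(box, d) {
  gx <- box$lo[1]:box$hi[1]; gy <- box$lo[2]:box$hi[2]
  gz <- box$lo[3]:box$hi[3]
  as.vector(outer(outer(gx + 1, d[1] * gy, `+`),
                  d[1] * d[2] * gz, `+`))
}

#' Compare fusion algorithms against ground truth
#'
#' Runs SBA, majority vote and STAPLE on the same warped label maps and
#' reports the per-landmark centroid error of each against the true
#' landmark locations (available in synthetic studies).
#'
#' @param inputs list of warped label-map [volume()]s.
#' @param truth_landmarks [landmark_set()] of true locations.
#' @return A tibble with columns `landmark`, `method`, `error_mm`,
#'   `lost`.
#' @export
compare_fusions <- function(inputs, truth_landmarks) {
  L <- nrow(truth_landmarks)
  fused <- list(sba = fuse_sba(inputs, n_labels = L),
                mv = fuse_mv(inputs, n_labels = L),
                staple = if (length(inputs) >= 2)
                  fuse_staple(inputs, n_labels = L)$label_map else NULL)
  fused <- Filter(Negate(is.null), fused)
  rows <- list()
  tr <- lm_coords(truth_landmarks)
  for (meth in names(fused)) {
    cc <- label_centroids(fused[[meth]], L, names = truth_landmarks$name)
    err <- sqrt(rowSums((cc$coords - tr)^2))
    rows[[meth]] <- tibble::tibble(landmark = truth_landmarks$name,
                                   method = meth, error_mm = err,
                                   lost = seq_len(L) %in% cc$lost)
  }
  do.call(rbind, rows)
}
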