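#' Atlas-building configuration
#'
#' @param tol convergence tolerance, in voxels, on the mean magnitude
#'   of the voxelwise average of the per-sample displacement fields
#'   over the foreground: iteration stops once the deformations into
#'   atlas space sum to (approximately) zero there, i.e. the atlas sits
#'   within `tol` voxels of the population's deformation centroid. The
#'   default of half a voxel reflects the sub-voxel floor set by the
#'   registration engine's regularization.
#' @param max_iter maximum atlas iterations.
#' @param registration a [registration_config()] used for every
#'   pairwise registration.
#' @return A list of class `atlas_config`.
#' @export
atlas_config <- function(tol = 0.5, max_iter = 10,
                         registration = registration_config()) {
  structure(list(tol = tol, max_iter = max_iter,
                 registration = registration),
            class = "atlas_config")
}

#' Build an unbiased population atlas
#'
#' Iteratively registers every sample to the current reference, averages
#' the warped intensities, and moves the reference by the voxelwise mean
#' displacement (small-deformation correction), so that at convergence
#' the atlas sits at the population's deformation centroid: the
#' transforms carrying the samples into atlas space sum to approximately
#' zero everywhere, and the result is unbiased with respect to the
#' initializing sample.
#'
#' @param samples list of [volume()] objects on compatible grids (>= 2).
#' @param init_sample_id index of the sample used to initialize the
#'   reference.
#' @param config an [atlas_config()].
#' @return An object of class `atlas`: `mean` (mean-intensity volume in
#'   atlas space), `transforms` (per-sample `displacement_transform`,
#'   atlas grid -> sample space, pull-back), `init_id`, `log` (mean
#'   residual displacement in voxels per iteration), `converged`.
#' @export
build_atlas <- function(samples, init_sample_id = 1,
                        config = atlas_config()) {
  n <- length(samples)
  if (n < 2) stop("build_atlas needs >= 2 samples")
  if (init_sample_id < 1 || init_sample_id > n)
    stop("init sample must be a member of the population")
  for (s in samples) stopifnot_volume(s, "every sample")
  ref <- samples[[init_sample_id]]
  d <- dim(ref$data)
  log_mag <- numeric(0)
  transforms <- NULL
  for (iter in seq_len(config$max_iter)) {
    transforms <- vector("list", n)
    warped <- matrix(0, prod(d), n)
    for (i in seq_len(n)) {
      tf <- tryCatch(register(ref, samples[[i]], config$registration),
                     error = function(e)
                       stop("build_atlas: registration of sample ", i,
                            " to the reference failed: ",
                            conditionMessage(e)))
      transforms[[i]] <- tf
      warped[, i] <- cpp_warp_by_field(as.numeric(samples[[i]]$data), d,
                                       effective_field_vox(tf, samples[[i]]),
                                       0, TRUE)
    }
    mean_img <- array(rowMeans(warped), d)
    mean_field <- Reduce(`+`, lapply(transforms, field_vox)) / n
    fg <- as.numeric(mean_img) > 0.5 * max(mean_img)
    mag <- mean(sqrt(rowSums(mean_field[fg, , drop = FALSE]^2)))
    log_mag <- c(log_mag, mag)
    ref <- volume(array(cpp_warp_by_field(as.numeric(mean_img), d,
                                          -mean_field, 0, TRUE), d),
                  ref$spacing, ref$origin, kind = "grayscale")
    if (mag < config$tol) break
  }
  structure(list(mean = ref, transforms = transforms,
                 init_id = init_sample_id, log = log_mag,
                 converged = log_mag[length(log_mag)] < config$tol,
                 n = n),
            class = "atlas")
}

#' @export
print.atlas <- function(x, ...) {
  cat(sprintf(paste0("<atlas> %d samples, init %d, %d iterations, ",
                     "final mean displacement %.4g voxels (%s)\n"),
              x$n, x$init_id, length(x$log), x$log[length(x$log)],
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Probabilistic atlas from binarized samples
#'
#' Warps each binarized sample into atlas space with the stored
#' transforms and averages, so a voxel's value is the frequency of that
#' voxel being foreground across the population (an exact multiple of
#' 1/n).
#'
#' @param atlas an [build_atlas()] result.
#' @param samples the same sample list the atlas was built from.
#' @param binarize_threshold foreground threshold applied to each sample
#'   (must lie within each sample's intensity range).
#' @return A probability [volume()].
#' @export
probability_atlas <- function(atlas, samples, binarize_threshold) {
  if (length(samples) != atlas$n)
    stop("probability_atlas: atlas was built from ", atlas$n,
         " samples, got ", length(samples))
  d <- dim(atlas$mean$data)
  acc <- numeric(prod(d))
  for (i in seq_along(samples)) {
    b <- binarize(samples[[i]], binarize_threshold)
    w <- warp_labels(volume(array(as.integer(b$data), d), b$spacing,
                            b$origin, kind = "label"),
                     atlas$transforms[[i]], n_labels = 1)
    acc <- acc + as.numeric(w$data)
  }
  volume(array(acc / length(samples), d), atlas$mean$spacing,
         atlas$mean$origin, kind = "probability")
}

#' Probability surface mask
#'
#' The p-surface of a probabilistic atlas is the boundary of the mask of
#' voxels with foreground frequency >= p. Masks are nested: p1 <= p2
#' implies mask(p2) is contained in mask(p1).
#'
#' @param prob_volume a probability [volume()].
#' @param p probability level in (0, 1].
#' @return A binary [volume()].
#' @export
probability_surface <- function(prob_volume, p) {
  stopifnot_volume(prob_volume, "prob_volume")
  if (p <= 0 || p > 1) stop("p must be in (0, 1]")
  m <- (prob_volume$data >= p) * 1
  if (sum(m) == 0) stop("no voxels at probability ", p)
  volume(m, prob_volume$spacing, prob_volume$origin, kind = "binary")
}

#' Pairwise atlas similarity table
#'
#' Compares a set of atlases (e.g. built from different initializing
#' samples) by Dice overlap of their probability-surface masks and by
#' Pearson correlation of their mean intensities, in the layout of an
#' initialization-sensitivity experiment: Dice in the upper triangle,
#' correlation in the lower.
#'
#' @param atlases list of `atlas` objects on a common grid.
#' @param samples the sample list used for every atlas.
#' @param binarize_threshold threshold for [probability_atlas()].
#' @param p probability level of the compared surface mask.
#' @return A list with `matrix` (Dice upper / correlation lower
#'   triangle) and `table` (tidy tibble of all pairs).
#' @export
compare_atlases <- function(atlases, samples, binarize_threshold = 0.5,
                            p = 0.5) {
  k <- length(atlases)
  if (k < 2) stop("need >= 2 atlases")
  masks <- lapply(atlases, function(a)
    probability_surface(probability_atlas(a, samples, binarize_threshold),
                        p))
  m <- diag(1, k)
  rows <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    dij <- dice(masks[[i]], masks[[j]])
    cij <- intensity_correlation(atlases[[i]]$mean, atlases[[j]]$mean)
    m[i, j] <- dij
    m[j, i] <- cij
    rows[[length(rows) + 1]] <-
      tibble::tibble(atlas_a = i, atlas_b = j, dice = dij,
                     correlation = cij)
  }
  dimnames(m) <- list(paste0("atlas", seq_len(k)),
                      paste0("atlas", seq_len(k)))
  list(matrix = m, table = do.call(rbind, rows))
}
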