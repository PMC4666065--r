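#' Synthetic study specification
#'
#' Parameters for generating a synthetic population of 3D "mandible-like"
#' grayscale volumes with known landmarks, smooth inter-individual
#' deformations, and simulated repeated manual annotations. Defaults
#' describe the package's reference synthetic study: a population of 40
#' samples on a 64 x 96 x 64 grid at 0.03442 mm isotropic spacing with 16
#' landmarks, deformation s.d. of 2 voxels, and per-landmark observer
#' noise whose attempt-to-attempt median distance is 0.048 mm.
#'
#' @param n population size (>= 2).
#' @param grid grid dimensions in voxels (x, y, z).
#' @param spacing isotropic voxel size in mm.
#' @param n_landmarks number of landmarks (16 for the default shape).
#' @param deform_sd_voxels s.d. of the random smooth displacement fields,
#'   in voxels.
#' @param control_grid control-point grid for the deformation model.
#' @param deform_smooth_sigma Gaussian smoothing sigma (voxels) applied
#'   to the upsampled displacement field.
#' @param jacobian_min fields whose Jacobian determinant drops to or
#'   below this value anywhere are rejected and resampled (folding
#'   guard).
#' @param max_retries rejection-sampling cap per sample.
#' @param intensity_noise_sd additive Gaussian intensity noise s.d.
#'   (intensity units; the base shape has intensity ~1).
#' @param blur_sigma Gaussian blur (voxels) applied to the binary base
#'   shape to mimic partial-volume smoothness.
#' @param observer_sd_mm length-`n_landmarks` vector of per-landmark
#'   isotropic manual-annotation s.d. in mm. The default follows the
#'   characteristic pattern of real digitization errors (most landmarks
#'   precise, a few curvature-defined "type III" landmarks several times
#'   noisier), scaled so that the median distance between two simulated
#'   attempts is 0.048 mm.
#' @return A list of class `synth_spec`.
#' @export
synth_study_spec <- function(n = 40,
                             grid = c(64, 96, 64),
                             spacing = 0.03442,
                             n_landmarks = 16,
                             deform_sd_voxels = 2,
                             control_grid = c(4, 5, 4),
                             deform_smooth_sigma = NULL,
                             jacobian_min = 0.05,
                             max_retries = 25,
                             intensity_noise_sd = 0.02,
                             blur_sigma = 1.2,
                             observer_sd_mm = NULL) {
  if (n < 2) stop("population size n must be >= 2")
  if (is.null(observer_sd_mm)) {
    # per-landmark error pattern (mm): most small, landmarks 7/10/12/16
    # larger (type III); factor 0.36372 calibrates the simulated
    # attempt-to-attempt median distance to 0.048 mm
    pattern <- c(0.04, 0.06, 0.04, 0.07, 0.02, 0.05, 0.14, 0.06,
                 0.06, 0.18, 0.07, 0.10, 0.05, 0.07, 0.04, 0.11)
    observer_sd_mm <- rep_len(pattern, n_landmarks) * 0.36372
  }
  if (length(observer_sd_mm) != n_landmarks)
    stop("observer_sd_mm must have length n_landmarks")
  # deformation correlation length scales with the grid so that warps
  # stay diffeomorphic at the default displacement s.d.
  if (is.null(deform_smooth_sigma))
    deform_smooth_sigma <- 0.15 * min(grid)
  structure(list(n = n, grid = as.integer(grid), spacing = spacing,
                 n_landmarks = n_landmarks,
                 deform_sd_voxels = deform_sd_voxels,
                 control_grid = as.integer(control_grid),
                 deform_smooth_sigma = deform_smooth_sigma,
                 jacobian_min = jacobian_min, max_retries = max_retries,
                 intensity_noise_sd = intensity_noise_sd,
                 blur_sigma = blur_sigma,
                 observer_sd_mm = observer_sd_mm),
            class = "synth_spec")
}

#' Build the synthetic base shape with its landmarks
#'
#' The base shape is a composition of ellipsoidal lobes (an elongated
#' body, an ascending ramus plate, and condylar, coronoid and angular
#' processes for the default "mandible-like" form), rasterized as a
#' binary union and Gaussian-blurred into a grayscale volume. Landmarks
#' are placed at named loci of the lobes (poles, junctions, and two
#' mid-curvature points standing in for type III landmarks).
#'
#' @param spec a [synth_study_spec()], or a list of custom lobes, each
#'   `list(center=, radii=, intensity=)` in voxel units, supplied via
#'   `lobes`.
#' @param lobes optional custom lobe list overriding the default shape.
#' @param landmarks optional custom landmark matrix (voxel coords) with
#'   rownames; overrides the default 16.
#' @return A list with `volume` (grayscale [volume()]) and `landmarks`
#'   (a [landmark_set()] in world mm).
#' @export
make_base_shape <- function(spec = synth_study_spec(), lobes = NULL,
                            landmarks = NULL) {
  d <- spec$grid
  sp <- rep(spec$spacing, 3)
  if (is.null(lobes)) lobes <- default_lobes(d)
  if (length(lobes) == 0) stop("at least one lobe is required")
  arr <- array(0, d)
  gx <- seq_len(d[1]) - 1; gy <- seq_len(d[2]) - 1; gz <- seq_len(d[3]) - 1
  for (lb in lobes) {
    c0 <- lb$center; r0 <- lb$radii
    ex <- ((gx - c0[1]) / r0[1])^2
    ey <- ((gy - c0[2]) / r0[2])^2
    ez <- ((gz - c0[3]) / r0[3])^2
    inside <- outer(outer(ex, ey, `+`), ez, `+`) <= 1
    arr[inside] <- pmax(arr[inside], lb$intensity %||% 1)
  }
  if (spec$blur_sigma > 0)
    arr <- array(cpp_gaussian_smooth(as.numeric(arr), d,
                                     rep(spec$blur_sigma, 3)), d)
  vol <- volume(arr, sp, c(0, 0, 0), kind = "grayscale")
  if (is.null(landmarks)) landmarks <- default_landmarks(d)
  if (nrow(landmarks) < 3) stop("need at least 3 landmarks")
  out_of_grid <- landmarks[, 1] < 0 | landmarks[, 2] < 0 |
    landmarks[, 3] < 0 | landmarks[, 1] > d[1] - 1 |
    landmarks[, 2] > d[2] - 1 | landmarks[, 3] > d[3] - 1
  if (any(out_of_grid))
    stop("landmarks outside the configured grid: ",
         paste(rownames(landmarks)[out_of_grid], collapse = ", "))
  lms <- landmark_set(rownames(landmarks), voxel_to_world(landmarks, vol))
  list(volume = vol, landmarks = lms)
}

default_lobes <- function(d) {
  # positions as fractions of the grid so the shape scales with it
  f <- function(p) p * (d - 1)
  list(
    body     = list(center = f(c(0.50, 0.38, 0.40)),
                    radii  = f(c(0.26, 0.32, 0.22)), intensity = 1),
    ramus    = list(center = f(c(0.50, 0.68, 0.55)),
                    radii  = f(c(0.22, 0.18, 0.28)), intensity = 1),
    condyle  = list(center = f(c(0.50, 0.80, 0.74)),
                    radii  = f(c(0.12, 0.10, 0.11)), intensity = 1),
    coronoid = list(center = f(c(0.50, 0.58, 0.80)),
                    radii  = f(c(0.10, 0.08, 0.11)), intensity = 1),
    angular  = list(center = f(c(0.50, 0.80, 0.26)),
                    radii  = f(c(0.12, 0.11, 0.10)), intensity = 1)
  )
}

default_landmarks <- function(d) {
  f <- function(px, py, pz) c(px, py, pz) * (d - 1)
  m <- rbind(
    incisor_tip        = f(0.50, 0.07, 0.40),
    body_ant_dorsal    = f(0.50, 0.17, 0.56),
    body_ant_ventral   = f(0.50, 0.17, 0.24),
    body_mid_dorsal    = f(0.50, 0.38, 0.61),
    body_mid_ventral   = f(0.50, 0.38, 0.19),
    body_lat_left      = f(0.25, 0.38, 0.40),
    body_lat_right     = f(0.75, 0.38, 0.40),
    body_ramus_notch   = f(0.50, 0.53, 0.60),   # type III: curvature point
    coronoid_tip       = f(0.50, 0.58, 0.90),
    sigmoid_notch      = f(0.50, 0.69, 0.70),   # type III: deepest point
    condyle_top        = f(0.50, 0.80, 0.84),
    condyle_post       = f(0.50, 0.91, 0.74),
    ramus_post         = f(0.50, 0.86, 0.55),
    angular_post       = f(0.50, 0.91, 0.26),
    angular_ventral    = f(0.50, 0.80, 0.17),
    gonial_notch       = f(0.50, 0.71, 0.22)    # junction angular/body
  )
  m
}

#' Sample a synthetic population of deformed volumes
#'
#' Each sample is the base shape warped by a random smooth displacement
#' field (random control-point displacements, trilinearly upsampled,
#' Gaussian-smoothed, rescaled to the requested s.d., and
#' rejection-sampled until the Jacobian determinant of `id + u` stays
#' positive) plus additive intensity noise. Ground-truth landmarks are
#' the exact images of the base landmarks under each sample's generating
#' deformation. Fully reproducible from `seed`.
#'
#' @param base output of [make_base_shape()].
#' @param spec a [synth_study_spec()].
#' @param seed integer RNG seed.
#' @param keep_fields if `TRUE`, the generating `displacement_transform`
#'   of each sample is kept (memory-heavy; used for conservation checks).
#' @return List of samples, each `list(volume=, truth=, field=)`.
#' @export
sample_population <- function(base, spec, seed = 1, keep_fields = FALSE) {
  if (spec$n < 2) stop("population size n must be >= 2")
  set.seed(seed)
  vol <- base$volume
  d <- dim(vol$data)
  out <- vector("list", spec$n)
  for (i in seq_len(spec$n)) {
    field <- draw_smooth_field(spec, d)
    v <- cpp_warp_by_field(as.numeric(vol$data), d, field, 0, TRUE)
    if (spec$intensity_noise_sd > 0)
      v <- v + stats::rnorm(length(v), 0, spec$intensity_noise_sd)
    sample_vol <- volume(array(v, d), vol$spacing, vol$origin,
                         kind = "grayscale")
    truth <- deform_points(base$landmarks, field, vol)
    tf <- new_transform(sweep(field, 2, vol$spacing, `*`), d,
                        vol$spacing, vol$origin)
    out[[i]] <- list(volume = sample_vol, truth = truth,
                     field = if (keep_fields) tf else NULL)
  }
  out
}

draw_smooth_field <- function(spec, d) {
  if (spec$deform_sd_voxels == 0) return(matrix(0, prod(d), 3))
  cg <- spec$control_grid
  for (try in seq_len(spec$max_retries)) {
    # control-point displacements ~ N(0, sd^2) voxels; upsampling and
    # smoothing yield the smooth realized field (its pointwise s.d. is
    # below the control-point s.d., as in free-form deformation models)
    ctrl <- matrix(stats::rnorm(3 * prod(cg), 0, spec$deform_sd_voxels),
                   ncol = 3)
    field <- cpp_resample_field(ctrl, cg, d, 1)
    for (c in 1:3)
      field[, c] <- cpp_gaussian_smooth(field[, c], d,
                                        rep(spec$deform_smooth_sigma, 3))
    jd <- cpp_jacobian_det(field, d)
    if (min(jd) > spec$jacobian_min) return(field)
  }
  stop("rejection sampling failed after ", spec$max_retries,
       " tries: deformation s.d. too large for a folding-free field")
}

# exact image of base landmarks under the generating deformation:
# solve p + u(p) = q per point by fixed-point iteration on the
# continuously interpolated field
deform_points <- function(lms, field_vox, vol) {
  q <- world_to_voxel(lm_coords(lms), vol)
  p <- q
  d <- dim(vol$data)
  for (it in 1:50) {
    u <- cpp_field_at_points(field_vox, d, p)
    p_new <- q - u
    if (max(abs(p_new - p)) < 1e-10) { p <- p_new; break }
    p <- p_new
  }
  lm_replace_coords(lms, voxel_to_world(p, vol))
}

#' Simulate repeated manual annotation attempts
#'
#' Each attempt adds iid zero-mean isotropic Gaussian noise per landmark
#' with that landmark's s.d. Averaging the attempts (see
#' [average_landmarks()]) yields the synthetic gold standard.
#'
#' @param truth a [landmark_set()] of true locations.
#' @param observer_sd_mm per-landmark s.d. vector (mm), length L.
#' @param n_attempts number of annotation attempts.
#' @param seed integer RNG seed.
#' @return List of `n_attempts` [landmark_set()] objects.
#' @export
simulate_observers <- function(truth, observer_sd_mm, n_attempts = 2,
                               seed = 1) {
  L <- nrow(truth)
  if (length(observer_sd_mm) != L)
    stop("observer_sd_mm must have length ", L)
  set.seed(seed)
  lapply(seq_len(n_attempts), function(a) {
    noise <- matrix(stats::rnorm(3 * L), L, 3) * observer_sd_mm
    lm_replace_coords(truth, lm_coords(truth) + noise)
  })
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper: base shape, deformed population with truth
#' landmarks, two simulated manual annotation attempts per sample, and
#' their average as the gold standard (GS).
#'
#' @param spec a [synth_study_spec()].
#' @param seed integer RNG seed controlling both deformations and
#'   observer noise.
#' @param n_attempts manual attempts per sample (default 2).
#' @param keep_fields keep generating fields (see [sample_population()]).
#' @return A list of class `synth_study` with elements `base`,
#'   `samples` (volumes), `truth`, `attempts`, `gs`, `spec`, `seed`.
#' @export
synth_study <- function(spec = synth_study_spec(), seed = 1,
                        n_attempts = 2, keep_fields = FALSE) {
  base <- make_base_shape(spec)
  pop <- sample_population(base, spec, seed = seed,
                           keep_fields = keep_fields)
  attempts <- vector("list", spec$n)
  gs <- vector("list", spec$n)
  for (i in seq_len(spec$n)) {
    attempts[[i]] <- simulate_observers(pop[[i]]$truth, spec$observer_sd_mm,
                                        n_attempts = n_attempts,
                                        seed = seed * 1000L + i)
    gs[[i]] <- average_landmarks(attempts[[i]])
  }
  structure(list(base = base,
                 samples = lapply(pop, `[[`, "volume"),
                 truth = lapply(pop, `[[`, "truth"),
                 fields = lapply(pop, `[[`, "field"),
                 attempts = attempts, gs = gs,
                 spec = spec, seed = seed),
            class = "synth_study")
}

#' @export
print.synth_study <- function(x, ...) {
  cat(sprintf("<synth_study> n=%d, grid %s, %d landmarks, seed %d\n",
              x$spec$n, paste(x$spec$grid, collapse = "x"),
              x$spec$n_landmarks, x$seed))
  invisible(x)
}

#' Write a synthetic study to a directory
#'
#' Emits one NRRD volume per sample, truth landmarks, each observer
#' attempt and the gold standard (both fcsv and CSV), plus a JSON
#' manifest recording every generator parameter and the seed. The
#' Gaussian form of the observer noise is an assumption and is flagged
#' as such in the manifest.
#'
#' @param study a [synth_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- study$spec$n
  for (i in seq_len(n)) {
    id <- sprintf("sample_%02d", i)
    write_volume(study$samples[[i]], file.path(dir, paste0(id, ".nrrd")))
    write_landmarks(study$truth[[i]],
                    file.path(dir, paste0(id, "_truth.csv")))
    for (a in seq_along(study$attempts[[i]]))
      write_landmarks(study$attempts[[i]][[a]],
                      file.path(dir, sprintf("%s_attempt%d.fcsv", id, a)))
    write_landmarks(study$gs[[i]], file.path(dir, paste0(id, "_gs.fcsv")))
  }
  manifest <- c(unclass(study$spec),
                list(seed = study$seed,
                     observer_noise_model =
                       "isotropic Gaussian per landmark (assumed form)"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
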