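#' Registration configuration
#'
#' Settings for the built-in multi-resolution deformable registration
#' engine (demons-style forces with Gaussian fluid/diffusion
#' regularization). The engine is fully deterministic: no stochastic
#' sampling is used, so repeated runs on the same inputs give identical
#' transforms.
#'
#' @param levels number of multi-resolution pyramid levels (>= 1);
#'   each level halves the grid.
#' @param iterations iterations per level, coarsest first; recycled to
#'   `levels`.
#' @param smooth_update_sigma Gaussian sigma (voxels) applied to each
#'   update field ("fluid" regularization).
#' @param smooth_field_sigma Gaussian sigma (voxels) applied to the
#'   accumulated field ("diffusion" regularization).
#' @param max_step per-iteration displacement cap in voxels.
#' @param metric similarity metric reported and monitored:
#'   `"ncc"` (normalized cross-correlation) or `"mse"`.
#' @param attributes if `TRUE`, demons forces are averaged over an
#'   attribute-channel stack (intensity plus gradient magnitude) instead
#'   of raw intensity alone — a lightweight stand-in for richer
#'   texture-attribute matching.
#' @param saliency if `TRUE`, per-voxel updates are down-weighted where
#'   the local residual is noisy relative to the local gradient, so that
#'   regions with unreliable correspondence contribute less.
#' @param translation_init if `TRUE`, initialize with the foreground
#'   center-of-mass translation.
#' @param tol early-stopping tolerance on relative metric improvement.
#' @return A list of class `registration_config`.
#' @export
registration_config <- function(levels = 3, iterations = c(100, 60, 30),
                                smooth_update_sigma = 1.0,
                                smooth_field_sigma = 1.0,
                                max_step = 2.0,
                                metric = c("ncc", "mse"),
                                attributes = FALSE,
                                saliency = FALSE,
                                translation_init = TRUE,
                                tol = 1e-5) {
  metric <- match.arg(metric)
  if (levels < 1) stop("levels must be >= 1")
  if (smooth_update_sigma < 0 || smooth_field_sigma < 0)
    stop("smoothing sigmas must be >= 0")
  iterations <- rep_len(iterations, levels)
  structure(list(levels = levels, iterations = iterations,
                 smooth_update_sigma = smooth_update_sigma,
                 smooth_field_sigma = smooth_field_sigma,
                 max_step = max_step, metric = metric,
                 attributes = attributes, saliency = saliency,
                 translation_init = translation_init, tol = tol),
            class = "registration_config")
}

new_transform <- function(field_mm, dim, spacing, origin,
                          similarity = NA_real_, meta = list()) {
  structure(list(field = field_mm, dim = as.integer(dim),
                 spacing = spacing, origin = origin,
                 similarity = similarity, meta = meta),
            class = "displacement_transform")
}

#' @export
print.displacement_transform <- function(x, ...) {
  mag <- sqrt(rowSums(x$field^2))
  cat(sprintf(paste0("<displacement_transform> grid %s, mean |u| %.4g mm,",
                     " max |u| %.4g mm, similarity %.4f\n"),
              paste(x$dim, collapse = "x"), mean(mag), max(mag),
              x$similarity))
  invisible(x)
}

is_transform <- function(x) inherits(x, "displacement_transform")

field_vox <- function(tf) sweep(tf$field, 2, tf$spacing, `/`)

zero_transform <- function(ref) {
  n <- prod(dim(ref$data))
  new_transform(matrix(0, n, 3), dim(ref$data), ref$spacing, ref$origin,
                similarity = 1)
}

base_grid <- function(d) {
  cbind(rep(seq_len(d[1]) - 1, times = d[2] * d[3]),
        rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3]),
        rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
}

normalize01 <- function(x) {
  r <- range(x)
  if (r[2] > r[1]) (x - r[1]) / (r[2] - r[1]) else x * 0
}

ncc_of <- function(a, b) {
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(0)
  stats::cor(a, b)
}

#' Deformable registration of two volumes
#'
#' Estimates a dense displacement transform mapping points of the fixed
#' volume's space into the moving volume's space (pull-back convention),
#' by symmetric-force demons over a Gaussian image pyramid. When the two
#' volumes are not on the same grid, the moving volume is first resampled
#' onto the fixed grid through world coordinates.
#'
#' @param fixed,moving [volume()] objects with overlapping fields of view.
#' @param config a [registration_config()].
#' @return A `displacement_transform` on the fixed grid with the achieved
#'   similarity (`$similarity`, NCC by default) and the per-level metric
#'   trace in `$meta$trace`.
#' @export
register <- function(fixed, moving, config = registration_config()) {
  stopifnot_volume(fixed, "fixed"); stopifnot_volume(moving, "moving")
  if (length(dim(fixed$data)) != 3 || length(dim(moving$data)) != 3)
    stop("register: both volumes must be 3D")
  if (!same_grid(fixed, moving)) {
    moving <- resample_to_grid(moving, fixed)
  }
  f <- normalize01(as.numeric(fixed$data))
  m <- normalize01(as.numeric(moving$data))
  d <- dim(fixed$data)

  # pyramid, coarsest first; depth capped so the coarsest level keeps
  # at least ~12 voxels along the shortest axis
  n_levels <- min(config$levels,
                  max(1L, floor(log2(min(d) / 12)) + 1L))
  iterations <- rep_len(rev(rev(config$iterations)[seq_len(n_levels)]),
                        n_levels)
  pyr_f <- list(list(data = f, dim = as.integer(d)))
  pyr_m <- list(list(data = m, dim = as.integer(d)))
  if (n_levels > 1) {
    for (l in 2:n_levels) {
      pf <- pyr_f[[1]]; pm <- pyr_m[[1]]
      sm_f <- cpp_gaussian_smooth(pf$data, pf$dim, rep(0.7, 3))
      sm_m <- cpp_gaussian_smooth(pm$data, pm$dim, rep(0.7, 3))
      pyr_f <- c(list(cpp_downsample2(sm_f, pf$dim)), pyr_f)
      pyr_m <- c(list(cpp_downsample2(sm_m, pm$dim)), pyr_m)
    }
  }

  u <- matrix(0, prod(pyr_f[[1]]$dim), 3)
  if (config$translation_init) {
    t0 <- com_translation(pyr_f[[1]], pyr_m[[1]])
    u <- matrix(rep(t0, each = nrow(u)), ncol = 3)
  }
  trace <- list()
  for (lev in seq_len(n_levels)) {
    pf <- pyr_f[[lev]]; pm <- pyr_m[[lev]]
    res <- if (!config$attributes && !config$saliency) {
      out <- cpp_demons_level(as.numeric(pf$data), as.numeric(pm$data),
                              pf$dim, u, iterations[lev],
                              config$smooth_update_sigma,
                              config$smooth_field_sigma,
                              config$max_step, config$tol)
      check_divergence(out$metric, pf$dim)
      out
    } else demons_level(pf, pm, u, config, iterations[lev])
    u <- res$u
    trace[[lev]] <- res$metric
    if (lev < n_levels) {
      u <- cpp_resample_field(u, pf$dim, pyr_f[[lev + 1]]$dim, 2)
    }
  }
  warped <- cpp_warp_by_field(m, as.integer(d), u, 0, TRUE)
  sim <- if (config$metric == "mse") -mean((warped - f)^2) else
    ncc_of(warped, f)
  field_mm <- sweep(u, 2, fixed$spacing, `*`)
  new_transform(field_mm, d, fixed$spacing, fixed$origin, similarity = sim,
                meta = list(trace = trace, config = config))
}

com_translation <- function(pf, pm) {
  g <- base_grid(pf$dim)
  wf <- pmax(as.numeric(pf$data) - 0.1, 0)
  wm <- pmax(as.numeric(pm$data) - 0.1, 0)
  if (sum(wf) == 0 || sum(wm) == 0) return(c(0, 0, 0))
  cf <- colSums(g * wf) / sum(wf)
  cm <- colSums(g * wm) / sum(wm)
  cm - cf  # pull-back: fixed point + t lands on moving
}

demons_level <- function(pf, pm, u, config, n_iter) {
  d <- pf$dim
  f <- as.numeric(pf$data)
  gfix <- cpp_gradient(f, d)
  metric <- numeric(0)
  sig_u <- rep(config$smooth_update_sigma, 3)
  sig_f <- rep(config$smooth_field_sigma, 3)
  chans_f <- list(f)
  if (config$attributes) {
    gm_f <- sqrt(rowSums(gfix^2))
    chans_f <- c(chans_f, list(normalize01(gm_f)))
  }
  best_u <- u; best_metric <- Inf
  stall <- 0L
  for (it in seq_len(n_iter)) {
    w <- cpp_warp_by_field(pm$data, d, u, 0, TRUE)
    diffs <- w - f
    gw <- cpp_gradient(w, d)
    grad <- 0.5 * (gw + gfix)
    upd <- demons_force(diffs, grad, config$max_step)
    if (config$attributes) {
      gm_w <- normalize01(sqrt(rowSums(gw^2)))
      diffs2 <- gm_w - chans_f[[2]]
      grad2 <- 0.5 * (cpp_gradient(gm_w, d) + cpp_gradient(chans_f[[2]], d))
      upd <- 0.5 * (upd + demons_force(diffs2, grad2, config$max_step))
    }
    if (config$saliency) {
      loc_var <- cpp_gaussian_smooth(diffs^2, d, rep(2, 3))
      loc_g2 <- cpp_gaussian_smooth(rowSums(grad^2), d, rep(2, 3))
      sal <- loc_g2 / (loc_g2 + loc_var + 1e-6)
      upd <- upd * as.numeric(sal)
    }
    for (c in 1:3) upd[, c] <- cpp_gaussian_smooth(upd[, c], d, sig_u)
    u <- u + upd
    if (config$smooth_field_sigma > 0)
      for (c in 1:3) u[, c] <- cpp_gaussian_smooth(u[, c], d, sig_f)
    mval <- mean(diffs^2)  # demons objective; monitored for divergence
    if (!is.finite(mval))
      stop("register: non-finite metric at level grid ",
           paste(d, collapse = "x"), ", iteration ", it)
    metric <- c(metric, mval)
    if (mval < best_metric - 1e-12) {
      best_metric <- mval; best_u <- u; stall <- 0L
    } else stall <- stall + 1L
    if (it > 5 &&
        abs(metric[it] - metric[it - 5]) <
          config$tol * max(abs(metric[it]), 1e-12)) break
    if (stall >= 10L) break
  }
  check_divergence(metric, d)
  list(u = best_u, metric = metric)
}

check_divergence <- function(metric, d) {
  # only substantive monotone worsening counts; tiny drifts around an
  # already-perfect match (MSE ~ 0 on the normalized intensity scale)
  # are numerical noise
  if (length(metric) >= 5 && all(diff(metric) > 0) &&
      metric[length(metric)] > 1.05 * metric[1] &&
      metric[length(metric)] > 1e-5)
    stop("register: metric diverged monotonically over level grid ",
         paste(d, collapse = "x"), " (MSE trace: ",
         paste(signif(metric, 4), collapse = ", "), ")")
  invisible(NULL)
}

demons_force <- function(diffs, grad, max_step) {
  diffs <- as.numeric(diffs)
  g2 <- rowSums(grad^2)
  denom <- g2 + diffs^2
  s <- ifelse(denom > 1e-9, -diffs / denom, 0)
  upd <- grad * s
  mag <- sqrt(rowSums(upd^2))
  over <- mag > max_step
  if (any(over)) upd[over, ] <- upd[over, ] * (max_step / mag[over])
  upd
}

#' Resample a volume onto the grid of a reference volume
#'
#' @param vol the volume to resample.
#' @param ref the reference [volume()] providing the target grid.
#' @param interpolation `"linear"` or `"nearest"`.
#' @param background value used outside `vol`'s domain.
#' @return A [volume()] on `ref`'s grid.
#' @export
resample_to_grid <- function(vol, ref, interpolation = "linear",
                             background = 0) {
  d <- dim(ref$data)
  pts_world <- voxel_to_world(base_grid(d), ref)
  pts_vox <- world_to_voxel(pts_world, vol)
  vals <- if (interpolation == "nearest") {
    nearest_lookup(vol$data, pts_vox, background)
  } else {
    cpp_interp_at_points(as.numeric(vol$data), dim(vol$data), pts_vox,
                         background, FALSE)
  }
  volume(array(vals, d), ref$spacing, ref$origin, kind = vol$kind)
}

nearest_lookup <- function(arr, pts_vox, background = 0) {
  d <- dim(arr)
  ix <- round(pts_vox[, 1]); iy <- round(pts_vox[, 2]); iz <- round(pts_vox[, 3])
  ok <- ix >= 0 & iy >= 0 & iz >= 0 & ix <= d[1] - 1 & iy <= d[2] - 1 &
    iz <= d[3] - 1
  out <- rep(background, nrow(pts_vox))
  lin <- ix[ok] + d[1] * iy[ok] + d[1] * d[2] * iz[ok] + 1
  out[ok] <- arr[lin]
  out
}

#' Invert a displacement transform
#'
#' Fixed-point inversion of the dense field. The inverse is defined on
#' the same grid; composing the transform with its inverse displaces any
#' in-domain point by less than the stated tolerance at 99% of voxels
#' (the achieved residual is attached as attribute `"residual"`).
#'
#' @param transform a `displacement_transform`.
#' @param n_iter fixed-point iterations.
#' @param tol round-trip residual tolerance in voxels (default 0.05).
#' @return The inverse `displacement_transform`.
#' @export
invert <- function(transform, n_iter = 30, tol = 0.05) {
  stopifnot(is_transform(transform))
  uvox <- field_vox(transform)
  jd <- cpp_jacobian_det(uvox, transform$dim)
  if (min(jd) <= 0 && mean(jd <= 0) > 0.001)
    stop("invert: non-invertible field (Jacobian <= 0 at ",
         signif(100 * mean(jd <= 0), 3), "% of voxels)")
  v <- cpp_invert_field(uvox, transform$dim, n_iter)
  resid <- cpp_compose_fields(uvox, v, transform$dim)
  rmag <- sqrt(rowSums(resid^2))
  q99 <- stats::quantile(rmag, 0.99, names = FALSE)
  if (q99 > tol)
    warning("invert: round-trip residual 99th percentile ",
            signif(q99, 3), " voxels exceeds tolerance ", tol)
  out <- new_transform(sweep(v, 2, transform$spacing, `*`),
                       transform$dim, transform$spacing, transform$origin,
                       similarity = transform$similarity,
                       meta = c(transform$meta, list(inverse = TRUE)))
  attr(out, "residual") <- c(q99_voxels = q99, max_voxels = max(rmag))
  out
}

# effective voxel-unit displacement field carrying the fixed grid of `tf`
# into voxel coordinates of `moving` (handles differing origins/spacings)
effective_field_vox <- function(tf, moving) {
  if (all(abs(tf$spacing - moving$spacing) < 1e-9) &&
      all(abs(tf$origin - moving$origin) < 1e-9) &&
      identical(tf$dim, dim(moving$data))) {
    return(field_vox(tf))
  }
  g <- base_grid(tf$dim)
  pts_world <- sweep(sweep(g, 2, tf$spacing, `*`), 2, tf$origin, `+`) +
    tf$field
  pts_vox_mov <- sweep(sweep(pts_world, 2, moving$origin, `-`),
                       2, moving$spacing, `/`)
  pts_vox_mov - g
}

#' Warp a volume through a displacement transform
#'
#' Produces the warped image on the transform's fixed grid:
#' `out(x) = vol(x + u(x))` (pull-back).
#'
#' @param vol the moving [volume()].
#' @param transform a `displacement_transform`.
#' @param interpolation `"linear"` or `"nearest"`.
#' @param background value for points mapped outside `vol`.
#' @return A [volume()] on the transform's fixed grid.
#' @export
warp_volume <- function(vol, transform, interpolation = c("linear", "nearest"),
                        background = 0) {
  stopifnot_volume(vol, "vol"); stopifnot(is_transform(transform))
  interpolation <- match.arg(interpolation)
  ef <- effective_field_vox(transform, vol)
  d <- transform$dim
  if (interpolation == "nearest") {
    pts <- base_grid(d) + ef
    vals <- nearest_lookup(vol$data, pts, background)
  } else {
    vals <- cpp_warp_by_field(as.numeric(vol$data), d, ef, background,
                              FALSE)
  }
  volume(array(vals, d), transform$spacing, transform$origin,
         kind = if (vol$kind == "binary") "grayscale" else vol$kind)
}

#' Warp a label map through a displacement transform
#'
#' Each label (including background) is interpolated as a linear
#' indicator function and the output voxel takes the label with maximal
#' interpolated weight, which avoids the label erosion of plain
#' nearest-neighbour resampling. The label value set is never extended.
#'
#' @param label_map a label-map [volume()].
#' @param transform a `displacement_transform` whose fixed grid is the
#'   output grid.
#' @param n_labels number of landmark labels L (defaults to the maximum
#'   label present).
#' @return A label-map [volume()] on the transform's fixed grid.
#' @export
warp_labels <- function(label_map, transform, n_labels = NULL) {
  stopifnot_volume(label_map, "label_map"); stopifnot(is_transform(transform))
  n_labels <- n_labels %||% max(label_map$data)
  ef <- effective_field_vox(transform, label_map)
  lab <- cpp_warp_labels(as.integer(label_map$data), transform$dim, ef,
                         as.integer(n_labels))
  out <- volume(array(as.integer(lab), transform$dim), transform$spacing,
                transform$origin, kind = "label")
  attr(out, "landmark_names") <- attr(label_map, "landmark_names")
  out
}

#' Warp landmarks through a displacement transform
#'
#' Exact point mapping (no resampling error): each point `p` in the
#' transform's fixed space maps to `p + u(p)` with `u` interpolated at
#' `p`. To carry points living in the *moving* space back to the fixed
#' space, pass the inverse transform (see [invert()]).
#'
#' @param lms a [landmark_set()] with points in the transform's fixed
#'   space (world mm).
#' @param transform a `displacement_transform`.
#' @return The mapped [landmark_set()].
#' @export
warp_landmarks <- function(lms, transform) {
  stopifnot(is_transform(transform))
  p <- lm_coords(lms)
  pv <- sweep(sweep(p, 2, transform$origin, `-`), 2, transform$spacing, `/`)
  u <- cpp_field_at_points(transform$field, transform$dim, pv)
  lm_replace_coords(lms, p + u)
}

#' Read and write displacement transforms
#'
#' Dense fields are stored as 4D NRRD vector images (component axis
#' first, displacements in mm, LPS).
#'
#' @param transform a `displacement_transform`.
#' @param path output `.nrrd` path.
#' @export
write_transform <- function(transform, path) {
  stopifnot(is_transform(transform))
  d <- transform$dim
  hdr <- c("NRRD0004",
           "type: double",
           "dimension: 4",
           paste0("sizes: 3 ", paste(d, collapse = " ")),
           "space: left-posterior-superior",
           "kinds: vector domain domain domain",
           sprintf("space directions: none (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
                   transform$spacing[1], transform$spacing[2],
                   transform$spacing[3]),
           sprintf("space origin: (%.17g,%.17g,%.17g)",
                   transform$origin[1], transform$origin[2],
                   transform$origin[3]),
           "endian: little",
           "encoding: raw")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n\n"), con, eos = NULL)
  writeBin(as.numeric(t(transform$field)), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  if (!file.exists(path)) stop("transform file not found: ", path)
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  nl <- which(raw_all == as.raw(10L))
  hdr_end <- NA; prev <- 0L
  for (i in nl) {
    blank <- prev > 0 &&
      (i - prev == 1L || (i - prev == 2L && raw_all[prev + 1] == as.raw(13L)))
    if (blank) { hdr_end <- i; break }
    prev <- i
  }
  if (is.na(hdr_end)) stop("malformed transform NRRD: ", path)
  lines <- strsplit(rawToChar(raw_all[1:hdr_end]), "\r?\n")[[1]]
  kv <- list()
  for (ln in lines[-1]) {
    pos <- regexpr(":", ln, fixed = TRUE)
    if (pos < 0) next
    kv[[tolower(trimws(substr(ln, 1, pos - 1)))]] <-
      trimws(substr(ln, pos + 1, nchar(ln)))
  }
  sizes <- as.integer(strsplit(kv[["sizes"]], "\\s+")[[1]])
  if (length(sizes) != 4 || sizes[1] != 3)
    stop("not a 3-vector 4D field: ", path)
  d <- sizes[2:4]
  n <- prod(d)
  vals <- read_bin_data(raw_all, hdr_end, 3 * n, dtype_info("double"),
                        kv[["endian"]] %||% "little")
  field <- t(matrix(vals, nrow = 3))
  dirs <- parse_nrrd_vectors(kv[["space directions"]] %||% "(1,0,0) (0,1,0) (0,0,1)")
  spacing <- vapply(dirs, function(v) sqrt(sum(v^2)), numeric(1))
  origin <- if (!is.null(kv[["space origin"]]))
    parse_nrrd_vectors(kv[["space origin"]])[[1]] else c(0, 0, 0)
  new_transform(field, d, spacing, origin)
}
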