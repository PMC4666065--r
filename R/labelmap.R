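#' Rasterize landmarks as spherical labels
#'
#' Each landmark l in `lms` is painted into an integer label map on the
#' grid of `ref` as a sphere of radius `radius_voxels` centered on the
#' landmark. For isotropic spacing, sphere membership is evaluated in
#' voxel units (a voxel belongs to the sphere when its center lies within
#' the radius of the landmark's voxel position); for anisotropic volumes
#' membership is evaluated in world distance (mm). When spheres overlap,
#' a voxel is assigned to the nearest landmark; exact ties go to the
#' lower landmark index.
#'
#' @param lms a [landmark_set()] in world mm.
#' @param ref a [volume()] providing the target grid.
#' @param radius_voxels sphere radius in voxels (>= 0); radius 0 labels
#'   exactly one voxel per landmark.
#' @return A label-map `volume` (kind `"label"`) with values `0..L`.
#' @export
rasterize_spheres <- function(lms, ref, radius_voxels = 2) {
  stopifnot_volume(ref, "ref")
  if (radius_voxels < 0) stop("radius_voxels must be >= 0")
  d <- dim(ref$data)
  vx <- world_to_voxel(lm_coords(lms), ref)
  out_of_grid <- vx[, 1] < 0 | vx[, 2] < 0 | vx[, 3] < 0 |
    vx[, 1] > d[1] - 1 | vx[, 2] > d[2] - 1 | vx[, 3] > d[3] - 1
  if (any(out_of_grid))
    stop("landmark(s) outside grid: ",
         paste(lms$name[out_of_grid], collapse = ", "))
  iso <- max(ref$spacing) / min(ref$spacing) < 1 + 1e-6
  if (nrow(vx) > 1) {
    dmin <- min(stats::dist(vx))
    if (dmin < 1) warning("two landmarks closer than 1 voxel (",
                          signif(dmin, 3), " voxels)")
  }
  lab <- array(0L, d)
  best <- array(Inf, d)
  if (iso) {
    r <- radius_voxels
    r_ax <- rep(radius_voxels, 3)
  } else {
    r <- radius_voxels * min(ref$spacing)      # world-distance membership
    r_ax <- r / ref$spacing                    # per-axis bound in voxels
  }
  for (l in seq_len(nrow(vx))) {
    c_vox <- vx[l, ]
    # snap centers that are numerically at a grid point, so symmetric
    # spheres stay symmetric despite float round-off
    snap <- abs(c_vox - round(c_vox)) < 1e-6
    c_vox[snap] <- round(c_vox[snap])
    lo <- pmax(ceiling(c_vox - r_ax), 0)
    hi <- pmin(floor(c_vox + r_ax), d - 1)
    if (any(lo > hi)) next
    gx <- lo[1]:hi[1]; gy <- lo[2]:hi[2]; gz <- lo[3]:hi[3]
    if (iso) {
      dx <- (gx - c_vox[1]); dy <- (gy - c_vox[2]); dz <- (gz - c_vox[3])
    } else {
      dx <- (gx - c_vox[1]) * ref$spacing[1]
      dy <- (gy - c_vox[2]) * ref$spacing[2]
      dz <- (gz - c_vox[3]) * ref$spacing[3]
    }
    dist2 <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`)
    inside <- dist2 <= r^2 + 1e-12
    if (!any(inside)) next
    sub <- best[gx + 1, gy + 1, gz + 1, drop = FALSE]
    take <- inside & (dist2 < sub - 1e-12)  # strict: ties keep lower index
    sub[take] <- dist2[take]
    best[gx + 1, gy + 1, gz + 1] <- sub
    labsub <- lab[gx + 1, gy + 1, gz + 1, drop = FALSE]
    labsub[take] <- l
    lab[gx + 1, gy + 1, gz + 1] <- labsub
  }
  empty <- setdiff(seq_len(nrow(vx)), unique(as.vector(lab)))
  if (length(empty))
    warning("labels with no voxels after rasterization: ",
            paste(lms$name[empty], collapse = ", "))
  out <- volume(lab, ref$spacing, ref$origin, kind = "label")
  attr(out, "landmark_names") <- lms$name
  out
}

#' Centroid of a label in a label map
#'
#' The final landmark location of a transferred label is taken as the
#' centroid of its member voxels: the unweighted mean of their world
#' coordinates, or an intensity-weighted mean when `weights` is given
#' (the fuzzy variant, used for fused probability labels).
#'
#' @param label_map a label-map [volume()].
#' @param label integer label value (>= 1).
#' @param weights optional [volume()] of per-voxel weights on the same
#'   grid.
#' @return World coordinates (mm) of the label centroid, length 3.
#' @export
label_centroid <- function(label_map, label, weights = NULL) {
  stopifnot_volume(label_map, "label_map")
  idx <- which(label_map$data == label)
  if (length(idx) == 0)
    stop("landmark lost in fusion: label ", label, " has no voxels")
  d <- dim(label_map$data)
  vox <- cbind((idx - 1) %% d[1],
               ((idx - 1) %/% d[1]) %% d[2],
               (idx - 1) %/% (d[1] * d[2]))
  w <- if (is.null(weights)) rep(1, length(idx)) else weights$data[idx]
  if (sum(w) <= 0) stop("label_centroid: nonpositive total weight")
  ctr_vox <- colSums(vox * w) / sum(w)
  voxel_to_world(ctr_vox, label_map)
}

#' Extract all label centroids as a landmark set
#'
#' @param label_map a label-map [volume()].
#' @param n_labels number of landmark labels L.
#' @param names optional landmark names (defaults to the rasterization
#'   names attached to the map, or `LM1..LML`).
#' @param weights optional weight volume (fuzzy centroid).
#' @return A list: `landmarks` (a [landmark_set()] of the recovered
#'   labels), `lost` (ids of labels with no voxels), `names`, and
#'   `coords` (L x 3 matrix with NA rows for lost labels).
#' @export
label_centroids <- function(label_map, n_labels, names = NULL,
                            weights = NULL) {
  names <- names %||% attr(label_map, "landmark_names") %||%
    paste0("LM", seq_len(n_labels))
  coords <- matrix(NA_real_, n_labels, 3)
  lost <- integer(0)
  for (l in seq_len(n_labels)) {
    res <- tryCatch(label_centroid(label_map, l, weights),
                    error = function(e) NULL)
    if (is.null(res)) lost <- c(lost, l) else coords[l, ] <- res
  }
  ok <- stats::complete.cases(coords)
  lm <- landmark_set(names[ok], coords[ok, , drop = FALSE])
  list(landmarks = lm, lost = lost, names = names, coords = coords)
}
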