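#' Construct a 3D volume
#'
#' A `volume` is a 3D scalar grid with voxel spacing and world origin.
#' The world frame is LPS in millimetres; voxel indices are 0-based with
#' the voxel-center convention, so `world = origin + index * spacing`.
#'
#' @param data 3D numeric array (grayscale, binary, probability or
#'   integer label values).
#' @param spacing numeric length-3, voxel size in mm per axis (x, y, z);
#'   must be strictly positive.
#' @param origin numeric length-3, world position (mm) of the center of
#'   voxel (0, 0, 0).
#' @param kind one of `"grayscale"`, `"binary"`, `"probability"`,
#'   `"label"`. Binary volumes must contain only {0, 1}; probability
#'   volumes must lie in [0, 1].
#' @return An object of class `volume`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                   kind = c("grayscale", "binary", "probability", "label")) {
  kind <- match.arg(kind)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3D array, got ",
         paste(dim(data), collapse = "x"))
  if (any(dim(data) < 1L)) stop("all volume dimensions must be >= 1")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive finite numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite numbers")
  if (kind == "binary" && !all(data %in% c(0, 1)))
    stop("binary volume values must be in {0, 1}")
  if (kind == "probability" && (min(data) < 0 || max(data) > 1))
    stop("probability volume values must be in [0, 1]")
  structure(list(data = data, spacing = spacing, origin = origin,
                 kind = kind),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("<volume> %s, %s voxels, spacing (%s) mm, origin (%s) mm\n",
              x$kind, paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 6), collapse = ", "),
              paste(signif(x$origin, 6), collapse = ", ")))
  invisible(x)
}

#' @export
dim.volume <- function(x) dim(x$data)

is_volume <- function(x) inherits(x, "volume")

stopifnot_volume <- function(x, what = "argument") {
  if (!is_volume(x)) stop(what, " must be a volume object")
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-8) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

#' Convert voxel indices to world coordinates
#'
#' @param index numeric vector of length 3 or an n x 3 matrix of 0-based
#'   voxel indices (fractional indices allowed, out-of-grid allowed).
#' @param vol a [volume()].
#' @return World coordinates in mm, same shape as `index`.
#' @export
voxel_to_world <- function(index, vol) {
  stopifnot_volume(vol, "vol")
  if (is.matrix(index)) {
    sweep(sweep(index, 2, vol$spacing, `*`), 2, vol$origin, `+`)
  } else {
    vol$origin + as.numeric(index) * vol$spacing
  }
}

#' @rdname voxel_to_world
#' @param point world coordinates in mm (length-3 vector or n x 3 matrix).
#' @export
world_to_voxel <- function(point, vol) {
  stopifnot_volume(vol, "vol")
  if (is.matrix(point)) {
    sweep(sweep(point, 2, vol$origin, `-`), 2, vol$spacing, `/`)
  } else {
    (as.numeric(point) - vol$origin) / vol$spacing
  }
}

#' Binarize a volume at a threshold
#'
#' @param vol a [volume()].
#' @param threshold voxels with value >= `threshold` become foreground.
#' @return A binary `volume`.
#' @export
binarize <- function(vol, threshold) {
  stopifnot_volume(vol, "vol")
  rng <- range(vol$data)
  if (threshold < rng[1] || threshold > rng[2])
    stop("threshold ", threshold, " outside volume intensity range [",
         signif(rng[1], 4), ", ", signif(rng[2], 4), "]")
  volume((vol$data >= threshold) * 1, vol$spacing, vol$origin, kind = "binary")
}

#' Dice overlap coefficient of two binary volumes
#'
#' Computes `2|A n B| / (|A| + |B|)`; equals 1 exactly for identical
#' nonempty masks and 0 for disjoint masks.
#'
#' @param a,b binary volumes on the same grid.
#' @return Dice coefficient in [0, 1].
#' @export
dice <- function(a, b) {
  stopifnot_volume(a, "a"); stopifnot_volume(b, "b")
  if (!identical(dim(a$data), dim(b$data))) stop("dice: grid mismatch")
  sa <- sum(a$data > 0); sb <- sum(b$data > 0)
  if (sa + sb == 0) stop("dice undefined: both masks empty (0/0)")
  2 * sum(a$data > 0 & b$data > 0) / (sa + sb)
}

#' Pearson correlation of two volumes' intensities
#'
#' @param a,b volumes on the same grid.
#' @param mask optional binary volume restricting the computation; when
#'   omitted all voxels are used.
#' @return Pearson correlation coefficient in [-1, 1].
#' @export
intensity_correlation <- function(a, b, mask = NULL) {
  stopifnot_volume(a, "a"); stopifnot_volume(b, "b")
  if (!identical(dim(a$data), dim(b$data)))
    stop("intensity_correlation: grid mismatch")
  va <- as.numeric(a$data); vb <- as.numeric(b$data)
  if (!is.null(mask)) {
    keep <- as.logical(mask$data > 0)
    va <- va[keep]; vb <- vb[keep]
  }
  if (length(va) < 2) stop("need at least 2 voxels")
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("intensity_correlation: zero variance within mask")
  stats::cor(va, vb)
}

#' RMS surface distance between two binary masks
#'
#' Boundary voxels of each mask are extracted (foreground voxels with at
#' least one 6-neighbour in the background) and the root-mean-square
#' Euclidean distance (mm, via distance transform) from each boundary to
#' the other mask's boundary is computed. The symmetrized value (the
#' larger of the two directions) is returned; per-direction values are
#' attached as attribute `"directions"`.
#'
#' @param mask_a,mask_b nonempty binary volumes on the same grid.
#' @return RMS surface distance in mm.
#' @export
surface_rms_distance <- function(mask_a, mask_b) {
  stopifnot_volume(mask_a, "mask_a"); stopifnot_volume(mask_b, "mask_b")
  if (!identical(dim(mask_a$data), dim(mask_b$data)))
    stop("surface_rms_distance: grid mismatch")
  ba <- boundary_mask(mask_a$data)
  bb <- boundary_mask(mask_b$data)
  if (!any(ba) || !any(bb)) stop("surface_rms_distance: empty mask")
  dmn <- dim(mask_a$data)
  db_sq <- cpp_edt_sq(as.numeric(bb), dmn, mask_a$spacing)
  da_sq <- cpp_edt_sq(as.numeric(ba), dmn, mask_a$spacing)
  rms_ab <- sqrt(mean(db_sq[ba]))
  rms_ba <- sqrt(mean(da_sq[bb]))
  structure(max(rms_ab, rms_ba),
            directions = c(a_to_b = rms_ab, b_to_a = rms_ba))
}

boundary_mask <- function(arr) {
  fg <- arr > 0
  d <- dim(arr)
  shift_pad <- function(m, ax, by) {
    # shift logical array, padding with FALSE (outside counts as background)
    out <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[ax]
    if (by == 1) { idx_src[[ax]] <- 1:(n - 1); idx_dst[[ax]] <- 2:n }
    else { idx_src[[ax]] <- 2:n; idx_dst[[ax]] <- 1:(n - 1) }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  interior <- fg
  for (ax in 1:3) for (by in c(-1, 1)) {
    if (d[ax] == 1) { interior[] <- FALSE; next }
    interior <- interior & shift_pad(fg, ax, by)
  }
  fg & !interior
}
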