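#' Construct a landmark set
#'
#' An ordered, named set of 3D points in world coordinates (LPS, mm).
#' The ordering must be identical across every sample in a study.
#'
#' @param names character vector of unique landmark names.
#' @param coords n x 3 numeric matrix of world coordinates (mm).
#' @param missing optional logical vector flagging missing landmarks.
#' @return A tibble of class `landmark_set` with columns
#'   `name`, `x`, `y`, `z` (and `missing` if any are flagged).
#' @export
landmark_set <- function(names, coords, missing = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must have 3 columns")
  names <- as.character(names)
  if (length(names) != nrow(coords))
    stop("length(names) must match nrow(coords)")
  if (anyDuplicated(names)) stop("duplicate landmark names: ",
                                 paste(unique(names[duplicated(names)]),
                                       collapse = ", "))
  if (any(!is.finite(coords))) stop("landmark coordinates must be finite")
  out <- tibble::tibble(name = names,
                        x = as.numeric(coords[, 1]),
                        y = as.numeric(coords[, 2]),
                        z = as.numeric(coords[, 3]))
  if (!is.null(missing)) out$missing <- as.logical(missing)
  class(out) <- c("landmark_set", class(out))
  out
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d landmarks (mm, LPS)\n", nrow(x)))
  NextMethod()
}

lm_coords <- function(lms) {
  as.matrix(lms[, c("x", "y", "z")])
}

lm_replace_coords <- function(lms, coords) {
  landmark_set(lms$name, coords,
               missing = if ("missing" %in% names(lms)) lms$missing else NULL)
}

#' Average several landmark sets pointwise
#'
#' Used e.g. to average repeated manual annotation attempts into a gold
#' standard, or warped template landmarks into an atlas estimate.
#'
#' @param sets list of `landmark_set` objects sharing names and order.
#' @return A `landmark_set` of pointwise mean coordinates.
#' @export
average_landmarks <- function(sets) {
  stopifnot(length(sets) >= 1)
  nm <- sets[[1]]$name
  for (s in sets) {
    if (!identical(s$name, nm))
      stop("landmark sets differ in names or order")
  }
  acc <- Reduce(`+`, lapply(sets, lm_coords)) / length(sets)
  landmark_set(nm, acc)
}

#' Read and write landmark files
#'
#' Supports plain CSV (`name,x,y,z`, world mm, LPS) and 3D Slicer fcsv.
#' fcsv stores points in RAS; on read the x and y coordinates are negated
#' into the internal LPS frame, and on write the conversion is reversed,
#' so write followed by read is the identity on world coordinates. The
#' fcsv comment header is preserved as attribute `"header"`.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"fcsv"`; guessed from the extension when
#'   omitted.
#' @return `read_landmarks` returns a [landmark_set()].
#' @export
read_landmarks <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("landmark file not found: ", path)
  dialect <- dialect %||% guess_lm_dialect(path)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "fcsv") {
    hdr <- lines[startsWith(lines, "#")]
    body <- lines[!startsWith(lines, "#") & nzchar(lines)]
    if (length(body) == 0) stop("no landmark rows in ", path)
    fields <- strsplit(body, ",")
    n_col <- lengths(fields)
    if (any(n_col < 4)) stop("fcsv row with fewer than 4 columns in ", path)
    ras <- t(vapply(fields, function(f) {
      v <- suppressWarnings(as.numeric(f[2:4]))
      if (any(is.na(v))) stop("non-numeric coordinates in ", path)
      v
    }, numeric(3)))
    # Slicer fcsv columns: id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,node
    nm <- vapply(seq_along(fields), function(i) {
      f <- fields[[i]]
      if (length(f) >= 12 && nzchar(f[12])) f[12] else f[1]
    }, character(1))
    lps <- ras
    lps[, 1] <- -lps[, 1]
    lps[, 2] <- -lps[, 2]
    out <- landmark_set(nm, lps)
    attr(out, "header") <- hdr
    out
  } else if (dialect == "csv") {
    body <- lines[nzchar(lines)]
    fields <- strsplit(body, ",")
    if (length(fields) && identical(tolower(trimws(fields[[1]][1])), "name"))
      fields <- fields[-1]
    if (length(fields) == 0) stop("no landmark rows in ", path)
    if (any(lengths(fields) != 4))
      stop("csv landmark rows must have exactly 4 columns (name,x,y,z) in ",
           path)
    nm <- vapply(fields, function(f) trimws(f[1]), character(1))
    xyz <- t(vapply(fields, function(f) {
      v <- suppressWarnings(as.numeric(f[2:4]))
      if (any(is.na(v))) stop("non-numeric coordinates in ", path)
      v
    }, numeric(3)))
    landmark_set(nm, xyz)
  } else stop("unsupported landmark dialect: ", dialect)
}

#' @rdname read_landmarks
#' @param lms a [landmark_set()] to write.
#' @export
write_landmarks <- function(lms, path, dialect = NULL) {
  dialect <- dialect %||% guess_lm_dialect(path)
  if (dialect == "fcsv") {
    hdr <- attr(lms, "header")
    if (is.null(hdr)) {
      hdr <- c("# Markups fiducial file version = 4.11",
               "# CoordinateSystem = RAS",
               "# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID")
    }
    rows <- vapply(seq_len(nrow(lms)), function(i) {
      sprintf("%s,%.9g,%.9g,%.9g,0,0,0,1,1,1,0,%s,,",
              paste0("vtkMRMLMarkupsFiducialNode_", i),
              -lms$x[i], -lms$y[i], lms$z[i], lms$name[i])
    }, character(1))
    writeLines(c(hdr, rows), path)
  } else if (dialect == "csv") {
    rows <- sprintf("%s,%.9g,%.9g,%.9g", lms$name, lms$x, lms$y, lms$z)
    writeLines(c("name,x,y,z", rows), path)
  } else stop("unsupported landmark dialect: ", dialect)
  invisible(path)
}

guess_lm_dialect <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "fcsv") "fcsv" else if (ext == "csv") "csv"
  else stop("cannot guess landmark dialect from extension: ", path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
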