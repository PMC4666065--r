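#' Read and write 3D volumes
#'
#' Supported formats: NRRD (`.nrrd`), NIfTI-1 (`.nii`, `.nii.gz`, via
#' RNifti) and MetaImage (`.mha`, `.mhd`). The internal world frame is
#' LPS in mm; NIfTI (RAS on disk) gets its x/y axes sign-flipped on both
#' read and write so that round trips are the identity on world
#' coordinates. Round trips preserve data, spacing and origin bit-exactly
#' for integer data (and for `double` on-disk types) and to float
#' precision otherwise.
#'
#' @param path file path.
#' @param format one of `"nrrd"`, `"nifti"`, `"metaimage"`; guessed from
#'   the extension when omitted.
#' @return `read_volume` returns a [volume()].
#' @export
read_volume <- function(path, format = NULL) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  format <- format %||% guess_vol_format(path)
  switch(format,
         nrrd = read_nrrd(path),
         nifti = read_nifti_vol(path),
         metaimage = read_metaimage(path),
         stop("unsupported volume format: ", format))
}

#' @rdname read_volume
#' @param vol a [volume()] to write.
#' @param dtype on-disk element type for NRRD/MetaImage: `"double"`,
#'   `"float"`, `"int32"`, `"int16"` or `"uint8"`.
#' @export
write_volume <- function(vol, path, format = NULL, dtype = "double") {
  stopifnot_volume(vol, "vol")
  format <- format %||% guess_vol_format(path)
  switch(format,
         nrrd = write_nrrd(vol, path, dtype),
         nifti = write_nifti_vol(vol, path),
         metaimage = write_metaimage(vol, path, dtype),
         stop("unsupported volume format: ", format))
  invisible(path)
}

guess_vol_format <- function(path) {
  p <- tolower(path)
  if (grepl("\\.(nrrd|nhdr)$", p)) "nrrd"
  else if (grepl("\\.nii(\\.gz)?$", p)) "nifti"
  else if (grepl("\\.(mha|mhd)$", p)) "metaimage"
  else stop("cannot guess volume format from extension: ", path)
}

dtype_info <- function(dtype) {
  switch(dtype,
         uint8 = list(size = 1L, signed = FALSE, what = "integer",
                      nrrd = "uint8", met = "MET_UCHAR"),
         int16 = list(size = 2L, signed = TRUE, what = "integer",
                      nrrd = "int16", met = "MET_SHORT"),
         int32 = list(size = 4L, signed = TRUE, what = "integer",
                      nrrd = "int32", met = "MET_INT"),
         float = list(size = 4L, signed = TRUE, what = "numeric",
                      nrrd = "float", met = "MET_FLOAT"),
         double = list(size = 8L, signed = TRUE, what = "numeric",
                       nrrd = "double", met = "MET_DOUBLE"),
         stop("unsupported dtype: ", dtype))
}

nrrd_type_to_dtype <- function(ty) {
  ty <- tolower(ty)
  map <- c("uchar" = "uint8", "unsigned char" = "uint8", "uint8" = "uint8",
           "uint8_t" = "uint8", "short" = "int16", "short int" = "int16",
           "signed short" = "int16", "int16" = "int16", "int16_t" = "int16",
           "int" = "int32", "signed int" = "int32", "int32" = "int32",
           "int32_t" = "int32", "float" = "float", "double" = "double")
  out <- map[ty]
  if (is.na(out)) stop("unsupported NRRD type: ", ty)
  unname(out)
}

read_bin_data <- function(con_raw, offset, n, info, endian = "little") {
  vals <- readBin(con_raw[(offset + 1):length(con_raw)], info$what, n = n,
                  size = info$size, signed = info$signed, endian = endian)
  if (length(vals) != n) stop("truncated volume data")
  vals
}

# ---- NRRD -----------------------------------------------------------------

read_nrrd <- function(path) {
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  # header ends at the first blank line
  nl <- which(raw_all == as.raw(10L))
  hdr_end <- NA
  prev <- 0L
  for (i in nl) {
    blank <- prev > 0 &&
      (i - prev == 1L || (i - prev == 2L && raw_all[prev + 1] == as.raw(13L)))
    if (blank) { hdr_end <- i; break }
    prev <- i
  }
  if (is.na(hdr_end)) stop("malformed NRRD (no header terminator) in ", path)
  hdr_txt <- rawToChar(raw_all[1:hdr_end])
  lines <- strsplit(hdr_txt, "\r?\n")[[1]]
  if (!grepl("^NRRD", lines[1])) stop("not an NRRD file: ", path)
  lines <- lines[-1]
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexpr(":=?", ln))
    pos <- regexpr(":=?", ln)
    key <- tolower(trimws(substr(ln, 1, pos - 1)))
    val <- trimws(substr(ln, pos + attr(pos, "match.length"), nchar(ln)))
    kv[[key]] <- val
  }
  ndim <- as.integer(kv[["dimension"]])
  if (is.null(ndim) || is.na(ndim) || ndim != 3L)
    stop("not a 3D volume: ", path, " (dimension ", kv[["dimension"]], ")")
  sizes <- as.integer(strsplit(kv[["sizes"]], "\\s+")[[1]])
  dtype <- nrrd_type_to_dtype(kv[["type"]])
  info <- dtype_info(dtype)
  endian <- kv[["endian"]] %||% "little"
  enc <- tolower(kv[["encoding"]] %||% "raw")
  n <- prod(sizes)
  if (enc == "raw") {
    vals <- read_bin_data(raw_all, hdr_end, n, info, endian)
  } else if (enc %in% c("ascii", "text", "txt")) {
    vals <- scan(text = rawToChar(raw_all[(hdr_end + 1):length(raw_all)]),
                 quiet = TRUE)
    if (length(vals) != n) stop("truncated ascii NRRD data in ", path)
  } else if (enc %in% c("gzip", "gz")) {
    dec <- memDecompress(raw_all[(hdr_end + 1):length(raw_all)], type = "gzip")
    vals <- read_bin_data(dec, 0, n, info, endian)
  } else stop("unsupported NRRD encoding: ", enc)
  if (info$what == "integer") vals <- as.integer(vals)
  spacing <- c(1, 1, 1); origin <- c(0, 0, 0)
  if (!is.null(kv[["spacings"]]))
    spacing <- as.numeric(strsplit(kv[["spacings"]], "\\s+")[[1]])
  if (!is.null(kv[["space directions"]])) {
    dirs <- parse_nrrd_vectors(kv[["space directions"]])
    spacing <- vapply(dirs, function(v) sqrt(sum(v^2)), numeric(1))
  }
  if (!is.null(kv[["space origin"]]))
    origin <- parse_nrrd_vectors(kv[["space origin"]])[[1]]
  space <- tolower(kv[["space"]] %||% "left-posterior-superior")
  if (space %in% c("right-anterior-superior", "ras")) {
    origin[1] <- -origin[1]; origin[2] <- -origin[2]
  }
  volume(array(vals, sizes), spacing, origin)
}

parse_nrrd_vectors <- function(s) {
  chunks <- regmatches(s, gregexpr("\\(([^)]*)\\)", s))[[1]]
  lapply(chunks, function(ch)
    as.numeric(strsplit(gsub("[()]", "", ch), ",")[[1]]))
}

write_nrrd <- function(vol, path, dtype = "double", encoding = "raw") {
  info <- dtype_info(dtype)
  hdr <- c("NRRD0004",
           paste0("type: ", info$nrrd),
           "dimension: 3",
           paste0("sizes: ", paste(dim(vol$data), collapse = " ")),
           "space: left-posterior-superior",
           sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
                   vol$spacing[1], vol$spacing[2], vol$spacing[3]),
           sprintf("space origin: (%.17g,%.17g,%.17g)",
                   vol$origin[1], vol$origin[2], vol$origin[3]),
           "endian: little",
           paste0("encoding: ", encoding))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n\n"), con, eos = NULL)
  vals <- as.vector(vol$data)
  if (encoding == "raw") {
    if (info$what == "integer")
      writeBin(as.integer(vals), con, size = info$size, endian = "little")
    else writeBin(as.numeric(vals), con, size = info$size, endian = "little")
  } else if (encoding %in% c("ascii", "text")) {
    writeChar(paste(format(vals, digits = 17, scientific = TRUE),
                    collapse = " "), con, eos = NULL)
  } else stop("unsupported NRRD encoding for writing: ", encoding)
  invisible(path)
}

# ---- NIfTI (via RNifti) ---------------------------------------------------

read_nifti_vol <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("not a 3D volume: ", path, " (",
                            length(d), "D data)")
  x <- RNifti::xform(img)  # voxel -> RAS affine
  spacing <- sqrt(colSums(x[1:3, 1:3]^2))
  origin_ras <- x[1:3, 4]
  origin <- c(-origin_ras[1], -origin_ras[2], origin_ras[3])
  volume(array(as.numeric(img), d), spacing, origin)
}

write_nifti_vol <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  m <- diag(4)
  m[1, 1] <- -vol$spacing[1]
  m[2, 2] <- -vol$spacing[2]
  m[3, 3] <- vol$spacing[3]
  m[1:3, 4] <- c(-vol$origin[1], -vol$origin[2], vol$origin[3])
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

# ---- MetaImage ------------------------------------------------------------

read_metaimage <- function(path) {
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  # header is line-oriented Key = Value until ElementDataFile
  nl <- which(raw_all == as.raw(10L))
  kv <- list(); data_off <- NA; ext_file <- NA
  prev <- 0L
  for (i in nl) {
    ln <- rawToChar(raw_all[(prev + 1):(i - 1)])
    ln <- sub("\r$", "", ln)
    prev <- i
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) next
    key <- trimws(substr(ln, 1, eq - 1))
    val <- trimws(substr(ln, eq + 1, nchar(ln)))
    kv[[key]] <- val
    if (key == "ElementDataFile") {
      if (toupper(val) == "LOCAL") data_off <- i else ext_file <- val
      break
    }
  }
  ndims <- as.integer(kv[["NDims"]] %||% "0")
  if (ndims != 3L) stop("not a 3D volume: ", path, " (NDims ", ndims, ")")
  sizes <- as.integer(strsplit(kv[["DimSize"]], "\\s+")[[1]])
  spacing <- as.numeric(strsplit(kv[["ElementSpacing"]] %||% "1 1 1",
                                 "\\s+")[[1]])
  origin <- as.numeric(strsplit(kv[["Offset"]] %||%
                                  kv[["Origin"]] %||% "0 0 0", "\\s+")[[1]])
  met <- kv[["ElementType"]] %||% "MET_DOUBLE"
  dtype <- switch(met, MET_UCHAR = "uint8", MET_SHORT = "int16",
                  MET_INT = "int32", MET_FLOAT = "float",
                  MET_DOUBLE = "double",
                  stop("unsupported MetaImage ElementType: ", met))
  info <- dtype_info(dtype)
  msb <- identical(toupper(kv[["BinaryDataByteOrderMSB"]] %||% "FALSE"),
                   "TRUE")
  n <- prod(sizes)
  if (!is.na(ext_file)) {
    rp <- file.path(dirname(path), ext_file)
    if (!file.exists(rp)) stop("MetaImage data file not found: ", rp)
    raw_data <- readBin(rp, "raw", n = file.info(rp)$size)
    vals <- read_bin_data(raw_data, 0, n, info,
                          if (msb) "big" else "little")
  } else {
    vals <- read_bin_data(raw_all, data_off, n, info,
                          if (msb) "big" else "little")
  }
  volume(array(vals, sizes), spacing, origin)
}

write_metaimage <- function(vol, path, dtype = "double") {
  info <- dtype_info(dtype)
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           paste0("DimSize = ", paste(dim(vol$data), collapse = " ")),
           paste0("ElementSpacing = ",
                  paste(format(vol$spacing, digits = 17), collapse = " ")),
           paste0("Offset = ",
                  paste(format(vol$origin, digits = 17), collapse = " ")),
           paste0("ElementType = ", info$met),
           "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  vals <- as.vector(vol$data)
  if (info$what == "integer")
    writeBin(as.integer(vals), con, size = info$size, endian = "little")
  else writeBin(as.numeric(vals), con, size = info$size, endian = "little")
  invisible(path)
}
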