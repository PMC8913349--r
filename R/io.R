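#' Read a 3D image volume
#'
#' Supports NIfTI (.nii, .nii.gz) via the RNifti library and uncompressed
#' MetaImage (.mha, .mhd + .raw).  Spacing, origin and direction are taken
#' from the header.  If the stored direction matrix has negative determinant
#' the third axis is flipped (values reversed, origin moved) so that the
#' returned grid satisfies the det = +1 invariant without changing any
#' voxel's physical position.
#'
#' @param path file path.
#' @return a \code{voxel_grid}.
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    stop(sprintf("image file does not exist: %s", path))
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    read_nifti_grid(path)
  } else if (grepl("\\.(mha|mhd)$", path, ignore.case = TRUE)) {
    read_metaimage(path)
  } else {
    stop(sprintf("unsupported image format (expected .nii/.nii.gz/.mha/.mhd): %s",
                 path))
  }
}

#' Write a 3D image volume
#'
#' Format chosen from the extension: NIfTI for .nii/.nii.gz, MetaImage for
#' .mha (raw data embedded) or .mhd (raw data in a sibling .raw file).
#' Values are stored as 64-bit floats so write-then-read round-trips are
#' bitwise exact.
#'
#' @param grid a \code{voxel_grid}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_image <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    write_nifti_grid(grid, path)
  } else if (grepl("\\.(mha|mhd)$", path, ignore.case = TRUE)) {
    write_metaimage(grid, path)
  } else {
    stop(sprintf("unsupported image format (expected .nii/.nii.gz/.mha/.mhd): %s",
                 path))
  }
  invisible(path)
}

read_nifti_grid <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop(sprintf("failed to read NIfTI file %s: %s",
                                 path, conditionMessage(e))))
  x <- RNifti::xform(img)
  vals <- as.array(img)
  attributes(vals) <- list(dim = dim(vals))  # drop niftiImage attributes
  storage.mode(vals) <- "double"
  if (length(dim(vals)) == 2L) dim(vals) <- c(dim(vals), 1L)
  if (length(dim(vals)) != 3L)
    stop(sprintf("expected a 3D volume in %s (got %d dims)",
                 path, length(dim(vals))))
  M <- x[1:3, 1:3]
  spacing <- sqrt(colSums(M^2))
  if (any(spacing <= 0)) stop(sprintf("degenerate spacing in %s", path))
  direction <- sweep(M, 2, spacing, "/")
  origin <- x[1:3, 4]
  if (det(direction) < 0) {
    # flip axis 3 to restore a right-handed frame
    d <- dim(vals)
    vals <- vals[, , rev(seq_len(d[3])), drop = FALSE]
    origin <- origin + direction[, 3] * spacing[3] * (d[3] - 1)
    direction[, 3] <- -direction[, 3]
  }
  voxel_grid(vals, spacing, origin, direction)
}

write_nifti_grid <- function(grid, path) {
  img <- RNifti::asNifti(grid$values)
  RNifti::pixdim(img) <- grid$spacing
  m <- diag(4)
  m[1:3, 1:3] <- grid$direction %*% diag(grid$spacing)
  m[1:3, 4] <- grid$origin
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
}

.met_types <- list(
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_UINT   = list(what = "integer", size = 4L, signed = TRUE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT  = list(what = "numeric", size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "numeric", size = 8L, signed = TRUE))

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0)
      stop(sprintf("truncated MetaImage header in %s", path))
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3)
      stop(sprintf("malformed MetaImage header line in %s: '%s'", path, line))
    hdr[[kv[2]]] <- trimws(kv[3])
    if (kv[2] == "ElementDataFile") break
  }
  if (!is.null(hdr$CompressedData) && toupper(hdr$CompressedData) == "TRUE")
    stop(sprintf("compressed MetaImage data is not supported: %s", path))
  if (!is.null(hdr$BinaryDataByteOrderMSB) &&
      toupper(hdr$BinaryDataByteOrderMSB) == "TRUE")
    stop(sprintf("big-endian MetaImage data is not supported: %s", path))
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  if (length(dims) != 3) stop(sprintf("expected 3D MetaImage in %s", path))
  spacing <- as.numeric(strsplit(hdr$ElementSpacing %||% "1 1 1", "\\s+")[[1]])
  origin <- as.numeric(strsplit(hdr$Offset %||% "0 0 0", "\\s+")[[1]])
  tm <- as.numeric(strsplit(hdr$TransformMatrix %||%
                              "1 0 0 0 1 0 0 0 1", "\\s+")[[1]])
  direction <- matrix(tm, 3, 3, byrow = TRUE)
  ty <- .met_types[[hdr$ElementType %||% "MET_DOUBLE"]]
  if (is.null(ty))
    stop(sprintf("unsupported MetaImage ElementType '%s' in %s",
                 hdr$ElementType, path))
  n <- prod(dims)
  if (hdr$ElementDataFile == "LOCAL") {
    raw <- readBin(con, what = ty$what, n = n, size = ty$size,
                   signed = ty$signed, endian = "little")
  } else {
    rawpath <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(rawpath))
      stop(sprintf("MetaImage data file not found: %s", rawpath))
    rcon <- file(rawpath, "rb")
    on.exit(close(rcon), add = TRUE)
    raw <- readBin(rcon, what = ty$what, n = n, size = ty$size,
                   signed = ty$signed, endian = "little")
  }
  if (length(raw) != n)
    stop(sprintf("truncated MetaImage data in %s: expected %d values, got %d",
                 path, n, length(raw)))
  vals <- array(as.double(raw), dim = dims)
  if (det(direction) < 0) {
    vals <- vals[, , rev(seq_len(dims[3])), drop = FALSE]
    origin <- origin + direction[, 3] * spacing[3] * (dims[3] - 1)
    direction[, 3] <- -direction[, 3]
  }
  voxel_grid(vals, spacing, origin, direction)
}

write_metaimage <- function(grid, path) {
  local <- grepl("\\.mha$", path, ignore.case = TRUE)
  datafile <- if (local) "LOCAL" else
    paste0(sub("\\.mhd$", "", basename(path), ignore.case = TRUE), ".raw")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("TransformMatrix =",
          paste(format(t(grid$direction), digits = 17), collapse = " ")),
    paste("Offset =", paste(format(grid$origin, digits = 17), collapse = " ")),
    paste("ElementSpacing =",
          paste(format(grid$spacing, digits = 17), collapse = " ")),
    paste("DimSize =", paste(dim(grid$values), collapse = " ")),
    "ElementType = MET_DOUBLE",
    paste("ElementDataFile =", datafile))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (local) {
    writeBin(as.vector(grid$values), con, size = 8L, endian = "little")
  } else {
    rcon <- file(file.path(dirname(path), datafile), "wb")
    on.exit(close(rcon), add = TRUE)
    writeBin(as.vector(grid$values), rcon, size = 8L, endian = "little")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
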