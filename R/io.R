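formatOf <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) return("nifti")
  if (grepl("\\.mha$", lower)) return("mha")
  if (grepl("\\.mhd$", lower)) return("mhd")
  stop("unsupported image format for '", path,
       "' (expected .nii, .nii.gz, .mha or .mhd)")
}

# Extract an axis-aligned geometry from a NIfTI xform; oblique grids are
# rejected rather than silently mishandled.
niftiGeometry <- function(img, path) {
  d <- dim(img)
  if (length(d) != 3L)
    stop("'", path, "' is not a 3-D volume (found ", length(d),
         " dimensions)")
  xf <- RNifti::xform(img)
  code <- attr(xf, "code")
  if (is.null(code) || code == 0L) {
    sp <- RNifti::pixdim(img)
    return(GridGeometry(d, spacing = sp, origin = c(0, 0, 0)))
  }
  rot <- xf[1:3, 1:3]
  sp <- sqrt(colSums(rot^2))
  offdiag <- rot - diag(diag(rot))
  if (any(abs(offdiag) > 1e-4 * max(sp)))
    stop("'", path, "' has an oblique orientation; only axis-aligned ",
         "grids are supported")
  if (any(diag(rot) <= 0))
    stop("'", path, "' has a flipped axis orientation; only grids with ",
         "positive axis-aligned direction cosines are supported")
  GridGeometry(d, spacing = diag(rot), origin = xf[1:3, 4])
}

writeNiftiVolume <- function(arr, geometry, path, datatype) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- geometry@spacing
  aff <- diag(c(geometry@spacing, 1))
  aff[1:3, 4] <- geometry@origin
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

metaElementTypes <- c(MET_UCHAR = "uchar", MET_CHAR = "char",
                      MET_SHORT = "short", MET_USHORT = "ushort",
                      MET_INT = "int", MET_FLOAT = "float",
                      MET_DOUBLE = "double")

readMetaHeader <- function(raw, path) {
  # header is ASCII key = value lines terminated by the ElementDataFile line
  marker <- charToRaw("ElementDataFile")
  pos <- NA_integer_
  limit <- min(length(raw), 65536L)
  for (i in seq_len(limit - length(marker) + 1L)) {
    if (raw[i] == marker[1L] &&
        identical(raw[i:(i + length(marker) - 1L)], marker)) {
      pos <- i
      break
    }
  }
  if (is.na(pos))
    stop("'", path, "': no ElementDataFile entry; not a MetaImage header")
  nl <- pos
  while (nl <= length(raw) && raw[nl] != as.raw(10L)) nl <- nl + 1L
  header <- strsplit(rawToChar(raw[1:(nl - 1L)]), "\n", fixed = TRUE)[[1]]
  kv <- list()
  for (line in header) {
    parts <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(parts) >= 2L)
      kv[[trimws(parts[1])]] <- trimws(paste(parts[-1], collapse = "="))
  }
  list(fields = kv, dataOffset = nl)
}

readMetaImage <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  hd <- readMetaHeader(raw, path)
  kv <- hd$fields
  ndims <- as.integer(kv[["NDims"]])
  if (is.na(ndims) || ndims != 3L)
    stop("'", path, "' is not a 3-D volume (NDims = ", kv[["NDims"]], ")")
  if (!is.null(kv[["CompressedData"]]) &&
      tolower(kv[["CompressedData"]]) == "true")
    stop("'", path, "': compressed MetaImage data is not supported")
  if (!is.null(kv[["BinaryDataByteOrderMSB"]]) &&
      tolower(kv[["BinaryDataByteOrderMSB"]]) == "true")
    stop("'", path, "': big-endian MetaImage data is not supported")
  tm <- kv[["TransformMatrix"]]
  if (!is.null(tm)) {
    m <- matrix(as.numeric(strsplit(tm, "\\s+")[[1]]), 3, 3, byrow = TRUE)
    if (max(abs(m - diag(3))) > 1e-4)
      stop("'", path, "' has a non-identity TransformMatrix; only ",
           "axis-aligned grids are supported")
  }
  dims <- as.integer(strsplit(kv[["DimSize"]], "\\s+")[[1]])
  sp <- if (!is.null(kv[["ElementSpacing"]]))
    as.numeric(strsplit(kv[["ElementSpacing"]], "\\s+")[[1]]) else c(1, 1, 1)
  org <- if (!is.null(kv[["Offset"]]))
    as.numeric(strsplit(kv[["Offset"]], "\\s+")[[1]]) else c(0, 0, 0)
  et <- kv[["ElementType"]]
  if (is.null(et) || !(et %in% names(metaElementTypes)))
    stop("'", path, "': unsupported ElementType '", et, "'")
  n <- prod(dims)
  datafile <- kv[["ElementDataFile"]]
  if (identical(datafile, "LOCAL")) {
    payload <- raw[(hd$dataOffset + 1L):length(raw)]
  } else {
    rawpath <- file.path(dirname(path), datafile)
    if (!file.exists(rawpath))
      stop("'", path, "': ElementDataFile '", datafile, "' not found")
    payload <- readBin(rawpath, "raw", n = file.size(rawpath))
  }
  con <- rawConnection(payload, "rb")
  on.exit(close(con))
  vals <- switch(et,
    MET_UCHAR  = as.double(readBin(con, "integer", n, size = 1,
                                   signed = FALSE)),
    MET_CHAR   = as.double(readBin(con, "integer", n, size = 1,
                                   signed = TRUE)),
    MET_SHORT  = as.double(readBin(con, "integer", n, size = 2,
                                   signed = TRUE, endian = "little")),
    MET_USHORT = as.double(readBin(con, "integer", n, size = 2,
                                   signed = FALSE, endian = "little")),
    MET_INT    = as.double(readBin(con, "integer", n, size = 4,
                                   endian = "little")),
    MET_FLOAT  = readBin(con, "numeric", n, size = 4, endian = "little"),
    MET_DOUBLE = readBin(con, "numeric", n, size = 8, endian = "little"))
  if (length(vals) != n)
    stop("'", path, "': truncated MetaImage data block")
  list(array = array(vals, dims), geometry = GridGeometry(dims, sp, org))
}

writeMetaImage <- function(arr, geometry, path, elementType) {
  fmt <- formatOf(path)
  local_mha <- fmt == "mha"
  datafile <- if (local_mha) "LOCAL"
              else paste0(tools::file_path_sans_ext(basename(path)), ".raw")
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    paste("Offset =", paste(format(geometry@origin, digits = 17),
                            collapse = " ")),
    paste("ElementSpacing =", paste(format(geometry@spacing, digits = 17),
                                    collapse = " ")),
    paste("DimSize =", paste(geometry@shape, collapse = " ")),
    paste("ElementType =", elementType),
    paste("ElementDataFile =", datafile))
  vals <- as.vector(arr)
  payload <- switch(elementType,
    MET_UCHAR = writeBin(as.raw(as.integer(vals)), raw()),
    MET_FLOAT = writeBin(as.numeric(vals), raw(), size = 4,
                         endian = "little"),
    stop("unsupported MetaImage write type ", elementType))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(paste(header, collapse = "\n"), "\n"), con,
            eos = NULL)
  if (local_mha) {
    writeBin(payload, con)
  } else {
    rawcon <- file(file.path(dirname(path), datafile), "wb")
    writeBin(payload, rawcon)
    close(rawcon)
  }
  invisible(path)
}

readVolumeArray <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  fmt <- formatOf(path)
  if (fmt == "nifti") {
    img <- RNifti::readNifti(path)
    geom <- niftiGeometry(img, path)
    list(array = array(as.numeric(img), dim(img)), geometry = geom)
  } else {
    readMetaImage(path)
  }
}

#' Read a 3-D image volume
#'
#' Reads NIfTI-1 (\code{.nii}, \code{.nii.gz}) or MetaImage (\code{.mha},
#' \code{.mhd} + \code{.raw}) files. Geometry (spacing, origin) is taken
#' from the header; spacing is interpreted as mm. Oblique grids and
#' non-3-D data are rejected with a format error naming the file.
#'
#' @param path path to the image file
#' @return an \linkS4class{ImageVolume}
#' @seealso [writeImageVolume()], [readMask()]
#' @export
readImageVolume <- function(path) {
  v <- readVolumeArray(path)
  ImageVolume(v$array, v$geometry)
}

#' Write a 3-D image volume
#'
#' Images are stored as 32-bit float. \code{.nii.gz} output is
#' gzip-compressed. The written file reads back with identical geometry
#' and intensities within float32 precision.
#'
#' @param vol an \linkS4class{ImageVolume}
#' @param path output path (\code{.nii}, \code{.nii.gz}, \code{.mha},
#'   \code{.mhd})
#' @return the path, invisibly
#' @export
writeImageVolume <- function(vol, path) {
  stopifnot(is(vol, "ImageVolume"))
  if (!dir.exists(dirname(path)))
    stop("cannot write '", path, "': directory does not exist")
  fmt <- formatOf(path)
  if (fmt == "nifti")
    writeNiftiVolume(vol@intensities, vol@geometry, path, "float")
  else
    writeMetaImage(vol@intensities, vol@geometry, path, "MET_FLOAT")
  invisible(path)
}

#' Read a binary structure mask
#'
#' Reads a label volume and converts it to a \linkS4class{BinaryMask}.
#' A single nonzero label value (any value) is accepted as foreground.
#' If the file contains several distinct nonzero labels, \code{label}
#' selects which one becomes foreground; omitting it is an error.
#'
#' @param path path to the label volume
#' @param label optional numeric label to select when the file is
#'   multi-label
#' @return a \linkS4class{BinaryMask}
#' @export
readMask <- function(path, label = NULL) {
  v <- readVolumeArray(path)
  vals <- round(v$array)
  if (max(abs(v$array - vals)) > 1e-6)
    stop("'", path, "' contains non-integer values; not a label volume")
  labels <- sort(unique(vals[vals != 0]))
  if (is.null(label)) {
    if (length(labels) > 1L)
      stop("'", path, "' contains multiple labels (",
           paste(labels, collapse = ", "),
           "); pass 'label' to select one")
    membership <- vals != 0
  } else {
    membership <- vals == label
  }
  BinaryMask(array(membership, dim(vals)), v$geometry)
}

#' Write a binary structure mask
#'
#' Masks are stored as unsigned 8-bit volumes with 0 = background and
#' 1 = member, for maximal interoperability; the round trip through
#' [readMask()] is voxel-exact.
#'
#' @param mask a \linkS4class{BinaryMask}
#' @param path output path (\code{.nii}, \code{.nii.gz}, \code{.mha},
#'   \code{.mhd})
#' @return the path, invisibly
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "BinaryMask"))
  if (!dir.exists(dirname(path)))
    stop("cannot write '", path, "': directory does not exist")
  arr <- array(as.integer(mask@membership), dim(mask@membership))
  fmt <- formatOf(path)
  if (fmt == "nifti")
    writeNiftiVolume(arr, mask@geometry, path, "uint8")
  else
    writeMetaImage(arr, mask@geometry, path, "MET_UCHAR")
  invisible(path)
}

#' Write a signed distance map for inspection
#'
#' @param sdm a \linkS4class{SignedDistanceMap}
#' @param path output path
#' @return the path, invisibly
#' @export
writeDistanceMap <- function(sdm, path) {
  stopifnot(is(sdm, "SignedDistanceMap"))
  fmt <- formatOf(path)
  if (fmt == "nifti")
    writeNiftiVolume(sdm@values, sdm@geometry, path, "float")
  else
    writeMetaImage(sdm@values, sdm@geometry, path, "MET_FLOAT")
  invisible(path)
}
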