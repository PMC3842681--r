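#' Construct a GridGeometry
#'
#' @param shape integer vector of length 3, voxels per axis
#' @param spacing numeric length 3 (or scalar, recycled), voxel spacing mm
#' @param origin numeric length 3 (or scalar), world position of the first
#'   voxel centre, mm
#' @return a \linkS4class{GridGeometry}
#' @examples
#' GridGeometry(c(64, 64, 64), spacing = c(1, 1, 2))
#' @export
GridGeometry <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("GridGeometry",
      shape = as.integer(rep_len(shape, 3L)),
      spacing = as.numeric(rep_len(spacing, 3L)),
      origin = as.numeric(rep_len(origin, 3L)))
}

#' Construct an ImageVolume
#'
#' @param intensities 3-D numeric array of finite intensities
#' @param geometry a \linkS4class{GridGeometry}; defaults to unit spacing at
#'   the world origin
#' @return an \linkS4class{ImageVolume}
#' @export
ImageVolume <- function(intensities, geometry = NULL) {
  intensities <- as.array(intensities)
  storage.mode(intensities) <- "double"
  if (is.null(geometry)) geometry <- GridGeometry(dim(intensities))
  new("ImageVolume", geometry = geometry, intensities = intensities)
}

#' Construct a BinaryMask
#'
#' @param membership 3-D logical (or coercible 0/1) array
#' @param geometry a \linkS4class{GridGeometry}; defaults to unit spacing
#' @return a \linkS4class{BinaryMask}
#' @export
BinaryMask <- function(membership, geometry = NULL) {
  membership <- as.array(membership)
  storage.mode(membership) <- "logical"
  if (is.null(geometry)) geometry <- GridGeometry(dim(membership))
  new("BinaryMask", geometry = geometry, membership = membership)
}

#' Construct a SignedDistanceMap
#'
#' @param values 3-D numeric array of signed distances, mm
#' @param geometry a \linkS4class{GridGeometry}
#' @return a \linkS4class{SignedDistanceMap}
#' @export
SignedDistanceMap <- function(values, geometry = NULL) {
  values <- as.array(values)
  storage.mode(values) <- "double"
  if (is.null(geometry)) geometry <- GridGeometry(dim(values))
  new("SignedDistanceMap", geometry = geometry, values = values)
}

#' Construct an AtlasProposal
#'
#' @param atlasId single string
#' @param image deformed atlas \linkS4class{ImageVolume}
#' @param mask deformed structure \linkS4class{BinaryMask}
#' @return an \linkS4class{AtlasProposal}
#' @export
AtlasProposal <- function(atlasId, image, mask) {
  if (!any(mask@membership))
    warning("proposal '", atlasId, "' has an empty mask; it cannot be ",
            "fused")
  new("AtlasProposal", atlasId = as.character(atlasId), image = image,
      mask = mask)
}

#' Compare two grid geometries within tolerance
#'
#' Shapes must be identical; spacing and origin components must agree
#' within \code{tol} mm.
#'
#' @param a,b \linkS4class{GridGeometry} objects
#' @param tol tolerance in mm for spacing and origin
#' @return logical
#' @export
sameGeometry <- function(a, b, tol = 1e-4) {
  identical(a@shape, b@shape) &&
    all(abs(a@spacing - b@spacing) <= tol) &&
    all(abs(a@origin - b@origin) <= tol)
}

#' Assert that objects share a common grid
#'
#' Fusion and evaluation require every volume on the target grid; this
#' checks all geometries against the first and names the first offender.
#'
#' @param items non-empty list of geometry-bearing objects
#'   (\linkS4class{GridVolume}s, \linkS4class{AtlasProposal}s,
#'   \linkS4class{GridGeometry}s)
#' @param tol tolerance in mm for spacing and origin (default 1e-4)
#' @return invisibly \code{TRUE}; raises an error on mismatch
#' @export
assertCommonGrid <- function(items, tol = 1e-4) {
  if (length(items) == 0L) stop("assertCommonGrid: empty list")
  geoms <- lapply(items, function(x)
    if (is(x, "GridGeometry")) x else geometry(x))
  ref <- geoms[[1L]]
  for (i in seq_along(geoms)[-1L]) {
    if (!sameGeometry(ref, geoms[[i]], tol = tol)) {
      nm <- names(items)[i]
      label <- if (!is.null(nm) && nzchar(nm)) nm else paste0("item ", i)
      stop("grid mismatch: ", label,
           " is not on the common grid (shape/spacing/origin differ ",
           "beyond ", tol, " mm)")
    }
  }
  invisible(TRUE)
}

# World coordinates (mm) of every voxel centre, as three vectors in array
# (column-major) order.
voxelCenters <- function(geometry) {
  sh <- geometry@shape
  idx <- arrayInd(seq_len(prod(sh)), sh)
  list(x = geometry@origin[1] + (idx[, 1] - 1) * geometry@spacing[1],
       y = geometry@origin[2] + (idx[, 2] - 1) * geometry@spacing[2],
       z = geometry@origin[3] + (idx[, 3] - 1) * geometry@spacing[3])
}

# Length of the grid diagonal in mm (bound on any voxel-centre distance).
gridDiagonal <- function(geometry) {
  sqrt(sum(((geometry@shape - 1L) * geometry@spacing)^2))
}
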