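#' @useDynLib AtlasFuse, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject is slot setValidity show
#' @importFrom stats rnorm runif pnorm median sd cor
#' @importFrom utils write.csv read.csv packageVersion
NULL

#' GridGeometry: the physical layout of a voxel grid
#'
#' Describes a 3-D axis-aligned voxel grid: the number of voxels per axis,
#' the physical voxel spacing in mm, and the world position (mm) of the
#' centre of the first voxel. Index \code{(i, j, k)} (1-based) maps to the
#' world position \code{origin + (c(i, j, k) - 1) * spacing}. Oblique
#' (rotated) grids are not representable and are rejected at read time.
#'
#' @slot shape integer vector of length 3, voxels per axis (each >= 1)
#' @slot spacing numeric vector of length 3, voxel spacing in mm (each > 0)
#' @slot origin numeric vector of length 3, world position of the first
#'   voxel centre in mm
#' @export
setClass("GridGeometry",
  representation(shape = "integer", spacing = "numeric", origin = "numeric"))

setValidity("GridGeometry", function(object) {
  msgs <- character()
  if (length(object@shape) != 3L || anyNA(object@shape))
    msgs <- c(msgs, "shape must be an integer vector of length 3")
  else if (any(object@shape < 1L))
    msgs <- c(msgs, "all shape components must be >= 1")
  if (length(object@spacing) != 3L || anyNA(object@spacing))
    msgs <- c(msgs, "spacing must be a numeric vector of length 3")
  else if (any(object@spacing <= 0))
    msgs <- c(msgs, "all spacing components must be > 0 mm")
  if (length(object@origin) != 3L || anyNA(object@origin))
    msgs <- c(msgs, "origin must be a numeric vector of length 3")
  if (length(msgs)) msgs else TRUE
})

#' Virtual parent of all grid-attached volumes
#'
#' @slot geometry a \linkS4class{GridGeometry}
#' @keywords internal
#' @export
setClass("GridVolume", representation("VIRTUAL", geometry = "GridGeometry"))

#' ImageVolume: a 3-D scalar intensity volume
#'
#' Holds a grayscale image (the target patient image or a deformed atlas
#' image) as a 3-D array of finite intensities on a \linkS4class{GridGeometry}.
#'
#' @slot geometry a \linkS4class{GridGeometry}
#' @slot intensities 3-D numeric array matching \code{gridShape(geometry)}
#' @export
setClass("ImageVolume", contains = "GridVolume",
  representation(intensities = "array"))

setValidity("ImageVolume", function(object) {
  if (!identical(dim(object@intensities), as.integer(object@geometry@shape)))
    return("intensity array dimensions do not match the grid shape")
  if (!all(is.finite(object@intensities)))
    return("all intensities must be finite")
  TRUE
})

#' BinaryMask: a 3-D structure segmentation
#'
#' A boolean membership grid on the same geometry as the images it
#' annotates: manual delineations, deformed atlas proposals, and fused
#' segmentations are all BinaryMasks.
#'
#' @slot geometry a \linkS4class{GridGeometry}
#' @slot membership 3-D logical array matching \code{gridShape(geometry)}
#' @export
setClass("BinaryMask", contains = "GridVolume",
  representation(membership = "array"))

setValidity("BinaryMask", function(object) {
  if (!is.logical(object@membership))
    return("membership must be a logical array")
  if (!identical(dim(object@membership), as.integer(object@geometry@shape)))
    return("membership array dimensions do not match the grid shape")
  if (anyNA(object@membership))
    return("membership must not contain NA")
  TRUE
})

#' SignedDistanceMap: per-voxel signed distance to a structure surface
#'
#' The fusion substrate: each voxel stores the signed Euclidean distance in
#' mm from its centre to the nearest voxel centre across the structure
#' boundary. The sign convention is negative strictly inside the structure
#' and positive strictly outside, so thresholding at \code{< 0} recovers
#' the mask.
#'
#' @slot geometry a \linkS4class{GridGeometry}
#' @slot values 3-D numeric array of signed distances in mm
#' @export
setClass("SignedDistanceMap", contains = "GridVolume",
  representation(values = "array"))

setValidity("SignedDistanceMap", function(object) {
  if (!identical(dim(object@values), as.integer(object@geometry@shape)))
    return("distance array dimensions do not match the grid shape")
  TRUE
})

#' AtlasProposal: one deformed atlas (image + structure mask)
#'
#' The unit of input to fusion: a single atlas's image and structure
#' segmentation after deformable registration onto the target grid.
#'
#' @slot atlasId single string identifying the atlas
#' @slot image the deformed atlas \linkS4class{ImageVolume}
#' @slot mask the deformed structure \linkS4class{BinaryMask}
#' @export
setClass("AtlasProposal",
  representation(atlasId = "character", image = "ImageVolume",
                 mask = "BinaryMask"))

setValidity("AtlasProposal", function(object) {
  if (length(object@atlasId) != 1L || is.na(object@atlasId))
    return("atlasId must be a single string")
  if (!sameGeometry(object@image@geometry, object@mask@geometry))
    return("proposal image and mask must share one grid geometry")
  TRUE
})

#' SimilarityScore: per-atlas registration-success score
#'
#' Records the normalized cross-correlation between the target image and
#' one deformed atlas image, evaluated over that atlas's deformed structure
#' dilated by a physical margin.
#'
#' @slot atlasId single string
#' @slot ncc Pearson-type NCC in [-1, 1]
#' @slot roiVoxelCount number of voxels in the dilated ROI (>= 2)
#' @slot marginMm the dilation margin used, mm
#' @export
setClass("SimilarityScore",
  representation(atlasId = "character", ncc = "numeric",
                 roiVoxelCount = "integer", marginMm = "numeric"))

setValidity("SimilarityScore", function(object) {
  if (!is.finite(object@ncc) || object@ncc < -1 - 1e-12 ||
      object@ncc > 1 + 1e-12)
    return("ncc must lie in [-1, 1]")
  if (object@roiVoxelCount < 2L)
    return("roiVoxelCount must be >= 2")
  if (object@marginMm < 0)
    return("marginMm must be non-negative")
  TRUE
})

#' PWFConfig: parameters of probabilistic weighting fusion
#'
#' \code{kOverS} is the single parameter of the weighting model: the ratio
#' of the proportionality of segmentation quality to image-registration
#' quality (k) to the expected spread of segmentation quality (s). Zero
#' yields equal, unbiased weights; very large values select the single most
#' similar registration. Only the ratio enters the model, never k or s
#' individually. Defaults: 0.5 (suited to head-and-neck-like settings, the
#' package default) with 20 documented for prostate-like settings.
#'
#' @slot kOverS non-negative finite real
#' @slot quadratureNodes integer >= 32, Gauss-Hermite nodes for the weight
#'   integral
#' @slot marginMm non-negative dilation margin in mm for the NCC ROI
#' @export
setClass("PWFConfig",
  representation(kOverS = "numeric", quadratureNodes = "integer",
                 marginMm = "numeric"))

setValidity("PWFConfig", function(object) {
  if (!is.finite(object@kOverS) || object@kOverS < 0)
    return("kOverS must be finite and >= 0")
  if (object@quadratureNodes < 32L)
    return("quadratureNodes must be >= 32")
  if (!is.finite(object@marginMm) || object@marginMm < 0)
    return("marginMm must be finite and >= 0")
  TRUE
})

#' FusionResult: the output record of a PWF run
#'
#' @slot fusedMask the fused \linkS4class{BinaryMask}
#' @slot weights per-atlas fusion weights (non-negative, sum to 1)
#' @slot similarities data.frame with one row per atlas: atlas_id, ncc,
#'   roi_voxel_count, margin_mm
#' @slot config the \linkS4class{PWFConfig} used
#' @export
setClass("FusionResult",
  representation(fusedMask = "BinaryMask", weights = "numeric",
                 similarities = "data.frame", config = "PWFConfig"))

setValidity("FusionResult", function(object) {
  w <- object@weights
  if (any(w < -1e-12)) return("weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-9) return("weights must sum to 1 within 1e-9")
  if (length(w) != nrow(object@similarities))
    return("one weight and one similarity row per proposal required")
  TRUE
})

#' PhantomSpec: recipe for a synthetic target image and ground-truth mask
#'
#' The phantom emulates a CT neighbourhood of an elongated lymph-node-like
#' structure: a union of 1-3 ellipsoids rasterized by the voxel-centre
#' rule, painted with a constant contrast over a spatially correlated
#' background texture plus white observation noise.
#'
#' @slot shape integer grid shape (default 64^3)
#' @slot spacing voxel spacing mm
#' @slot ellipsoids list of lists with elements \code{center} (mm) and
#'   \code{semiaxes} (mm)
#' @slot contrast structure-minus-background intensity difference
#' @slot textureAmplitude standard deviation of the correlated background
#' @slot textureLengthMm correlation length of the background texture, mm
#' @slot noiseSigma white observation-noise standard deviation
#' @slot seed integer RNG seed (NA = use the current RNG state)
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", spacing = "numeric",
                 ellipsoids = "list", contrast = "numeric",
                 textureAmplitude = "numeric", textureLengthMm = "numeric",
                 noiseSigma = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (length(object@ellipsoids) < 1L || length(object@ellipsoids) > 3L)
    return("structure must be a union of 1-3 ellipsoids")
  for (e in object@ellipsoids) {
    if (!all(c("center", "semiaxes") %in% names(e)))
      return("each ellipsoid needs 'center' and 'semiaxes'")
    if (any(e$semiaxes <= 0)) return("all semi-axes must be > 0")
  }
  extent <- (object@shape - 1L) * object@spacing
  for (e in object@ellipsoids) {
    if (any(e$center - e$semiaxes < 5) ||
        any(e$center + e$semiaxes > extent - 5))
      return("structure must fit inside the grid with >= 5 mm clearance")
  }
  TRUE
})

#' DeformationSpec: recipe for a smooth random displacement field
#'
#' Emulates the output of B-spline deformable registration as a forward
#' generator: i.i.d. normal control-point displacements on a coarse lattice,
#' interpolated to the voxel grid, yielding a smooth field whose magnitude
#' is controlled by \code{displacementSigma}.
#'
#' @slot controlPointSpacingMm coarse lattice spacing, mm (default 16)
#' @slot displacementSigma per-axis standard deviation of control-point
#'   displacements, mm (scalar recycled to 3)
#' @slot intensityNoiseSigma white noise added to the warped image
#' @slot seed integer RNG seed (NA = use the current RNG state)
#' @export
setClass("DeformationSpec",
  representation(controlPointSpacingMm = "numeric",
                 displacementSigma = "numeric",
                 intensityNoiseSigma = "numeric", seed = "integer"))

setValidity("DeformationSpec", function(object) {
  if (any(object@displacementSigma < 0))
    return("displacementSigma must be >= 0")
  if (object@intensityNoiseSigma < 0)
    return("intensityNoiseSigma must be >= 0")
  if (object@controlPointSpacingMm <= 0)
    return("controlPointSpacingMm must be > 0")
  TRUE
})

#' DisplacementField: a dense per-voxel displacement in mm
#'
#' @slot geometry the voxel grid the field lives on
#' @slot displacements 4-D numeric array \code{c(shape, 3)}, mm per axis
#' @export
setClass("DisplacementField",
  representation(geometry = "GridGeometry", displacements = "array"))

setValidity("DisplacementField", function(object) {
  if (!identical(dim(object@displacements),
                 c(as.integer(object@geometry@shape), 3L)))
    return("displacement array must have dimensions c(shape, 3)")
  TRUE
})
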