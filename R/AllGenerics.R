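#' @name AtlasFuse-accessors
#' @title Accessors for AtlasFuse objects
#'
#' @description Slot access goes through these accessors; slots are an
#' implementation detail.
#'
#' @param x an AtlasFuse object
#' @return the requested component
NULL

#' @rdname AtlasFuse-accessors
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' @rdname AtlasFuse-accessors
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))

#' @rdname AtlasFuse-accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname AtlasFuse-accessors
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' @rdname AtlasFuse-accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname AtlasFuse-accessors
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))

#' @rdname AtlasFuse-accessors
#' @export
setGeneric("distanceValues", function(x) standardGeneric("distanceValues"))

#' @rdname AtlasFuse-accessors
#' @export
setGeneric("atlasId", function(x) standardGeneric("atlasId"))

#' @rdname AtlasFuse-accessors
#' @export
setGeneric("proposalImage", function(x) standardGeneric("proposalImage"))

#' @rdname AtlasFuse-accessors
#' @export
setGeneric("proposalMask", function(x) standardGeneric("proposalMask"))

#' @rdname AtlasFuse-accessors
#' @export
setGeneric("nccValue", function(x) standardGeneric("nccValue"))

#' @rdname AtlasFuse-accessors
#' @export
setGeneric("roiVoxelCount", function(x) standardGeneric("roiVoxelCount"))

#' @rdname AtlasFuse-accessors
#' @export
setGeneric("fusedMask", function(x) standardGeneric("fusedMask"))

#' @rdname AtlasFuse-accessors
#' @export
setGeneric("fusionWeights", function(x) standardGeneric("fusionWeights"))

#' @rdname AtlasFuse-accessors
#' @export
setGeneric("similarityTable", function(x) standardGeneric("similarityTable"))

#' @rdname AtlasFuse-accessors
#' @export
setGeneric("fusionConfig", function(x) standardGeneric("fusionConfig"))

#' @rdname AtlasFuse-accessors
#' @export
setGeneric("kOverS", function(x) standardGeneric("kOverS"))

#' @rdname AtlasFuse-accessors
#' @export
setMethod("geometry", "GridVolume", function(x) x@geometry)

#' @rdname AtlasFuse-accessors
#' @export
setMethod("geometry", "AtlasProposal", function(x) x@image@geometry)

#' @rdname AtlasFuse-accessors
#' @export
setMethod("geometry", "DisplacementField", function(x) x@geometry)

#' @rdname AtlasFuse-accessors
#' @export
setMethod("gridShape", "GridGeometry", function(x) x@shape)

#' @rdname AtlasFuse-accessors
#' @export
setMethod("gridShape", "GridVolume", function(x) x@geometry@shape)

#' @rdname AtlasFuse-accessors
#' @export
setMethod("spacing", "GridGeometry", function(x) x@spacing)

#' @rdname AtlasFuse-accessors
#' @export
setMethod("spacing", "GridVolume", function(x) x@geometry@spacing)

#' @rdname AtlasFuse-accessors
#' @export
setMethod("origin", "GridGeometry", function(x) x@origin)

#' @rdname AtlasFuse-accessors
#' @export
setMethod("origin", "GridVolume", function(x) x@geometry@origin)

#' @rdname AtlasFuse-accessors
#' @export
setMethod("intensities", "ImageVolume", function(x) x@intensities)

#' @rdname AtlasFuse-accessors
#' @export
setMethod("membership", "BinaryMask", function(x) x@membership)

#' @rdname AtlasFuse-accessors
#' @export
setMethod("distanceValues", "SignedDistanceMap", function(x) x@values)

#' @rdname AtlasFuse-accessors
#' @export
setMethod("atlasId", "AtlasProposal", function(x) x@atlasId)

#' @rdname AtlasFuse-accessors
#' @export
setMethod("atlasId", "SimilarityScore", function(x) x@atlasId)

#' @rdname AtlasFuse-accessors
#' @export
setMethod("proposalImage", "AtlasProposal", function(x) x@image)

#' @rdname AtlasFuse-accessors
#' @export
setMethod("proposalMask", "AtlasProposal", function(x) x@mask)

#' @rdname AtlasFuse-accessors
#' @export
setMethod("nccValue", "SimilarityScore", function(x) x@ncc)

#' @rdname AtlasFuse-accessors
#' @export
setMethod("roiVoxelCount", "SimilarityScore", function(x) x@roiVoxelCount)

#' @rdname AtlasFuse-accessors
#' @export
setMethod("fusedMask", "FusionResult", function(x) x@fusedMask)

#' @rdname AtlasFuse-accessors
#' @export
setMethod("fusionWeights", "FusionResult", function(x) x@weights)

#' @rdname AtlasFuse-accessors
#' @export
setMethod("similarityTable", "FusionResult", function(x) x@similarities)

#' @rdname AtlasFuse-accessors
#' @export
setMethod("fusionConfig", "FusionResult", function(x) x@config)

#' @rdname AtlasFuse-accessors
#' @export
setMethod("kOverS", "PWFConfig", function(x) x@kOverS)

#' @rdname AtlasFuse-accessors
#' @export
setMethod("kOverS", "FusionResult", function(x) x@config@kOverS)

setMethod("show", "GridGeometry", function(object) {
  cat("GridGeometry:", paste(object@shape, collapse = " x "),
      "voxels, spacing", paste(format(object@spacing), collapse = " x "),
      "mm, origin (", paste(format(object@origin), collapse = ", "), ") mm\n")
})

setMethod("show", "ImageVolume", function(object) {
  r <- range(object@intensities)
  cat("ImageVolume:", paste(gridShape(object), collapse = " x "),
      "voxels, spacing", paste(format(spacing(object)), collapse = " x "),
      "mm, intensity range [", format(r[1]), ",", format(r[2]), "]\n")
})

setMethod("show", "BinaryMask", function(object) {
  cat("BinaryMask:", paste(gridShape(object), collapse = " x "),
      "voxels,", sum(object@membership), "foreground voxels (",
      format(maskVolume(object)), "mm^3 )\n")
})

setMethod("show", "SignedDistanceMap", function(object) {
  r <- range(object@values)
  cat("SignedDistanceMap:", paste(gridShape(object), collapse = " x "),
      "voxels, value range [", format(r[1]), ",", format(r[2]), "] mm\n")
})

setMethod("show", "AtlasProposal", function(object) {
  cat("AtlasProposal '", object@atlasId, "': ",
      sum(object@mask@membership), " foreground voxels on a ",
      paste(gridShape(object@mask), collapse = " x "), " grid\n", sep = "")
})

setMethod("show", "SimilarityScore", function(object) {
  cat("SimilarityScore '", object@atlasId, "': ncc = ",
      format(object@ncc), " over ", object@roiVoxelCount,
      " ROI voxels (margin ", format(object@marginMm), " mm)\n", sep = "")
})

setMethod("show", "PWFConfig", function(object) {
  cat("PWFConfig: k/s =", format(object@kOverS), ", margin =",
      format(object@marginMm), "mm,", object@quadratureNodes,
      "quadrature nodes\n")
})

setMethod("show", "FusionResult", function(object) {
  cat("FusionResult:", nrow(object@similarities), "proposals fused",
      "(k/s =", format(object@config@kOverS), ")\n")
  cat("  fused volume:", format(maskVolume(object@fusedMask)), "mm^3\n")
  cat("  weights:", paste(format(round(object@weights, 4)),
                          collapse = " "), "\n")
})

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec:", paste(object@shape, collapse = " x "), "grid,",
      length(object@ellipsoids), "ellipsoid(s), contrast",
      format(object@contrast), "\n")
})

setMethod("show", "DeformationSpec", function(object) {
  cat("DeformationSpec: sigma", paste(format(object@displacementSigma),
      collapse = "/"), "mm, control-point spacing",
      format(object@controlPointSpacingMm), "mm\n")
})

setMethod("show", "DisplacementField", function(object) {
  mag <- sqrt(object@displacements[, , , 1]^2 +
              object@displacements[, , , 2]^2 +
              object@displacements[, , , 3]^2)
  cat("DisplacementField on", paste(gridShape(object@geometry),
      collapse = " x "), "grid, |d| max", format(max(mag)), "mm\n")
})
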