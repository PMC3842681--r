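degenerateROIError <- function(msg) {
  structure(class = c("degenerateROIError", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' Dilate a mask by a physical margin
#'
#' The output contains every voxel whose centre lies within
#' \code{marginMm} (Euclidean distance, mm) of some foreground voxel
#' centre, so anisotropic grids behave correctly — the margin is physical,
#' not a voxel-unit structuring element. The result is a superset of the
#' input, clipped at the grid bounds. This defines the ROI in which
#' registration similarity is evaluated (10 mm for head-and-neck-like and
#' 50 mm for prostate-like settings).
#'
#' @param mask a non-empty \linkS4class{BinaryMask}
#' @param marginMm non-negative margin in mm
#' @return a \linkS4class{BinaryMask}
#' @export
dilateMask <- function(mask, marginMm) {
  stopifnot(is(mask, "BinaryMask"))
  if (!is.finite(marginMm) || marginMm < 0)
    stop("dilation margin must be a non-negative number of mm")
  if (!any(mask@membership)) stop("cannot dilate an empty mask")
  if (marginMm == 0) return(mask)
  dims <- as.integer(dim(mask@membership))
  d <- edt_cpp(as.vector(mask@membership), dims, mask@geometry@spacing)
  # sub-nanometre slack so exact lattice distances (e.g. 1.0) are included
  BinaryMask(array(d <= marginMm + 1e-9, dims), mask@geometry)
}

#' Normalized cross-correlation over a region of interest
#'
#' The Pearson (zero-normalized) form:
#' \deqn{\mathrm{NCC} = \frac{\sum (a-\bar a)(b-\bar b)}
#'   {\sqrt{\sum (a-\bar a)^2 \sum (b-\bar b)^2}}}
#' over the ROI voxels, in \eqn{[-1, 1]}. It is symmetric in the two
#' images and invariant to positive affine intensity rescaling of either —
#' the standard registration-quality surrogate. A constant image inside
#' the ROI makes the score undefined and raises a degenerate-ROI error
#' (condition class \code{degenerateROIError}); [pwfFuse()] maps that to a
#' floor similarity.
#'
#' @param target,moving \linkS4class{ImageVolume}s on a common grid
#' @param roi \linkS4class{BinaryMask} with at least 2 voxels
#' @return NCC value in [-1, 1]
#' @export
nccSimilarity <- function(target, moving, roi) {
  stopifnot(is(target, "ImageVolume"), is(moving, "ImageVolume"),
            is(roi, "BinaryMask"))
  assertCommonGrid(list(target = target, moving = moving, roi = roi))
  sel <- roi@membership
  if (sum(sel) < 2L) stop("ROI must contain at least 2 voxels")
  a <- target@intensities[sel]
  b <- moving@intensities[sel]
  da <- a - mean(a)
  db <- b - mean(b)
  ssa <- sum(da * da)
  ssb <- sum(db * db)
  if (ssa == 0 || ssb == 0)
    stop(degenerateROIError(
      "zero intensity variance within the ROI; NCC undefined"))
  min(1, max(-1, sum(da * db) / sqrt(ssa * ssb)))
}

#' Score one atlas proposal against the target image
#'
#' Computes the local registration-success score of a deformed atlas: NCC
#' between the target image and the deformed atlas image over the deformed
#' structure dilated by \code{marginMm}. The ROI is that proposal's own —
#' there is no shared ROI across atlases.
#'
#' @param target the target \linkS4class{ImageVolume}
#' @param proposal an \linkS4class{AtlasProposal} on the target grid
#' @param marginMm dilation margin in mm (default 10)
#' @return a \linkS4class{SimilarityScore}
#' @export
scoreProposal <- function(target, proposal, marginMm = 10) {
  stopifnot(is(proposal, "AtlasProposal"))
  assertCommonGrid(list(target = target, proposal = proposal))
  roi <- dilateMask(proposal@mask, marginMm)
  val <- nccSimilarity(target, proposal@image, roi)
  new("SimilarityScore", atlasId = proposal@atlasId, ncc = val,
      roiVoxelCount = sum(roi@membership), marginMm = as.numeric(marginMm))
}
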