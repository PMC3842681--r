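#' Signed Euclidean distance map of a binary mask
#'
#' For every foreground voxel the value is minus the Euclidean distance in
#' mm from its centre to the nearest background voxel centre; for every
#' background voxel it is plus the distance to the nearest foreground voxel
#' centre. Distances are voxel-centre to voxel-centre with anisotropic
#' spacing respected; no sub-voxel surface model and no truncation. The
#' map is the substrate of weighted-superposition fusion: thresholding it
#' at \code{< 0} recovers the mask exactly.
#'
#' @param mask a non-empty, non-full \linkS4class{BinaryMask}
#' @return a \linkS4class{SignedDistanceMap} on the same grid
#' @examples
#' m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
#' sdm <- signedDistance(BinaryMask(m))
#' distanceValues(sdm)[3, 3, 3]  # -1: one voxel from background
#' @export
signedDistance <- function(mask) {
  stopifnot(is(mask, "BinaryMask"))
  fg <- mask@membership
  nfg <- sum(fg)
  if (nfg == 0L)
    stop("degenerate mask: empty (no foreground voxels)")
  if (nfg == length(fg))
    stop("degenerate mask: all-foreground (no background voxels)")
  dims <- as.integer(dim(fg))
  sp <- mask@geometry@spacing
  dToFg <- edt_cpp(as.vector(fg), dims, sp)
  dToBg <- edt_cpp(as.vector(!fg), dims, sp)
  vals <- ifelse(fg, -dToBg, dToFg)
  SignedDistanceMap(array(vals, dims), mask@geometry)
}

#' Recover a mask from a signed distance map
#'
#' Membership is \code{value < 0}: strictly negative means inside, and a
#' voxel exactly on the zero level set is background. The round trip
#' \code{maskFromDistance(signedDistance(m))} is the identity for any
#' proper mask. An everywhere non-negative map yields an empty mask with a
#' warning (downstream fusion treats that as a failed fusion, not an
#' error).
#'
#' @param sdm a \linkS4class{SignedDistanceMap} with finite values
#' @return a \linkS4class{BinaryMask}
#' @export
maskFromDistance <- function(sdm) {
  stopifnot(is(sdm, "SignedDistanceMap"))
  if (!all(is.finite(sdm@values)))
    stop("signed distance map contains non-finite values")
  inside <- sdm@values < 0
  if (!any(inside))
    warning("distance map is non-negative everywhere; returning an ",
            "empty mask")
  BinaryMask(array(inside, dim(sdm@values)), sdm@geometry)
}

#' Weighted superposition of signed distance maps
#'
#' The per-voxel convex combination \eqn{\sum_i w_i \, d_i(v)} of the
#' input maps. With the weights produced by [computeWeights()] this is the
#' shape-averaging step of probabilistic weighting fusion: the zero level
#' set of the weighted sum is the weighted mean shape.
#'
#' @param sdms list of \linkS4class{SignedDistanceMap}s on a common grid
#' @param weights non-negative numeric weights summing to 1 (within 1e-9)
#' @return a \linkS4class{SignedDistanceMap}
#' @export
weightedDistanceSum <- function(sdms, weights) {
  if (length(sdms) == 0L) stop("no distance maps to combine")
  if (length(weights) != length(sdms))
    stop("need exactly one weight per distance map")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-9)
    stop("weights must sum to 1 (deviation ",
         format(abs(sum(weights) - 1)), ")")
  assertCommonGrid(sdms)
  acc <- weights[1L] * sdms[[1L]]@values
  for (i in seq_along(sdms)[-1L])
    acc <- acc + weights[i] * sdms[[i]]@values
  SignedDistanceMap(acc, sdms[[1L]]@geometry)
}
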