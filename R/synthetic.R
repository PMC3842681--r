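maybeWithSeed <- function(seed, code) {
  if (is.na(seed)) code() else withr::with_seed(seed, code())
}

# seeds derived for sub-streams stay well below 2^31
deriveSeed <- function(seed, i) {
  as.integer(((as.double(seed) %% 100003) * 20011 + i) %% 2147483647)
}

#' Construct a PhantomSpec
#'
#' Defaults describe the study conditions used throughout the package's
#' simulations: a 64^3 grid at 1 mm isotropic spacing carrying an
#' elongated two-ellipsoid structure (volume roughly 7 cm^3, similar in
#' scale to a nodal target region), contrast 100 intensity units over a
#' correlated background texture (amplitude 20, correlation length 8 mm)
#' plus white observation noise (sigma 5).
#'
#' @param shape integer grid shape (default \code{c(64, 64, 64)})
#' @param spacing voxel spacing mm (default 1 mm isotropic)
#' @param ellipsoids list of lists with \code{center} and \code{semiaxes}
#'   in mm (1-3 ellipsoids, union)
#' @param contrast structure-minus-background intensity difference
#' @param textureAmplitude sd of the correlated background texture
#' @param textureLengthMm correlation length of the texture, mm
#' @param noiseSigma white observation-noise sd
#' @param seed integer seed; \code{NA} draws from the current RNG state
#' @return a \linkS4class{PhantomSpec}
#' @export
phantomSpec <- function(shape = c(64L, 64L, 64L), spacing = c(1, 1, 1),
                        ellipsoids = list(
                          list(center = c(30, 32, 26),
                               semiaxes = c(9, 8, 13)),
                          list(center = c(34, 31, 40),
                               semiaxes = c(8, 9, 12))),
                        contrast = 100, textureAmplitude = 20,
                        textureLengthMm = 8, noiseSigma = 5,
                        seed = NA_integer_) {
  new("PhantomSpec", shape = as.integer(rep_len(shape, 3L)),
      spacing = as.numeric(rep_len(spacing, 3L)), ellipsoids = ellipsoids,
      contrast = as.numeric(contrast),
      textureAmplitude = as.numeric(textureAmplitude),
      textureLengthMm = as.numeric(textureLengthMm),
      noiseSigma = as.numeric(noiseSigma), seed = as.integer(seed))
}

#' Construct a DeformationSpec
#'
#' @param displacementSigma per-axis sd of control-point displacements, mm
#'   (scalar recycled to 3)
#' @param intensityNoiseSigma white noise added to the warped image
#' @param controlPointSpacingMm coarse lattice spacing, mm (default 16)
#' @param seed integer seed; \code{NA} draws from the current RNG state
#' @return a \linkS4class{DeformationSpec}
#' @export
deformationSpec <- function(displacementSigma, intensityNoiseSigma = 0,
                            controlPointSpacingMm = 16,
                            seed = NA_integer_) {
  new("DeformationSpec",
      controlPointSpacingMm = as.numeric(controlPointSpacingMm),
      displacementSigma = as.numeric(rep_len(displacementSigma, 3L)),
      intensityNoiseSigma = as.numeric(intensityNoiseSigma),
      seed = as.integer(seed))
}

# White noise on a coarse isotropic lattice (spacing coarseMm), trilinearly
# interpolated to the voxel centres: smooth noise whose correlation length
# is the lattice spacing. Returns a vector in array order.
coarseInterpNoise <- function(geometry, coarseMm, sigma) {
  extent <- (geometry@shape - 1L) * geometry@spacing
  nC <- as.integer(ceiling(extent / coarseMm)) + 3L
  originC <- geometry@origin - coarseMm
  ctrl <- rnorm(prod(nC), 0, sigma)
  w <- voxelCenters(geometry)
  trilinear_cpp(ctrl, nC,
                (w$x - originC[1]) / coarseMm,
                (w$y - originC[2]) / coarseMm,
                (w$z - originC[3]) / coarseMm, 0)
}

#' Generate a phantom target image and its ground-truth mask
#'
#' The mask contains every voxel whose centre lies inside the ellipsoid
#' union (voxel-centre rule); the image is the contrast times the mask
#' indicator, plus correlated background texture, plus white noise.
#' Deterministic given the spec's seed.
#'
#' @param spec a \linkS4class{PhantomSpec}
#' @return list with components \code{image} (\linkS4class{ImageVolume})
#'   and \code{mask} (\linkS4class{BinaryMask})
#' @export
makePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  geometry <- GridGeometry(spec@shape, spec@spacing)
  w <- voxelCenters(geometry)
  inside <- rep(FALSE, length(w$x))
  for (e in spec@ellipsoids) {
    inside <- inside |
      (((w$x - e$center[1]) / e$semiaxes[1])^2 +
       ((w$y - e$center[2]) / e$semiaxes[2])^2 +
       ((w$z - e$center[3]) / e$semiaxes[3])^2 <= 1)
  }
  mask <- BinaryMask(array(inside, spec@shape), geometry)
  img <- maybeWithSeed(spec@seed, function() {
    vals <- spec@contrast * as.numeric(inside)
    if (spec@textureAmplitude > 0)
      vals <- vals + coarseInterpNoise(geometry, spec@textureLengthMm,
                                       spec@textureAmplitude)
    if (spec@noiseSigma > 0)
      vals <- vals + rnorm(length(vals), 0, spec@noiseSigma)
    ImageVolume(array(vals, spec@shape), geometry)
  })
  list(image = img, mask = mask)
}

#' Sample a smooth random displacement field
#'
#' Emulates B-spline-like registration output as a forward generator:
#' i.i.d. normal displacements on a coarse control-point lattice,
#' trilinearly interpolated to the voxel grid. The field is smooth (its
#' gradient is bounded by sigma over the control-point spacing), zero-mean
#' in expectation, and deterministic given the spec's seed.
#'
#' @param spec a \linkS4class{DeformationSpec}
#' @param geometry the voxel \linkS4class{GridGeometry} to interpolate onto
#' @return a \linkS4class{DisplacementField} (mm per axis per voxel)
#' @export
smoothDisplacementField <- function(spec, geometry) {
  stopifnot(is(spec, "DeformationSpec"), is(geometry, "GridGeometry"))
  validObject(spec)
  if (spec@controlPointSpacingMm < 2 * max(geometry@spacing))
    stop("control-point spacing must be at least twice the voxel spacing")
  sh <- geometry@shape
  maybeWithSeed(spec@seed, function() {
    d <- array(0, c(sh, 3L))
    for (ax in 1:3) {
      if (spec@displacementSigma[ax] > 0)
        d[, , , ax] <- coarseInterpNoise(geometry,
                                         spec@controlPointSpacingMm,
                                         spec@displacementSigma[ax])
    }
    new("DisplacementField", geometry = geometry, displacements = d)
  })
}

#' Warp an image and mask by a displacement field
#'
#' Backward mapping: the warped value at voxel centre x is sampled from
#' the input at x + d(x) by trilinear interpolation. The mask is warped
#' through its signed distance map — the map is interpolated and
#' re-thresholded at \code{< 0} — which preserves sub-voxel boundary
#' position and avoids the aliasing of nearest-neighbour label warping.
#' Samples falling outside the grid take the background intensity (0) for
#' the image and a large positive distance for the mask.
#'
#' @param image \linkS4class{ImageVolume} to warp
#' @param mask \linkS4class{BinaryMask} to warp (same grid)
#' @param field \linkS4class{DisplacementField} on the same grid, mm
#' @param atlasId identifier for the returned proposal
#' @param noiseSigma sd of white noise added to the warped image
#'   (default 0)
#' @return an \linkS4class{AtlasProposal}; if warping empties the mask a
#'   warning is raised and the proposal is still returned
#' @export
applyDeformation <- function(image, mask, field, atlasId = "warped",
                             noiseSigma = 0) {
  stopifnot(is(image, "ImageVolume"), is(mask, "BinaryMask"),
            is(field, "DisplacementField"))
  assertCommonGrid(list(image = image, mask = mask, field = field))
  geometry <- image@geometry
  sh <- geometry@shape
  w <- voxelCenters(geometry)
  xi <- (w$x + as.vector(field@displacements[, , , 1]) -
         geometry@origin[1]) / geometry@spacing[1]
  yi <- (w$y + as.vector(field@displacements[, , , 2]) -
         geometry@origin[2]) / geometry@spacing[2]
  zi <- (w$z + as.vector(field@displacements[, , , 3]) -
         geometry@origin[3]) / geometry@spacing[3]
  dims <- as.integer(sh)
  wimg <- trilinear_cpp(as.vector(image@intensities), dims, xi, yi, zi, 0)
  if (noiseSigma > 0)
    wimg <- wimg + rnorm(length(wimg), 0, noiseSigma)
  sdf <- signedDistance(mask)
  wsdf <- trilinear_cpp(as.vector(sdf@values), dims, xi, yi, zi,
                        gridDiagonal(geometry))
  wmask <- wsdf < 0
  AtlasProposal(atlasId,
                ImageVolume(array(wimg, sh), geometry),
                BinaryMask(array(wmask, sh), geometry))
}

#' Generate a synthetic multi-atlas ensemble with known ground truth
#'
#' Stands in for the clinical pipeline: the phantom provides the target
#' image and ground-truth structure, and each "atlas" proposal is the
#' target warped by an independent smooth random deformation, with image
#' noise coupled to the deformation magnitude so that image similarity is
#' statistically informative about segmentation quality — the premise the
#' probabilistic weighting exploits. Per-proposal DSC to truth is
#' recorded in the manifest. Fully deterministic given \code{seed};
#' distinct seeds give distinct ensembles.
#'
#' @param phantom a \linkS4class{PhantomSpec} (its own seed is ignored;
#'   \code{seed} governs the whole ensemble)
#' @param nAtlases number of proposals (default 15)
#' @param qualitySpread displacement sigmas mm, one per atlas; default
#'   draws them uniformly from 1-8 mm
#' @param noisePolicy function mapping displacement sigma to image-noise
#'   sigma; default linear, 4 intensity units per mm
#' @param controlPointSpacingMm deformation control-point spacing, mm
#' @param seed integer seed for the whole ensemble
#' @return list with \code{target} (\linkS4class{ImageVolume}),
#'   \code{truth} (\linkS4class{BinaryMask}), \code{proposals} (list of
#'   \linkS4class{AtlasProposal}) and \code{manifest} (data.frame with
#'   atlas_id, displacement_sigma, noise_sigma, dsc_to_truth)
#' @export
makeEnsemble <- function(phantom = phantomSpec(), nAtlases = 15L,
                         qualitySpread = NULL,
                         noisePolicy = function(sigma) 4 * sigma,
                         controlPointSpacingMm = 16, seed = 1L) {
  stopifnot(is(phantom, "PhantomSpec"), nAtlases >= 1L)
  if (!is.null(qualitySpread) && length(qualitySpread) != nAtlases)
    stop("qualitySpread must have one displacement sigma per atlas")
  withr::with_seed(deriveSeed(seed, 0L), {
    phantom@seed <- NA_integer_
    ph <- makePhantom(phantom)
    sigmas <- if (is.null(qualitySpread)) runif(nAtlases, 1, 8)
              else as.numeric(qualitySpread)
    noiseSigmas <- vapply(sigmas, noisePolicy, numeric(1))
    proposals <- vector("list", nAtlases)
    dscs <- numeric(nAtlases)
    for (i in seq_len(nAtlases)) {
      dspec <- deformationSpec(sigmas[i],
                               controlPointSpacingMm = controlPointSpacingMm)
      fld <- smoothDisplacementField(dspec, ph$image@geometry)
      proposals[[i]] <- applyDeformation(ph$image, ph$mask, fld,
                                         atlasId = sprintf("atlas%02d", i),
                                         noiseSigma = noiseSigmas[i])
      dscs[i] <- dice(proposals[[i]]@mask, ph$mask)
    }
    manifest <- data.frame(
      atlas_id = vapply(proposals, atlasId, ""),
      displacement_sigma = sigmas,
      noise_sigma = noiseSigmas,
      dsc_to_truth = dscs,
      stringsAsFactors = FALSE)
    list(target = ph$image, truth = ph$mask, proposals = proposals,
         manifest = manifest)
  })
}
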