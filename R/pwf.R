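#' Construct a PWFConfig
#'
#' @param kOverS non-negative ratio controlling how strongly similarity
#'   differences are converted into weight differences; 0 gives equal
#'   weights, very large values select the single most similar atlas.
#'   Default 0.5; 20 is the documented choice for prostate-like settings.
#' @param quadratureNodes Gauss-Hermite nodes for the weight integral
#'   (default 64)
#' @param marginMm dilation margin in mm for the similarity ROI
#'   (default 10; 50 for prostate-like settings)
#' @return a \linkS4class{PWFConfig}
#' @export
PWFConfig <- function(kOverS = 0.5, quadratureNodes = 64L, marginMm = 10) {
  new("PWFConfig", kOverS = as.numeric(kOverS),
      quadratureNodes = as.integer(quadratureNodes),
      marginMm = as.numeric(marginMm))
}

#' Probabilistic fusion weights from similarity scores
#'
#' The weighting model: each atlas's latent segmentation quality is
#' \eqn{q_i = (k/s)\, m_i + \epsilon_i} with \eqn{m_i} its similarity
#' score and \eqn{\epsilon_i} independent standard normal. The weight of
#' atlas \eqn{i} is the probability that it is the best,
#' \deqn{w_i = \int \phi(t) \prod_{j \ne i} \Phi\!\big(t + (k/s)(m_i - m_j)\big)\, dt,}
#' evaluated by Gauss-Hermite quadrature and renormalized to sum to 1.
#' Only similarity \emph{differences} enter, so the weights are invariant
#' to adding a constant to all scores. \code{kOverS = 0} gives equal,
#' unbiased weights \eqn{1/N}; \code{kOverS} very large concentrates all
#' weight on the most similar atlas. For \eqn{N = 2} the closed form is
#' \eqn{w_1 = \Phi\big((k/s)(m_1 - m_2)/\sqrt 2\big)}.
#'
#' @param similarities numeric vector of per-atlas similarity scores
#' @param kOverS non-negative real
#' @param quadratureNodes integer >= 32 (default 64)
#' @return numeric weights, non-negative, summing to 1
#' @examples
#' computeWeights(c(0.9, 0.8), kOverS = 10)  # ~ pnorm(1/sqrt(2))
#' computeWeights(c(0.9, 0.8, 0.7), kOverS = 0)  # uniform
#' @export
computeWeights <- function(similarities, kOverS, quadratureNodes = 64L) {
  m <- as.numeric(similarities)
  n <- length(m)
  if (n == 0L) stop("no similarity scores supplied")
  if (!all(is.finite(m))) stop("similarity scores must be finite")
  if (!is.finite(kOverS) || kOverS < 0)
    stop("kOverS must be finite and >= 0")
  if (quadratureNodes < 32L) stop("quadratureNodes must be >= 32")
  if (n == 1L) return(1)
  gh <- pracma::gaussHermite(as.integer(quadratureNodes))
  t <- sqrt(2) * gh$x                 # int phi(t) g(t) dt, t = sqrt(2) x
  w <- numeric(n)
  for (i in seq_len(n)) {
    # log prod_j Phi(t + (k/s)(m_i - m_j)); log space keeps extreme
    # kOverS from underflowing before the product is formed
    shift <- kOverS * (m[i] - m[-i])
    lp <- rowSums(pnorm(outer(t, shift, "+"), log.p = TRUE))
    w[i] <- sum(gh$w * exp(lp)) / sqrt(pi)
  }
  if (sum(w) <= 0)
    stop("quadrature produced a degenerate weight vector")
  w / sum(w)
}

extractMask <- function(x) {
  if (is(x, "AtlasProposal")) x@mask
  else if (is(x, "BinaryMask")) x
  else stop("proposals must be AtlasProposal or BinaryMask objects")
}

#' Fuse proposals by weighted superposition of distance maps
#'
#' Each proposal mask is converted to its signed distance map, the maps
#' are combined with the given convex weights, and the fused mask is the
#' negative region of the combined map. Because distance maps, not
#' indicator functions, are averaged, the result is a weighted mean
#' \emph{shape}; its boundary interpolates smoothly between the proposal
#' boundaries. An empty fused mask (possible when proposals barely
#' overlap) produces a warning, not an error.
#'
#' @param proposals list of \linkS4class{AtlasProposal} or
#'   \linkS4class{BinaryMask} objects on a common grid
#' @param weights non-negative weights summing to 1
#' @return the fused \linkS4class{BinaryMask}
#' @export
fuseProposals <- function(proposals, weights) {
  if (length(proposals) == 0L) stop("no proposals to fuse")
  masks <- lapply(proposals, extractMask)
  assertCommonGrid(masks)
  sdms <- lapply(masks, signedDistance)
  maskFromDistance(weightedDistanceSum(sdms, weights))
}

#' Probabilistic weighting fusion, end to end
#'
#' Scores every proposal against the target image ([scoreProposal()]),
#' converts the scores into weights ([computeWeights()]), and fuses the
#' proposal masks by weighted superposition of signed distance maps
#' ([fuseProposals()]). A proposal whose ROI has zero intensity variance
#' (a failed registration producing a constant patch) cannot be scored; it
#' is assigned the minimum similarity among scoreable proposals minus 0.1
#' with a warning, so it receives near-zero weight at large k/s and the
#' uniform weight at k/s = 0.
#'
#' @param target the target \linkS4class{ImageVolume}
#' @param proposals list of \linkS4class{AtlasProposal}s on the target grid
#' @param config a \linkS4class{PWFConfig}
#' @return a \linkS4class{FusionResult}
#' @export
pwfFuse <- function(target, proposals, config = PWFConfig()) {
  stopifnot(is(target, "ImageVolume"), is(config, "PWFConfig"))
  if (length(proposals) == 0L) stop("no proposals to fuse")
  validObject(config)
  assertCommonGrid(c(list(target = target), proposals))

  scores <- vector("list", length(proposals))
  ncc <- rep(NA_real_, length(proposals))
  roiN <- rep(NA_integer_, length(proposals))
  for (i in seq_along(proposals)) {
    s <- tryCatch(
      scoreProposal(target, proposals[[i]], config@marginMm),
      degenerateROIError = function(e) NULL)
    if (!is.null(s)) {
      scores[[i]] <- s
      ncc[i] <- s@ncc
      roiN[i] <- s@roiVoxelCount
    }
  }
  if (all(is.na(ncc)))
    stop("no proposal could be scored: every ROI has zero intensity ",
         "variance")
  if (anyNA(ncc)) {
    floorSim <- min(ncc, na.rm = TRUE) - 0.1
    bad <- which(is.na(ncc))
    warning("proposal(s) ",
            paste(vapply(proposals[bad], atlasId, ""), collapse = ", "),
            " have degenerate ROIs; assigned floor similarity ",
            format(floorSim))
    for (i in bad) {
      roi <- dilateMask(proposals[[i]]@mask, config@marginMm)
      ncc[i] <- floorSim
      roiN[i] <- sum(roi@membership)
    }
  }

  weights <- computeWeights(ncc, config@kOverS, config@quadratureNodes)
  fused <- fuseProposals(proposals, weights)
  simtab <- data.frame(
    atlas_id = vapply(proposals, atlasId, ""),
    ncc = ncc,
    roi_voxel_count = roiN,
    margin_mm = config@marginMm,
    stringsAsFactors = FALSE)
  new("FusionResult", fusedMask = fused, weights = weights,
      similarities = simtab, config = config)
}
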