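# Brute-force oracles: all-pairs voxel-centre computations, independent of
# the package's separable transforms. Only usable on small grids.

# distance (mm) from every voxel centre to the nearest TRUE voxel centre
bruteDistToFg <- function(fg, spacing) {
  sh <- dim(fg)
  idxAll <- arrayInd(seq_along(fg), sh)
  coords <- sweep(idxAll - 1, 2, spacing, "*")
  fgCoords <- coords[as.vector(fg), , drop = FALSE]
  d <- apply(coords, 1, function(p) {
    min(sqrt(colSums((t(fgCoords) - p)^2)))
  })
  array(d, sh)
}

bruteSignedDistance <- function(mask) {
  fg <- membership(mask)
  sp <- spacing(mask)
  dFg <- bruteDistToFg(fg, sp)
  dBg <- bruteDistToFg(!fg, sp)
  ifelse(fg, -dBg, dFg)
}

bruteDilate <- function(mask, marginMm) {
  d <- bruteDistToFg(membership(mask), spacing(mask))
  d <= marginMm + 1e-9
}

bruteDice <- function(a, b) {
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

# random proper mask (neither empty nor full) on a random small grid
randomProperMask <- function(maxDim = 8L, p = NULL) {
  sh <- sample(2:maxDim, 3L, replace = TRUE)
  sp <- sample(c(0.5, 1, 1.5, 2), 3L, replace = TRUE)
  if (is.null(p)) p <- runif(1, 0.1, 0.9)
  repeat {
    m <- array(runif(prod(sh)) < p, sh)
    if (any(m) && !all(m)) break
  }
  BinaryMask(m, GridGeometry(sh, spacing = sp))
}

# digitized ball by the voxel-centre rule, on an isotropic 1 mm grid
ballMask <- function(shape, centerMm, radiusMm, geometry = NULL) {
  if (is.null(geometry)) geometry <- GridGeometry(shape)
  idx <- arrayInd(seq_len(prod(shape)), shape)
  w <- sweep(sweep(idx - 1, 2, spacing(geometry), "*"), 2,
             origin(geometry), "+")
  d <- sqrt(colSums((t(w) - centerMm)^2))
  BinaryMask(array(d <= radiusMm, shape), geometry)
}

# compact phantom for fast simulation tests (structure scaled to a 32 mm
# field of view, same texture/noise character as the default spec)
smallPhantomSpec <- function(seed = NA_integer_) {
  phantomSpec(shape = c(32L, 32L, 32L),
              ellipsoids = list(list(center = c(15, 16, 13),
                                     semiaxes = c(5, 4, 7)),
                                list(center = c(17, 15, 19),
                                     semiaxes = c(4, 5, 6))),
              seed = seed)
}
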