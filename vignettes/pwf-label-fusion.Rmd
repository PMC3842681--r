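---
title: "Probabilistic weighting fusion of multi-atlas segmentations: model and methods"
author: "AtlasFuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic weighting fusion: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the fusion model
and its assumptions, the parameters that matter, what the synthetic
generator does and does not emulate, the numerical choices, and the known
limitations.

## The fusion model

Multi-atlas segmentation produces N binary proposals of one structure on
a common target grid, each the output of a deformable registration of a
different atlas. AtlasFuse combines them by **weighted superposition of
signed distance maps**. Every proposal mask is converted to its signed
Euclidean distance map (negative inside, positive outside, in mm), the
maps are combined with convex weights, and the fused mask is the strictly
negative region of the combination. Averaging distance maps rather than
indicator functions makes the result a weighted mean *shape*: its
boundary interpolates between the proposal boundaries instead of
producing staircase majority artefacts, and with a one-hot weight vector
it reproduces the corresponding proposal exactly.

The weights encode *local registration success*. Each atlas receives a
similarity score `m_i`: the Pearson normalized cross-correlation between
the target image and the deformed atlas image, computed over that atlas's
own deformed structure dilated by a physical margin. The weighting model
treats latent segmentation quality as

    q_i = (k/s) * m_i + eps_i,  eps_i ~ N(0,1) i.i.d.,

and sets `w_i = P(q_i = max_j q_j)`, computed as

    w_i = Integral phi(t) Prod_{j != i} Phi(t + (k/s)(m_i - m_j)) dt

by Gauss–Hermite quadrature. This particular definition was an open
design point — the ratio k/s is the only free parameter of the published
method, but the weighting formula itself is specified in an earlier
report we do not reproduce. The model above is this package's definition
of PWF, chosen because it (a) depends on the scores only through
`(k/s)(m_i - m_j)`, so exactly the ratio k/s and no other parameter
enters; (b) reproduces both documented limits exactly — k/s = 0 gives
equal, unbiased weights 1/N, and k/s → ∞ selects the single most similar
registration; and (c) admits a closed form at N = 2,
`w_1 = Phi((k/s)(m_1 - m_2)/sqrt(2))`, giving the quadrature an exact
independent check. The tests additionally validate the quadrature against
direct Monte-Carlo sampling of the latent model at N ≤ 4.

Assumptions worth keeping in mind: quality differences are driven by a
single scalar similarity per atlas (no voxelwise weighting); the noise on
latent quality is homoscedastic across atlases; and raw NCC values are
used without standardization (the construction is invariant to adding a
constant to all scores, so only the scale of NCC differences interacts
with k/s).

## Parameters

* **`kOverS`** (dimensionless, default 0.5; 20 documented for
  prostate-like settings). Controls how sharply similarity differences
  become weight differences. Because it multiplies NCC *differences*,
  its effective operating point depends on the spread of the similarity
  scores: `(k/s) * range(m)` of order 1 gives graded weighting, much
  larger values approach single-atlas selection. For optimal performance
  it should be tuned on representative material; no tuning machinery is
  included here.
* **`marginMm`** (mm, default 10; 50 documented for prostate-like
  settings). The uniform dilation of the deformed structure defining the
  NCC region of interest. Larger margins average image agreement over
  more context, compressing score differences; margins are physical so
  anisotropic grids behave correctly.
* **`quadratureNodes`** (default 64, minimum 32). Gauss–Hermite nodes
  for the weight integral. 64 nodes reproduce the N = 2 closed form to
  well below 1e-9; weights are renormalized after quadrature so the
  vector sums to 1 exactly.

## The synthetic generator

No clinical images ship with the package; the generator replaces both
the patient material and the commercial B-spline registration step with a
forward simulation that provides ground truth for free.

* **Phantom** (`makePhantom`): a union of 1–3 axis-aligned ellipsoids
  rasterized by the voxel-centre rule, painted with constant contrast
  over a spatially correlated background texture (white noise on a
  coarse lattice, trilinearly interpolated) plus white observation
  noise. Defaults — 64³ voxels at 1 mm, a two-ellipsoid elongated
  structure of roughly 7 cm³, contrast 100, texture amplitude 20 with
  8 mm correlation length, noise sigma 5 — were fixed once as a
  plausible desk-scale stand-in for a nodal target region in CT-like
  data: structure contrast well above noise, background structure on a
  coarser scale than the voxel.
* **Deformation** (`smoothDisplacementField`, `applyDeformation`):
  i.i.d. normal control-point displacements on a 16 mm lattice,
  trilinearly interpolated — a forward emulation of B-spline-like
  registration error, not a registration optimizer. Masks are warped
  through their signed distance map (interpolate, re-threshold at < 0),
  which preserves sub-voxel boundary placement and avoids the aliasing
  of nearest-neighbour label warping.
* **Ensemble** (`makeEnsemble`): per-atlas displacement sigmas drawn
  uniformly from 1–8 mm, with image noise coupled linearly to the
  displacement sigma (4 intensity units per mm). The coupling exists
  because probabilistic weighting only helps when image similarity
  predicts segmentation quality; the linear form is the simplest such
  policy and its strength is a knob (`noisePolicy`).

What the generator does **not** emulate: real CT anatomy and Hounsfield
calibration, inter-patient anatomical variability (proposals are warps of
the target itself, so NCC is optimistic), registration failure modes that
are not smooth (sliding, topology changes), and observer variability.
Passing tests on this generator demonstrate the internal correctness and
the qualitative behaviour of the method, not clinical performance.

## Behaviour at large k/s: a caveat on the shrinkage effect

Two directional properties of fusion are exercised by the test suite on
20-seed ensemble studies: the fused mask overlaps truth at least as well
as the average individual proposal, and — where genuine averaging occurs
— the fused volume is smaller than the average proposal volume, because
the superposition emphasises the central region common to most proposals
at the expense of peripheral disagreement. The second property depends
on the weights actually being spread over several atlases. On these
synthetic ensembles the NCC scores span a range of roughly 0.4–0.6 (the
1–8 mm deformations decorrelate a small phantom strongly, with or
without added image noise), so at k/s = 20 the weight vector concentrates
towards single-atlas selection and the volume behaviour follows the best
single proposal rather than a consensus core; the acceptance study
reports the shrinkage fraction at k/s = 20 alongside the equal-weight
volume ratio so both regimes are visible. In clinical use the same
arithmetic applies in reverse: k/s = 20 was workable there precisely
because similarity scores cluster tightly, making `(k/s)·Δm` of order 1.
Users choosing k/s for new material should inspect the NCC spread first.

## Numerical choices

* **Distance semantics**: voxel-centre to voxel-centre Euclidean
  distance in mm, computed by the exact separable squared-distance
  transform (lower-envelope-of-parabolas), anisotropic spacing
  respected, no truncation or clamping. This matches an all-pairs
  brute-force oracle exactly and keeps "threshold at < 0" an exact
  inverse of the transform.
* **Sign and tie rule**: negative strictly inside; a voxel with value
  exactly 0 is background. One strict, testable convention.
* **Empty fusion**: an everywhere-non-negative fused map yields an empty
  mask with a warning, not an error — a batch run should survive a
  failed fusion and report it.
* **Degenerate ROIs**: a proposal whose ROI has zero intensity variance
  cannot be scored; it is assigned the minimum scoreable similarity
  minus 0.1 with a warning, so it gets near-zero weight at large k/s and
  the uniform weight at k/s = 0.
* **Dilation inclusiveness**: voxels at exactly the margin distance are
  included (a sub-nanometre tolerance absorbs floating-point noise in
  exact lattice distances).
* **Grid equality**: spacing and origin must agree within 1e-4 mm;
  oblique direction cosines are rejected at read time rather than
  silently mishandled.
* **Masks on disk**: unsigned 8-bit, 0/1, for interoperability; images
  are 32-bit float. All physical quantities are mm throughout; there is
  no unit auto-detection.

## Problem sizes

The shipped tests and the acceptance study run at the generator's
default 64³ scale for the ensemble studies (20 seeds, N = 15), at 64³
for the concentric-ball closed-form check, and on grids up to 8³ for the
brute-force oracle suites (200 random masks), with smaller 32³ phantoms
for unit-level simulation properties. These sizes were chosen so the
full suite completes in a few minutes while keeping digitization error
small relative to the tolerances asserted.

## Limitations

* Weights are per structure, not per voxel; locality comes only from
  the ROI.
* Only axis-aligned grids are supported; DICOM/DICOM-RT and contour
  (polygon) representations are out of scope — masks in, masks out.
* No atlas selection, no STAPLE-style consensus estimation, and no
  optimization of k/s from training data.
* Volumes are voxel counts times voxel volume; no partial-volume
  modelling, so volumes from systems with sub-voxel contour handling
  will differ slightly.
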