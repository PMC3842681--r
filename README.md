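# AtlasFuse

Probabilistic weighting fusion (PWF) of multi-atlas segmentations for
radiotherapy structure delineation, with the evaluation metrics used to
assess such segmentations and a synthetic ensemble generator that stands
in for deformable registration.

## The problem

Atlas-based auto-segmentation deformably registers previously delineated
patient image sets ("atlases") onto a new patient image, producing N
deformed segmentation proposals for a structure such as the head-and-neck
or pelvic lymph node region. The proposals disagree, and a clinician needs
one consensus delineation to edit. AtlasFuse implements the fusion step:
combining N proposals into a single weighted mean shape, weighting each
atlas by how successfully its image registered locally around the
structure.

## The method

Each proposal mask `M_i` is converted to its signed Euclidean distance map
`d_i(x)` (negative inside, positive outside, mm). The fused segmentation
is the negative region of the convex combination

    d_fused(x) = Σ_i w_i d_i(x),      M_fused = { x : d_fused(x) < 0 }.

The weights come from a per-atlas similarity score `m_i`: the Pearson
normalized cross-correlation (NCC) between the target image and the
deformed atlas image, evaluated over that atlas's deformed structure
dilated by a uniform physical margin (10 mm for head-and-neck-like, 50 mm
for prostate-like settings). Latent segmentation quality is modelled as

    q_i = (k/s)·m_i + ε_i,   ε_i ~ N(0, 1) independent,

and the weight of atlas i is the probability that it is the best,

    w_i = P(q_i = max_j q_j)
        = ∫ φ(t) Π_{j≠i} Φ(t + (k/s)(m_i − m_j)) dt,

evaluated by Gauss–Hermite quadrature. The single parameter k/s (the
proportionality of segmentation quality to registration quality over the
expected spread of segmentation quality) interpolates between two regimes:
k/s = 0 gives equal, unbiased weights; k/s → ∞ selects the single most
similar registration. For N = 2 the closed form is
`w_1 = Φ((k/s)(m_1 − m_2)/√2)`.

Evaluation uses the Dice similarity coefficient
`DSC = 2|A∩B| / (|A|+|B|)` counted over voxels (voxel-centre rule),
structure volume (voxel count × voxel volume) and volume ratios against a
reference.

## Worked example

Simulate an ensemble of 15 deformed proposals around a known ground-truth
structure, fuse them, and evaluate:

```r
library(AtlasFuse)

ens <- makeEnsemble(nAtlases = 15, seed = 42)
res <- pwfFuse(ens$target, ens$proposals,
               PWFConfig(kOverS = 0.5, marginMm = 10))
res
#> FusionResult: 15 proposals fused (k/s = 0.5 )
#>   fused volume: 4878 mm^3
#>   weights: 0.0514 0.0573 0.0601 0.0605 0.0691 0.0678 0.0591 0.0546
#>            0.0673 0.0628 0.0884 0.0615 0.0716 0.0826 0.0859

head(similarityTable(res), 3)
#>   atlas_id       ncc roi_voxel_count margin_mm
#> 1  atlas01 0.2775191           41047        10
#> 2  atlas02 0.3898007           55054        10
#> 3  atlas03 0.4393482           47813        10

dice(fusedMask(res), ens$truth)          # 0.832
mean(ens$manifest$dsc_to_truth)          # 0.662
maskVolume(fusedMask(res))               # 4878 mm^3
```

The fused mask overlaps the ground truth better than the average
individual proposal (DSC 0.832 vs 0.662), and its volume (4878 mm³) is
smaller than the average proposal volume (6234 mm³): averaging distance
maps emphasises the central region common to most proposals at the
expense of the peripheral parts.

The same pipeline is available from a shell through the wrapper installed
at `system.file("scripts", "atlasfuse", package = "AtlasFuse")`:

```sh
atlasfuse simulate --n 15 --seed 42 --out sim/
atlasfuse fuse --target sim/target.nii.gz --manifest sim/manifest.csv \
               --k-over-s 0.5 --margin-mm 10 \
               --out fused.nii.gz --report fusion.json
atlasfuse evaluate --reference sim/truth.nii.gz \
                   --candidates fused=fused.nii.gz --out eval.csv
atlasfuse weights --similarities 0.9,0.8 --k-over-s 0    # 0.5 0.5
```

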