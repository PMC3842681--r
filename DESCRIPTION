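Package: AtlasFuse
Title: Probabilistic Weighting Fusion of Multi-Atlas Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-atlas label fusion for radiotherapy structure
    segmentation by probabilistic weighting fusion (PWF): deformed atlas
    segmentations are combined by weighted superposition of signed
    Euclidean distance maps, with per-atlas weights derived from the
    normalized cross-correlation between the target image and each
    deformed atlas image over the structure plus a uniform dilation
    margin, governed by a single k/s parameter. Includes evaluation
    metrics (Dice similarity coefficient, structure volume, volume
    ratio), NIfTI and MetaImage volume I/O, and a synthetic phantom and
    deformation-ensemble generator that stands in for deformable
    registration so the whole pipeline can be exercised without clinical
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    pracma,
    jsonlite,
    optparse,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
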