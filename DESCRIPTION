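Package: hippoboost
Title: Hippocampus Segmentation by Boosted Voxel Classification with Random Undersampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fully automated segmentation of the hippocampus from co-registered
    structural MRI volumes by voxelwise classification. Implements a
    confidence-rated boosting classifier with per-round random undersampling of
    the majority (background) class (RUSBoost), a 315-dimensional per-voxel
    feature space (3D Haar-like filters, Haralick texture statistics on gray
    level co-occurrence matrices, directional gradients and voxel positions),
    restriction of the classification to a training-derived reduced volume of
    interest, segmentation overlap metrics (Dice, precision, recall, relative
    overlap), volume-agreement statistics, a synthetic 3D phantom generator for
    end-to-end testing without any image download, minimal NIfTI-1 input and
    output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
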