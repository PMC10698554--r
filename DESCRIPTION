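Package: jcps
Title: Joint 2D-3D Cross-Pseudo Supervision for Carotid Vessel Wall Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Coarse-to-fine semi-supervised segmentation of the carotid
    vessel wall in black-blood MR volumes where only a fraction of slices
    carry manual labels. Provides a synthetic black-blood vessel phantom
    generator, vascular center-of-gravity positioning with centroid-track
    repair, a dual-task (classification plus signed-distance regression)
    coarse network, 2D and 3D cross-pseudo-supervised fine networks with
    pseudo-label and inter-slice continuity losses, patch cropping and
    overlapping sliding-window chunking with probability stitching, and the
    challenge-style evaluation suite (Dice, area differences, normalized
    wall index difference, radius-normalized Hausdorff distances, and the
    composite quantitative score). Networks are small convolutional models
    with built-in reverse-mode gradients so the full pipeline runs
    deterministically on a single CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    png,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
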