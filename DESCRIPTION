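Package: clearcount
Title: Volumetric Quantification of Dopaminergic Structures in Cleared
    Whole-Mount Brain Light-Sheet Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for 3D morphometric quantification of tyrosine
    hydroxylase (TH) positive structures in tissue-cleared, light-sheet
    imaged whole-mount mouse brains. Provides segmentation of TH+
    structures by intensity and voxel size with shape-based exclusion of
    vessel artifacts, counting of dopaminergic perikarya inside reference
    cuboids via automatically generated arrays of non-overlapping
    measuring spheres, a slab-intersection "pathway unit" statistic for
    the abundance of mesotelencephalic fascicles, batch-stratified
    permutation tests for group comparisons, and a fully seeded synthetic
    phantom generator with ground truth so that every stage of the
    pipeline can be validated without access to real specimens.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    tiff,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
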