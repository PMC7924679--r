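Package: protex
Title: Image-Based Texture Features from Protein Tertiary Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Generates image-based feature vectors from protein tertiary
    structures by rendering the pairwise alpha-carbon (or all-atom) Euclidean
    distance matrix as a grayscale image and summarising its texture with
    local binary pattern (LBP) histograms, Gabor-filtered LBP histograms and
    two block filters (separate-row-multiplication and
    neighbor-block-subtraction) followed by uniform LBP histograms, plus
    atom-composition and bond features read directly from the coordinates.
    Includes SMOTE oversampling restricted to training folds, a stratified
    cross-validation harness over standard classifiers for structural-class
    prediction, a similarity-based nearest-neighbour model for protein-ligand
    binding prediction with per-category distance thresholds and majority
    voting, and generators for synthetic PDB-format structures and planted
    binding datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    class,
    e1071,
    randomForest,
    rpart
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    png,
    jsonlite,
    optparse
Config/testthat/edition: 3
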