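Package: metradsp
Title: Pelvic Lymph Node Treatment Response Assessment from Segmentation Masks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A segmentation-agnostic toolkit for MET-RADS-P style treatment
    response assessment of pelvic lymph nodes. Given 3D node segmentation
    masks (NIfTI label volumes) at baseline and follow-up, the package
    computes RECIST-style short- and long-axis diameters per node, classifies
    nodes into MET-RADS-P size categories (target, nontarget,
    nonpathological), matches nodes across timepoints, derives per-category
    CR/PR/SD/PD response calls, and evaluates agreement between two
    segmentation or assessment sources with Dice similarity, volumetric
    similarity, Bland-Altman limits of agreement, Cohen's kappa and
    accuracy statistics. A synthetic-phantom module generates label-volume
    cohorts with known geometry and known response trajectories for
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    stats,
    utils,
    yaml
Suggests: e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
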