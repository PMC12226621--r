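Package: vesselreg
Title: Multistage 3D-2D Registration of Cerebral CTA to DSA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rigid 3D-2D registration of cerebral computed tomography
    angiography (CTA) volumes to 2D digital subtraction angiography (DSA)
    projections. Implements a multistage pipeline: a convolutional network,
    trained on self-synthesized perturbed digitally reconstructed radiograph
    (DRR) pairs of vein segmentations, regresses an initial pose; two
    iterative differentiable-rendering refinement stages then maximize
    normalized cross-correlation against the DSA vessel segmentation and
    mutual information against the DSA minimum-intensity projection. Includes
    SE(3) pose machinery with geodesic training losses, a differentiable
    fixed-step DRR renderer with analytic pose gradients, vein isolation by
    morphology and connected components, a synthetic cerebral-vessel phantom
    generator for training and testing without patient data, and the full
    evaluation methodology (mean projection error, capture-range histograms,
    success rates, reader-preference tallies with exact signed-rank tests).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    png,
    tiff,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
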