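Package: gradUQ
Title: Post Hoc Region-Wise Uncertainty Quantification for Segmentation
    Models via Local Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assigns a per-region uncertainty score to the output of a
    trained semantic segmentation model without retraining it or changing
    its predictions. For each connected component of the predicted label
    map, a differentiable regional target (the voxel-averaged KL divergence
    of the predicted-class softmax probabilities against a uniform
    reference, or the regional mean probability) is backpropagated through
    the network, and the L1 norm of the gradients on selected decoder
    convolutional blocks yields the Local Gradients score. Scores are
    normalized by the 95th percentile of a low-uncertainty calibration set
    so that all measures share a common, direction-aligned scale. The
    package also provides the non-gradient baseline measures, image
    degradation operators (additive Gaussian noise, speckle noise, Gaussian
    smoothing) with sweep bookkeeping, region extraction, matching and
    truth-labelling utilities, false-positive-filtering metrics (ROC AUC,
    FPR95, rank tests), a decoder-block sensitivity sweep, seeded synthetic
    lesion phantoms, and a tiny trainable encoder-decoder segmentation
    network so every experiment runs end-to-end on a laptop CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'containers.R'
    'calibration.R'
    'degradations.R'
    'regions.R'
    'utils.R'
    'targets.R'
    'unet.R'
    'gradients.R'
    'evaluation.R'
    'gradUQ-package.R'
    'nifti.R'
    'synthetic.R'
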