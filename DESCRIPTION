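Package: multiseg
Title: Multimodal MRI Tissue Segmentation with Gaussian Mixture Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Registration-free multichannel brain tissue segmentation.
    Voxel intensities from co-registered MRI contrasts (T1-weighted,
    FLAIR, R2* relaxation-rate maps) are modeled as per-class multivariate
    Gaussian mixtures fitted by expectation-maximization, with optional
    spatial tissue priors and polynomial bias-field correction. Includes
    log-linear R2* estimation from multi-echo magnitude series,
    Bhattacharyya-distance quantification of tissue-class separability, a
    synthetic multi-contrast phantom generator with ground truth
    (dura sheets, vessels, connective tissue, susceptibility dropout), and
    comparison metrics (probability-map differences, compartment volumes,
    Dice, confound leak rates) for unimodal versus multimodal segmentations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'volume.R'
    'relaxometry.R'
    'phantom.R'
    'comparison.R'
    'pipeline.R'
    'segmentation.R'
    'separation.R'
    'utils.R'
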