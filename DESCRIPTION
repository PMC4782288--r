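Package: xenovasc
Title: Quantitative Vascular Phenotyping of Tumor Xenografts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the vascular phenotype of tumor xenografts
    across imaging modalities: semi-quantitative perfusion metrics (initial
    area under the enhancement curve, enhancing-voxel fraction) from dynamic
    contrast-enhanced MRI, three-dimensional vascular morphometry (Hessian
    vesselness segmentation, fractional blood volume, local-thickness vessel
    calibers, distance-to-nearest-vessel maps) from micro-CT angiography,
    double-stain immunohistochemistry quantification (HSV threshold
    segmentation, marker-based watershed nucleus separation, proliferating
    endothelial cell density, pericyte-negative vessel fraction), PLS-DA
    chemometrics of HR MAS MR spectra with VIP scores and permutation
    testing, and a nonparametric group-comparison layer (exact Mann-Whitney
    U, median +/- MAD). Synthetic phantom generators with exact ground truth
    support validation of every stage, and a study pipeline composes the
    stages into a two-arm treatment-versus-control report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    EBImage,
    RNifti,
    tiff,
    png,
    jsonlite,
    yaml,
    minpack.lm,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'utils.R'
    'microct.R'
    'dcemri.R'
    'histology.R'
    'spectra.R'
    'plsda.R'
    'stats.R'
    'synth-vascular.R'
    'synth-dce.R'
    'synth-histology.R'
    'synth-spectra.R'
    'synth-study.R'
    'pipeline.R'
    'figures.R'
    'io.R'
    'xenovasc-package.R'
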