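Package: prostatlas
Title: Statistical Voxelised Atlas Construction for Prostate Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds statistical, voxelised biological atlases of the prostate
    from co-registered histology-derived data. Provides morphological,
    linear and probabilistic interpolation of sparsely annotated axial
    slices; construction of a consensus reference geometry from
    principal-moment-aligned cohort contours; distance-preserving deformable
    registration (log-domain symmetric-forces demons driven by normalised
    distance maps, with an optional pinned-boundary substructure stage);
    and voxel-level statistical models of tumour probability and cell
    density, including kernel-density-based Kullback-Leibler model
    selection between normal and log-normal density models. A synthetic
    phantom cohort generator with known ground truth supports end-to-end
    validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
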