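Package: voxelight
Title: Searchlight Morphometry and Longitudinal Decline Mapping for Binary Exposures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for detecting, constraining, and longitudinally tracking
    brain-structural correlates of a binary exposure in aging cohorts: propensity
    score matching with balance diagnostics, covariate-adjusted voxel-wise group
    contrasts with false discovery rate correction and cluster extraction,
    searchlight multivoxel pattern classification (spherical neighborhoods, PCA
    feature extraction, cross-validated linear support vector machines) with
    region constraining, per-voxel prediction of cognitive composites with a
    permutation null, per-subject annual gray-matter decline-rate maps with
    atlas aggregation, product-of-coefficients mediation, and a two-level
    growth model of cognitive decline. Includes a synthetic volumetric cohort
    generator with planted effects so every stage has a ground-truth recovery
    test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    e1071,
    lme4,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
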