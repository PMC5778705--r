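Package: cochmetric
Title: Automated Atlas-Based Cochlear A-Value and Duct-Length Measurement
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Automated measurement of the cochlear A-value from 3D CT volumes
    by atlas-based registration. A fiducial-bearing atlas is aligned to a
    target scan through a three-stage cascade (closed-form landmark rigid
    fit, 12-parameter affine, cubic B-spline free-form deformation) driven
    by normalized cross-correlation; the atlas round-window and basal-turn
    fiducials are propagated through the recovered transform chain and their
    distance reported as the A-value, from which cochlear duct length is
    estimated via configurable linear equations. Includes volume and
    fiducial I/O (NIfTI, NRRD, MetaImage, CSV/FCSV), a synthetic
    cochlea-phantom generator with analytic ground truth for validation,
    and the agreement-statistics battery (absolute percentage difference,
    Shapiro-Wilk, Wilcoxon matched pairs, Spearman correlation,
    Bland-Altman with a clinical acceptance band).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
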