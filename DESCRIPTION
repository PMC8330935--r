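Package: ccfdq
Title: Choriocapillaris Flow-Deficit Quantification for En-Face OCTA
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies choriocapillaris (CC) perfusion from en-face
    swept-source OCT angiography slabs. Implements structural-signal
    compensation, Phansalkar auto-local thresholding at the standard
    15-pixel and size-adjusted radii, particle-style flow-deficit (FD)
    detection with an intercapillary-distance size filter, and FD%
    measurement in four 1x1 mm corner sectors. A statistical layer fits
    linear mixed models for FD%, mixed logistic models for the visibility
    of large choroidal vessels (LCV) as a function of choroidal thickness
    (CT), and a Youden-index CT cutoff with cluster-adjusted confidence
    intervals. A seeded synthetic OCTA scene generator provides cohorts
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    EBImage,
    lme4,
    lmerTest,
    emmeans,
    tiff,
    png,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr
Config/testthat/edition: 3
biocViews: Visualization, Preprocessing, Classification
RoxygenNote: 7.3.3
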