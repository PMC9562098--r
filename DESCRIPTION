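Package: ridgemetry
Title: Quantification of the Fibrovascular Ridge in Retinopathy of
    Prematurity from Volumetric OCT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to measure the axial thickness of the fibrovascular
    ridge at the vascular-avascular junction in retinopathy of
    prematurity (ROP) from volumetric optical coherence tomography
    (OCT). Provides en face projections and adjacent B-scan averaging,
    curved-strip extraction of A-scan columns along a traced ridgeline,
    automated segmentation of the retinal pigment epithelium and inner
    ridge surface, and the top-10-maxima summary of pixelwise axial
    thickness. Includes a synthetic OCT phantom generator with ground
    truth for validation, and the clustered statistical analyses used
    for this biomarker: grader-label adjudication and agreement
    (percent agreement, weighted kappa, Pearson r), generalized
    estimating equations for stage-conditional thickness means,
    Spearman stage-thickness correlation, test-retest repeatability
    (intraclass correlation, coefficient of variation), and pre/post
    treatment windowed comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    ggplot2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Retina, Visualization, Preprocessing, StatisticalMethod
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'gee.R'
    'phantom-params.R'
    'phantom.R'
    'stats.R'
    'pipeline.R'
    'trace.R'
    'thickness.R'
    'volume-io.R'
    'volume.R'
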