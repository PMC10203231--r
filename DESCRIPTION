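Package: cvrcoupling
Title: Cerebrovascular Reactivity Mapping and Task-BOLD Coupling Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates cerebrovascular reactivity (CVR) from breath-hold and
    CO2-inhalation BOLD fMRI and quantifies the linear coupling between CVR and
    task-evoked BOLD response magnitude across atlas-defined cortical regions.
    Provides mass-univariate general linear model fitting with contrast t- and
    percent-signal-change maps, ramp-times-respiratory-response-function
    breath-hold modelling with staggered-onset lag selection and canonical-HRF
    fallback, end-tidal CO2 extraction and cross-correlation shift optimization
    for gas-challenge CVR in percent BOLD per mmHg, atlas ROI aggregation with
    outlier filtering, per-region regressions under false-discovery-rate
    control, and group-level analyses with voxel-wise or ROI-level vascular
    covariate correction. A synthetic-data module generates atlas-labelled
    BOLD phantoms with known regional CVR and known CVR-to-task coupling so
    every stage is testable against ground truth.
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
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'kernels.R'
    'glm.R'
    'breathhold.R'
    'utils.R'
    'group.R'
    'roi.R'
    'gas.R'
    'paradigms.R'
    'phantom.R'
    'simulate.R'
    'io.R'
    'config.R'
    'cli.R'
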