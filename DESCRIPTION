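Package: fcpipe
Title: Motion-Censored Functional Connectivity Analysis with Synthetic BOLD Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end resting-state functional-connectivity pipeline for
    comparing developmental cohorts: framewise-displacement motion censoring,
    voxelwise nuisance regression with tissue confounds and simultaneous
    discrete-cosine bandpass filtering, optional global signal regression,
    parcellation-based ROI and network connectivity (within-network means,
    between-network synchrony, homotopic interhemispheric pairs), and
    covariate-adjusted group inference with Benjamini-Hochberg false discovery
    rate control. Includes a synthetic BOLD cohort generator with planted
    network-level group effects, group-dependent motion spikes, tissue confound
    signals and a shared global component, so every stage of the pipeline can
    be validated by parameter recovery against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    Matrix,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    signal,
    optparse
Config/testthat/edition: 3
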