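Package: cvrmap
Title: Cerebrovascular Reactivity Mapping and Two-Time-Point Brain Volumetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for BOLD-MRI cerebrovascular reactivity (CVR)
    mapping against stepped end-tidal CO2 forcing, and for paired structural brain
    volumetry. Reduces mouth-sampled respiratory gas and flow traces to per-breath
    end-tidal values, computes oxyhemoglobin saturation from end-tidal O2 via the
    Severinghaus equation, time-aligns end-tidal regressors to the BOLD series by
    cross-correlation, fits a voxelwise general linear model with a nuisance
    saturation regressor, converts parameter estimates to CVR maps in percent per
    mmHg, and thresholds z-statistic maps with a resel-based multiple-comparison
    correction. Regional summaries dichotomize atlas structures into positive- and
    negative-CVR compartments that are carried to follow-up for repeated-measures
    analysis. Structural tools provide Gaussian-mixture tissue segmentation,
    edge-displacement percent brain volume change, and lesion counting. Synthetic
    gas-trace, BOLD and structural phantom generators with known ground truth make
    every stage testable without acquired data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    purrr,
    RNifti,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
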