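Package: blockmvpa
Title: Block-Design Task fMRI Simulation, GLM Contrasts, Conjunction ROIs
    and Multi-Voxel Pattern Analysis
Version: 0.1.0
Authors@R: person("Analysis", "Pipeline", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates block-design BOLD fMRI cohorts with a known ground
    truth (hemodynamic task responses, low-frequency drift, motion-coupled
    nuisance and AR(1) noise), and analyses them with the standard
    task-fMRI workflow: subject-level general linear models with
    discrete-cosine high-pass regressors and AR(1) prewhitening, contrast
    t-maps, group one-sample t-tests with sign-flip permutation
    cluster-level family-wise error control, conjunction-defined shared
    regions of interest, paired mean-activation-level comparisons, and
    two-step-normalized multi-voxel pattern analysis with block-grouped
    cross-validated linear max-margin classification. Includes stimulus
    norming utilities (action-consistency ratios and familiarity-based
    selection), plain NIfTI-1 and BIDS-style events TSV input/output, and
    an end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
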