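Package: adsubtype
Title: Norm-Based Subtyping of Regional Brain Atrophy in Alzheimer's Disease
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Classifies Alzheimer's disease patients into four atrophy
    subtypes (both impaired, hippocampal atrophy only, cortical atrophy
    only, both spared) from FreeSurfer-style regional brain volumes.
    Regional volumes are scaled by intracranial volume, standardized
    against age- and gender-specific normative tables built from
    cognitively normal subjects with overlapping age stratification, and
    thresholded at Z < -1.0. Includes the downstream group comparisons
    (ANOVA/ANCOVA, chi-square, Kruskal-Wallis and Mann-Whitney tests for
    CSF biomarkers, linear mixed models with random intercepts for
    2-year cognitive trajectories) and a synthetic ADNI-like cohort
    generator so the full pipeline is testable without access-controlled
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
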