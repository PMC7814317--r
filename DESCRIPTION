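Package: weibullnet
Title: Weibull Degree Distributions in Voxel-Level Functional Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction of voxel-level resting-state functional connectivity
    graphs, maximum-likelihood fitting and comparison of discrete heavy-tailed
    degree-distribution models (power law, power law with exponential cutoff,
    and Weibull), and group-level statistics on the Weibull shape parameter.
    Includes a synthetic-cohort generator with known distributional ground
    truth so the whole pipeline (graph construction, model fitting,
    Vuong-style model comparison, FDR-corrected group and cognition GLMs)
    can be exercised and calibrated end to end without external imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
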