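Package: vpdlim
Title: Quantitative Photosynthetic Limitation Analysis Across Vapour Pressure Deficit Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for partitioning photosynthetic limitation into stomatal, mesophyll and
    biochemical components across vapour pressure deficit (VPD) gradients from steady-state
    leaf gas exchange and chlorophyll fluorescence. Implements a Farquhar-von Caemmerer-Berry
    (FvCB) steady-state leaf simulator with known ground truth, the variable-J estimator of
    mesophyll conductance, carboxylation-efficiency and FvCB capacity (Vcmax, Jmax) fitting,
    Laisk-style two-light estimation of day respiration and the photocompensation point,
    soil-plant-atmosphere water potential analysis, and the linear, logarithmic and
    exponential VPD-response regressions used to summarise such experiments, chained into a
    reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
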