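Package: rtrobust
Title: Daily Robustness-Band Evaluation for Proton Therapy Plans
Version: 0.1.0
Authors@R: person("rtrobust", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to assess day-to-day robustness of intensity-modulated
    proton therapy plans for head-and-neck targets. Builds min-max bands of
    expected dose-volume histogram (DVH) metrics under setup (e.g. 3 mm vs
    5 mm) and proton range (e.g. 3.5 percent) uncertainty scenarios, evaluates
    per-fraction DVH metrics (D95, V100, OAR max/mean) against those bands,
    and computes fractional dose and volumetric deviation statistics with
    cohort-level Student's t comparisons. Ships a synthetic phantom cohort
    with an analytic proton-like dose model (lateral Gaussian times a
    spread-out-Bragg-peak depth profile with distal falloff) so the full
    pipeline runs with no external planning-system data; externally computed
    dose grids, masks and shift logs can be imported instead.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
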