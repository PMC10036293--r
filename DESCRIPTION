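Package: wnorm
Title: Normative W-Score Modelling of Regional Brain MRI Measures
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits per-region normative linear regression models in healthy
    controls (adjusting regional grey matter volumes and white matter
    diffusion indices for age, sex, total intracranial volume and scanner
    type), converts mutation-carrier measures to covariate-adjusted
    w-scores, classifies regions as normal or abnormal against control
    percentile cut points with modality-aware direction, builds group-level
    percentile-band abnormality maps with bootstrap percentile confidence
    intervals, and compares baseline to 12-month clinical progression
    within normal and abnormal strata using an exact Wilcoxon signed-rank
    test with small-sample exclusion rules. Includes a synthetic multi-site
    cohort generator emulating a genetic frontotemporal dementia study
    population so the full pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
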