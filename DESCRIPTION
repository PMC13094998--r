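Package: kanoneeds
Title: Kano Model Needs Assessment for Paired Likert Surveys
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies survey needs with the Kano two-dimensional model from
    paired positive/negative five-point Likert items, computes better (SI) and
    worse (DSI) coefficients, satisfaction sensitivity, centroid-based quadrant
    classification and priority rankings, compares demographic subgroups by
    chi-square tests, and summarises Delphi expert consultations (Kendall's W
    with mid-rank ties, authority coefficients). Includes questionnaire
    screening, reliability/validity statistics (Cronbach's alpha, KMO,
    Bartlett's sphericity), a synthetic respondent generator for pipeline
    validation, and CSV report writers, with a bundled reference profile from
    a needs assessment of grassroots disease-control centres.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ggplot2,
    rlang,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    MASS,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
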