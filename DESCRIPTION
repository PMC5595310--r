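Package: cticorrect
Title: Model-Based Correction of the Community Temperature Index
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes the community temperature index (CTI), an
    abundance-weighted mean of species' temperature preferences used as a
    climate-change indicator, and a model-based variant that removes the
    year-to-year abundance variation attributable to confounding species
    attributes (habitat preference, commercial exploitation, body size)
    before the index is calculated.  The correction fits a panel regression
    of log abundance indices on year-by-attribute interactions with AR(1)
    errors and sum-to-zero species random effects, then predicts abundances
    with the non-temperature year interactions excluded.  Includes a
    population time-series simulator for validating the correction under
    controlled trait covariation and observation error, diagnostics for
    attribute covariation and long-term trend effects, quartile mechanism
    analysis, and loess trend smoothing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    nlme,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
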