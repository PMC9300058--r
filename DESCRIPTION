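Package: branta
Title: Gompertz Growth Analysis for Barnacle Goose Goslings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of postnatal growth in barnacle goose (Branta
    leucopsis) goslings across breeding colonies spanning the Arctic to
    the temperate zone. Implements fixed-endpoint Gompertz growth curves
    (hatch size and adult asymptote pinned a priori) with nested
    cohort/nest random effects on the growth coefficient, fitted by
    Laplace-approximated maximum likelihood on either an age-in-days or
    an accumulated-daylight time axis; population contrasts via dummy
    coding; civil-twilight daylight and accumulated photoperiod from
    colony coordinates; residual hatch-date analysis with linear mixed
    models and backward AIC selection; haldane rates of phenotypic
    change; and a synthetic-data generator emulating the three study
    colonies for parameter-recovery simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    geosphere,
    nlme,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
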