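Package: qale
Title: Quality-Adjusted Life Expectancy by the Sullivan Method
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for estimating quality-adjusted life expectancy (QALE)
    and dimension-specific healthy life expectancies from EQ-5D-5L survey
    data and age-specific mortality rates. Provides EQ-5D-5L index-value
    scoring with explicit value-set tables, survey-weighted population
    norms with Kish effective sample sizes, non-abridged period life
    tables with an open age group at 100, Sullivan health expectancies
    with EURO-REVES style standard errors and Z-score comparisons, the
    Nusselder-Looman decomposition of changes in QALE into mortality and
    disutility effects, and a synthetic-data generator (Gompertz-Makeham
    mortality, ordered-probit EQ-5D responses with Gaussian-copula
    dependence) with exact population norms for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
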