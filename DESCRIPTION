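Package: strawpoly
Title: Response-Surface and Neural-Network Modelling of Sugarcane Straw
    Polyphenols
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models how biotic and abiotic harvest factors (collection date,
    variety, geographic area, borer infection level, harvest number) shape
    the polyphenol-class content (hydroxybenzoic acids, hydroxycinnamic
    acids, flavones) and antioxidant capacity (ABTS and DPPH IC50) of
    sugarcane straw extracts.  Provides coded-factor second-order
    response-surface regression with ordinary least squares, Derringer
    desirability multi-response optimisation over realizable harvest
    conditions, single-hidden-layer perceptron regression trained by BFGS
    with Garson connection-weight sensitivity analysis, and a quantitative
    RSM-versus-ANN comparison by coefficient of determination and root mean
    square error.  Ships transcribed study tables as plain-text fixtures and
    a seeded synthetic-surface generator so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
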