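Package: bnetscore
Title: Net Ion-Channel Block Scoring for Torsadogenic Risk Screening
Version: 0.1.0
Authors@R:
    person("PIPET", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes net multi-ion-channel block scores (Bnet) for
    torsades de pointes (TdP) risk screening from patch-clamp
    concentration-response summaries: Hill-equation fractional block of
    IKr, INaL, ICaL and INa at configurable multiples of the unbound
    Cmax, a dynamic-hERG variant parameterised by dynamic IC50 and
    maximal inhibition, and the ranking-performance statistics (ROC AUC
    on risk dichotomies, univariable logistic likelihood-ratio
    chi-square, Pearson r-squared, two-sample t-test) used to judge such
    metrics against CiPA-style three-level risk labels. Includes a
    seeded synthetic drug-panel generator, a long-format CSV data model,
    a packaged hERG literature table for the 16 CiPA validation drugs,
    and a command-line interface (score, evaluate, simulate).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
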