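Package: vabpcea
Title: Cost-Effectiveness Model for Ceftolozane/Tazobactam Versus Meropenem in Ventilated HABP/VABP
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A hybrid decision-tree plus Markov cohort model for the
    cost-effectiveness of ceftolozane/tazobactam versus meropenem in
    ventilated hospital-acquired and ventilator-associated bacterial
    pneumonia from the Japanese healthcare-payer perspective. The acute
    phase is an explicit two-line treatment decision tree (first-line
    antibiotic, second-line addition of amikacin) with component-wise
    costing from the national fee schedule; survivors are propagated
    through a discrete-time three-state Markov cohort model with
    age-dependent background mortality and discounting. Provides base-case
    evaluation (costs, QALYs, ICER, net monetary benefit), one-way
    sensitivity analysis with tornado ordering, probabilistic sensitivity
    analysis with cost-effectiveness plane and acceptability curves,
    configuration-file round-tripping, and synthetic generators for the
    life table and two-arm trial outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
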