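Package: fallscea
Title: Efficiency and Equity Evaluation of Community-Based Falls Prevention Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-level annual-cycle simulation of falls, frailty
    progression and care pathways in community-dwelling adults aged 60 and
    over, with a societal cost-utility layer (dominance/extended-dominance
    frontier, ICERs, net-benefit measures), probabilistic sensitivity
    analysis (CEAC/CEAF), and distributional cost-effectiveness analysis
    across socioeconomic-status quartiles using Atkinson and Kolm
    equally-distributed-equivalent net health benefit. Includes a synthetic
    default parameterisation, eight pathway scale-up strategies, and
    plus/minus 20 percent alternative scenario analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
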