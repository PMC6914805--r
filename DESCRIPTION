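Package: eggtol
Title: Tolerance Inheritance Analysis for Interval-Censored Egg-Mass Bioassays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of time-to-death bioassays of amphibian
    egg masses exposed to lethal contaminant levels. Provides a Mendelian
    single-locus simulator of tolerance under five dominance modes (dominant,
    recessive, overdominant, underdominant, incompletely dominant), maximum
    likelihood estimation of lethal times (LT25/LT50/LT75) from interval
    censored deaths under a probit model on log10 time, per-mass sensitivity
    classification and relative spread statistics, bimodality detection by
    censored normal mixtures, recessivity categories, and cohort-level
    evaluation of which inheritance mode best explains the observed tolerance
    distribution.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
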