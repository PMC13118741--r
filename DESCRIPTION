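Package: pemosi
Title: Mechanistic PK/PD Modelling of Schedule-Dependent Pemetrexed-Osimertinib Synergy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A quantitative systems pharmacology (QSP) PK/PD model of the
    schedule-dependent synergy between the antifolate pemetrexed and the
    third-generation EGFR inhibitor osimertinib in EGFR-mutant NSCLC
    xenografts. Couples two-compartment pharmacokinetics for both drugs to
    turnover models of folate metabolism and EGFR signalling and to an
    extended Simeoni tumour growth inhibition model with damage-driven EGFR
    feedback, G1-arrest gating of cytotoxicity and Bim-dependent apoptosis
    amplification. Includes in vitro to in vivo extrapolation (free-fraction
    potency correction, growth-rate scaling), stepwise calibration fitters
    (EGFR recovery, four-parameter logistic dose-response, mini tumour
    models, two-compartment PK, non-compartmental analysis and a
    bioequivalence-window DDI rule), dosing-interval comparison, Sobol
    global sensitivity analysis, Monte Carlo virtual-population objective
    response rate simulation, and synthetic-data generators with known
    ground truth for every calibration input.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    lhs,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
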