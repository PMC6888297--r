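Package: ampkswitch
Title: Dynamical Model of the AMPK-mTORC1-ULK1 Autophagy Switch
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ordinary-differential-equation model of the AMPK-mTORC1-ULK1
    regulatory triangle that controls autophagy induction, including the
    mTORC1-mediated inhibition of AMPK that closes a double negative
    feedback loop between the two nutrient/energy sensors. Each protein is
    represented as a Goldbeter-Koshland phosphorylation cycle. The package
    simulates treatment protocols (rapamycin, starvation, resveratrol,
    Compound C, siRNA silencing of ULK1 or TSC1/2, and staged
    combinations), locates steady states, scans one-parameter bifurcation
    diagrams with hysteresis detection, reduces the system to an AMPK-mTOR
    phase plane with nullclines, classifies simulated time courses into
    qualitative phenotype calls, scores them against a curated matrix of
    mutant phenotypes, calibrates rate constants against qualitative
    constraints, fits parameters to densitometry-style time courses, and
    generates synthetic immunoblot densitometry tables for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    grDevices,
    graphics,
    jsonlite,
    lhs,
    minpack.lm,
    stats,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
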