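# Calibrated default parameters for the AMPK-mTORC1-ULK1-ATG model.
# Rates in 1/min; Michaelis constants and totals dimensionless.
# kamtor (0.025 = half the hyper-activated 0.05) and the one-unit totals
# are structural; everything else was produced by qualitative-constraint
# calibration (see provenance).
kaA: 0.05
S: 1.0
kiA: 0.004
kiAU: 0.18
kiAM: 0.13
kamtor: 0.025
kiM: 0.015
kiMA: 0.03
kiMU: 0.009
kaUA: 0.04
kiU: 0.001
kiUM: 0.05
kaGU: 0.02
kaG0: 0.0005
kiG: 0.002
kiGM: 0.05
JaA: 0.01
JiA: 0.05
JaM: 0.01
JiM: 0.01
JaU: 0.05
JiU: 0.05
JaG: 0.05
JiG: 0.05
AT: 1.0
MT: 1.0
UT: 1.0
GT: 1.0
provenance:
  method: >-
    qualitative-constraint calibration (phenotype matrix, variant
    contrasts, physiological monostability, bistable stress window):
    analytic seeding of the Goldbeter-Koshland flux balances followed by
    constraint-guided refinement; reproduced by calibrate_parameters()
    with the shipped constraint battery (see analysis/01_calibrate.R)
  seed: 1
  constraint_battery: scenario_suite v1 (16 scenarios) + steady-state structure
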