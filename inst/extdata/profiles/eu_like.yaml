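# Illustrative European-style profile: higher CYP2D6 no-function
# haplotype frequency (PM ~ 5%), so the CYP2D6-PM-driven drugs
# (paroxetine, fluvoxamine, venlafaxine, aripiprazole, ...) have higher
# actionable fractions than under the QGP-like profile.
label: EU-like
cn_deletion_rate: 0.02
cn_duplication_rate: 0.01
frequencies:
  CYP2C19:
    "*1": 0.66
    "*17": 0.22
    "*2": 0.115
    "*3": 0.005
  CYP2D6:
    "*1": 0.52
    "*2": 0.15
    "*41": 0.07
    "*10": 0.02
    "*17": 0.01
    "*4": 0.19
    "*3": 0.025
    "*6": 0.015
  CYP2B6:
    "*1": 0.71
    "*6": 0.23
    "*4": 0.04
    "*18": 0.02
  CYP3A4:
    "*1": 0.935
    "*22": 0.06
    "*20": 0.005
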