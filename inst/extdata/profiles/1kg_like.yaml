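# Illustrative world-average-style profile: lower CYP2C19
# increased-function frequency than the QGP-like profile and a higher
# CYP2D6 decreased-function burden, so the modal non-standard TCA
# recommendation shifts to the 25%-starting-dose-reduction category.
label: 1KG-like
cn_deletion_rate: 0.015
cn_duplication_rate: 0.025
frequencies:
  CYP2C19:
    "*1": 0.78
    "*17": 0.10
    "*2": 0.10
    "*3": 0.02
  CYP2D6:
    "*1": 0.38
    "*2": 0.10
    "*10": 0.25
    "*41": 0.15
    "*4": 0.08
    "*3": 0.03
    "*6": 0.01
  CYP2B6:
    "*1": 0.62
    "*6": 0.28
    "*4": 0.07
    "*18": 0.03
  CYP3A4:
    "*1": 0.95
    "*22": 0.045
    "*20": 0.005
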