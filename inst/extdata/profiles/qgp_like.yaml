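# Illustrative Middle-Eastern-style profile: high CYP2C19
# increased-function frequency (CYP2C19-actionable fraction near 0.59,
# modal non-standard TCA category "alternative drug not metabolized by
# CYP2C19"), CYP2D6 no-function haplotype frequency 0.11 (PM ~ 1.2%
# without CN events), rare CYP3A4 poor metabolizers (~0.1%). Calibrated
# to published phenotype-percentage magnitudes only; not any cohort's
# actual allele frequencies.
label: QGP-like
cn_deletion_rate: 0.01
cn_duplication_rate: 0.03
frequencies:
  CYP2C19:
    "*1": 0.643
    "*17": 0.25
    "*2": 0.09
    "*3": 0.017
  CYP2D6:
    "*1": 0.50
    "*2": 0.14
    "*41": 0.15
    "*17": 0.06
    "*10": 0.04
    "*4": 0.08
    "*3": 0.02
    "*6": 0.01
  CYP2B6:
    "*1": 0.68
    "*6": 0.25
    "*4": 0.05
    "*18": 0.02
  CYP3A4:
    "*1": 0.967
    "*22": 0.03
    "*20": 0.003
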