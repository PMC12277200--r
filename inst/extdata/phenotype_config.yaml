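# Diplotype -> metabolizer phenotype translation.
#
# CYP2D6: activity-score bins (upper edges inclusive); score 0 -> PM,
# (0,1] -> IM (so a single functional copy, e.g. *1/*4 or *1/*5, is IM),
# (1,2.25] -> NM, >2.25 -> UM. Bin edges follow the consensus
# activity-score convention and live here, not in code, so revisions stay
# auditable.
#
# Categorical genes: unordered function-class pair -> phenotype, pair key
# with the two classes in sorted order joined by "+". Any uncertain-class
# allele yields Indeterminate (handled in code, not listed here). RM is a
# CYP2C19-only status.
cyp2d6_bins:
  - {max: 0, phenotype: PM}
  - {max: 1, phenotype: IM}
  - {max: 2.25, phenotype: NM}
  - {max: .inf, phenotype: UM}
pair_rules:
  CYP2C19:
    increased+increased: UM
    increased+normal: RM
    normal+normal: NM
    decreased+increased: NM
    no_function+normal: IM
    increased+no_function: IM
    decreased+normal: IM
    decreased+decreased: IM
    decreased+no_function: IM
    no_function+no_function: PM
  CYP2B6:
    increased+increased: UM
    increased+normal: NM
    normal+normal: NM
    decreased+increased: NM
    increased+no_function: IM
    decreased+normal: IM
    no_function+normal: IM
    decreased+decreased: PM
    decreased+no_function: PM
    no_function+no_function: PM
  CYP3A4:
    normal+normal: NM
    decreased+normal: IM
    no_function+normal: IM
    decreased+decreased: PM
    decreased+no_function: PM
    no_function+no_function: PM
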