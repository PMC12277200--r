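# Per-drug clinical actionability rules (CPIC / DPWG, evidence level 1A).
#
# Single-gene drugs: `actionable` lists the metabolizer phenotypes for
# which the guideline recommends a dose change or an alternative drug.
# Two-gene drugs carry a total recommendation matrix over the combined
# phenotype grid (Indeterminate excluded); a combination is actionable
# iff its category is not in `standard_categories`. Matrix keys are
# "<first-gene phenotype>+<second-gene phenotype>" in the order of
# `genes`. Only the category cells that are fixed by published guideline
# wording are load-bearing; the remaining cells are editable defaults.
#
# The paroxetine/vortioxetine actionable set {UM, PM} is a configured
# assumption (their guidelines are CYP2D6-based; the default follows the
# CPIC SSRI guideline).
drugs:
  citalopram_escitalopram:
    source: CPIC
    genes: [CYP2C19]
    actionable: [UM, RM, IM, PM]
  sertraline:
    source: CPIC
    genes: [CYP2C19, CYP2B6]
    standard_categories: [S, A]
    categories:
      A: >-
        Initiate therapy with recommended starting dose. If the patient
        does not adequately respond to recommended maintenance dosing,
        consider titrating to a higher maintenance dose or switching to a
        clinically appropriate alternative antidepressant not
        predominantly metabolized by CYP2C19 or CYP2B6.
      B: >-
        Initiate therapy with recommended starting dose. Consider a slower
        titration schedule and lower maintenance dose.
      C: >-
        Initiate therapy with recommended starting dose. Consider a slower
        titration schedule and lower maintenance dose than normal
        metabolizers.
      D: >-
        Consider a lower starting dose, slower titration schedule and 50%
        reduction of standard maintenance dose as compared to CYP2C19
        normal metabolizers, or select a clinically appropriate
        alternative antidepressant not predominantly metabolized by
        CYP2C19.
      E: >-
        Consider a lower starting dose, slower titration schedule and 25%
        reduction of standard maintenance dose as compared to CYP2B6
        normal metabolizers, or select a clinically appropriate
        alternative antidepressant not predominantly metabolized by
        CYP2B6.
      F: >-
        Consider a lower starting dose, slower titration schedule and 50%
        reduction of standard maintenance dose as compared to CYP2B6
        normal metabolizers.
      G: >-
        Select an alternative antidepressant not primarily metabolized by
        CYP2C19 or CYP2B6.
      S: Initiate therapy with recommended starting dose (standard care).
    matrix:
      UM+UM: A
      UM+NM: A
      UM+IM: A
      UM+PM: G
      RM+UM: A
      RM+NM: A
      RM+IM: A
      RM+PM: G
      NM+UM: S
      NM+NM: S
      NM+IM: C
      NM+PM: E
      IM+UM: B
      IM+NM: B
      IM+IM: C
      IM+PM: F
      PM+UM: D
      PM+NM: D
      PM+IM: D
      PM+PM: G
  paroxetine:
    source: CPIC
    genes: [CYP2D6]
    actionable: [UM, PM]
  fluvoxamine:
    source: CPIC
    genes: [CYP2D6]
    actionable: [PM]
  venlafaxine:
    source: CPIC
    genes: [CYP2D6]
    actionable: [PM]
  vortioxetine:
    source: CPIC
    genes: [CYP2D6]
    actionable: [UM, PM]
  amitriptyline:
    source: CPIC
    genes: [CYP2C19, CYP2D6]
    aliases: [clomipramine, doxepin, imipramine, trimipramine]
    standard_categories: [S]
    categories:
      A: Avoid amitriptyline use.
      B: Consider alternative drug not metabolized by CYP2C19.
      C: >-
        Avoid amitriptyline use. If amitriptyline is warranted, consider
        titrating to a higher target dose (compared to normal
        metabolizers).
      D: >-
        Avoid amitriptyline use. If amitriptyline is warranted, consider a
        50% reduction of recommended starting dose.
      E: Consider a 25% reduction of recommended starting dose.
      S: Initiate therapy with recommended starting dose (standard care).
    matrix:
      UM+UM: A
      UM+NM: B
      UM+IM: A
      UM+PM: A
      RM+UM: A
      RM+NM: B
      RM+IM: A
      RM+PM: A
      NM+UM: C
      NM+NM: S
      NM+IM: E
      NM+PM: D
      IM+UM: A
      IM+NM: S
      IM+IM: E
      IM+PM: A
      PM+UM: A
      PM+NM: B
      PM+IM: A
      PM+PM: A
  aripiprazole:
    source: DPWG
    genes: [CYP2D6]
    actionable: [PM]
  brexpiprazole:
    source: DPWG
    genes: [CYP2D6]
    actionable: [PM]
  haloperidol:
    source: DPWG
    genes: [CYP2D6]
    actionable: [PM, UM]
  risperidone:
    source: DPWG
    genes: [CYP2D6]
    actionable: [PM, UM]
  pimozide:
    source: DPWG
    genes: [CYP2D6]
    actionable: [PM, IM]
  zuclopenthixol:
    source: DPWG
    genes: [CYP2D6]
    actionable: [PM, IM, UM]
  quetiapine:
    source: DPWG
    genes: [CYP3A4]
    actionable: [PM]
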