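Package: pgxCohort
Title: Star-Allele Diplotyping, Metabolizer Phenotyping and
    Pharmacogenomic Actionability for Psychotropic Drug Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Cohort-scale pharmacogenomic actionability analysis for four
    cytochrome P450 genes (CYP2C19, CYP2D6, CYP2B6, CYP3A4). Assigns
    star-allele diplotypes from genotype-level VCF input with an optional
    CYP2D6 copy-number sidecar, translates diplotypes into metabolizer
    phenotypes (activity-score arithmetic for CYP2D6, categorical
    translation for the other genes), classifies samples as clinically
    actionable per psychotropic drug under CPIC/DPWG-style rule
    configurations including combined two-gene recommendation matrices for
    sertraline and tricyclic antidepressants, and compares actionable
    proportions between cohorts with two-proportion z-tests, odds ratios
    and Benjamini-Hochberg correction. Includes a Hardy-Weinberg cohort
    simulator with truth labels so every stage is testable without
    access-controlled genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
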