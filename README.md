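# pgxCohort

Cohort-scale pharmacogenomic actionability analysis for psychotropic
drugs, built around the four cytochrome P450 genes with CPIC/DPWG
prescribing guidelines: **CYP2C19, CYP2D6, CYP2B6 and CYP3A4**.

Population programs increasingly ask, for each drug with a level-1A
pharmacogenomic guideline, *what fraction of this population carries an
actionable genotype* — one for which the guideline recommends a dose
change or an alternative drug. Answering that requires a chain of steps
that this package implements end to end:

1. **Star-allele diplotyping** (`callCohort()`): each sample's two named
   haplotypes per gene are inferred from a genotype-level VCF. A
   candidate diplotype is an unordered allele pair (h₁, h₂) whose
   combined defining variants exactly reproduce the observed alternate
   dosage at every indexed position; ties are ranked by explained
   variants, then parsimony. CYP2D6 structural variation enters through a
   per-sample integer copy number (CN sidecar): CN 1 pairs the remaining
   allele with the deletion allele \*5, CN ≥ 3 assigns copy multiplicity
   (`*1x2/*4`) under a configurable duplication policy.
2. **Metabolizer phenotyping** (`phenotypeCohort()`): CYP2D6 uses the
   activity score AS = Σᵢ mᵢ·aᵢ over the diplotype's alleles (mᵢ = copy
   multiplicity, aᵢ = curated activity value), binned as
   AS = 0 → PM, 0 < AS ≤ 1 → IM, 1 < AS ≤ 2.25 → NM, AS > 2.25 → UM.
   The other genes translate the unordered pair of allele function
   classes through a configurable table (e.g. CYP2C19
   normal + increased → RM).
3. **Actionability classification** (`classifyCohort()`): per-drug rules
   (shipped as editable YAML) mark phenotypes or phenotype pairs as
   actionable. Sertraline uses the combined CYP2C19×CYP2B6
   recommendation matrix (categories A–G); the tricyclic antidepressants
   share a combined CYP2C19×CYP2D6 matrix (categories A–E).
4. **Population comparison** (`compareCohorts()`): per drug, a pooled
   two-proportion z-test (z² equals the uncorrected χ² on the 2×2
   table), Wald CI for p₁−p₂, cross-product odds ratio with Woolf CI
   (Haldane–Anscombe correction at zero cells), and Benjamini–Hochberg
   correction across the tested drugs.

Because population-scale genomes are access-controlled, the package
includes a first-class **Hardy–Weinberg cohort simulator**
(`simulateCohort()`) that draws diplotypes from configurable star-allele
frequency profiles (shipped: `qgp_like`, `1kg_like`, `eu_like`), writes
a genotype VCF plus CN sidecar, and keeps truth labels so every stage is
testable.

## Worked example

The package ships a three-sample cohort
(`inst/extdata/example_cohort.vcf` + CN sidecar; sample EX003 has a
CYP2D6 whole-gene deletion, CN = 1):

```r
library(pgxCohort)
tab <- readAlleleTable(system.file("extdata", "allele_definitions.tsv",
                                   package = "pgxCohort"))
calls <- callCohort(
  system.file("extdata", "example_cohort.vcf", package = "pgxCohort"),
  tab,
  cnSidecar = system.file("extdata", "example_cohort_cn.tsv",
                          package = "pgxCohort"))
ph <- phenotypeCohort(calls, tab)
subset(ph, sample_id == "EX003")
#>    sample_id    gene diplotype activity_score phenotype
#> 3      EX003  CYP2D6    *5/*41            0.5        IM
#> 6      EX003 CYP2C19     *1/*1             NA        NM
#> 9      EX003  CYP2B6     *6/*6             NA        PM
#> 12     EX003  CYP3A4     *1/*1             NA        NM
```

EX003 carries one decreased-function CYP2D6 allele over a deleted copy
(activity score 0.5 → intermediate metabolizer) and two
decreased-function CYP2B6 alleles (poor metabolizer). Its sertraline
recommendation therefore comes from the (CYP2C19 NM, CYP2B6 PM) cell:

```r
sertralineRecommendation("NM", "PM")$label
#> [1] "E"   # 25% maintenance-dose reduction vs CYP2B6 NM, or alternative
cls <- classifyCohort(ph, defaultDrugRules())
subset(cls, sample_id == "EX003" & actionable)
#>    sample_id           drug actionable category flagged
#> 6      EX003     sertraline       TRUE        E   FALSE
#> 21     EX003  amitriptyline       TRUE        E   FALSE
#> 36     EX003       pimozide       TRUE     <NA>   FALSE
#> 39     EX003 zuclopenthixol       TRUE     <NA>   FALSE
```

A full pipeline run (`runPipeline()`) writes diplotype, phenotype and
classification TSVs, a per-cohort actionability summary, category
histograms for the two-gene drugs, and — given two cohorts — a
comparison table with z, OR, raw and BH-adjusted p. The same stages are
exposed as a command line in `inst/scripts/pgx-cohort.R`
(`simulate | call | phenotype | classify | compare | landscape | run`).

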