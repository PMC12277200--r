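---
title: "pgxCohort: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pgxCohort: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxCohort)
```

# Scope and model

pgxCohort estimates, for a cohort of genotyped individuals, the
per-drug prevalence of *clinically actionable* pharmacogenomic status
for thirteen-plus psychotropic drugs whose prescribing guidelines (CPIC
or DPWG, evidence level 1A) key on four cytochrome P450 genes: CYP2C19,
CYP2D6, CYP2B6 and CYP3A4. The analysis chain is

star-allele diplotype → metabolizer phenotype → per-drug actionability
→ cohort summary and two-cohort comparison,

with every translation step expressed as editable configuration rather
than code, because the underlying curated knowledge (allele function
classes, activity values, score bins, guideline matrices) is revised
over time and a frozen copy must stay auditable.

## Diplotype calling from genotype-level input

Read-backed star-allele callers operate on alignments; pgxCohort
deliberately operates one level up, on a genotype VCF plus an optional
integer CYP2D6 copy number per sample (the "CN sidecar", standing in for
read-depth structural-variant evidence). This keeps the analysis surface
— diplotypes in, population statistics out — while remaining runnable on
desk-scale, shareable inputs.

A candidate diplotype for a gene is an unordered pair of named alleles
whose combined defining variants reproduce the observed alternate-allele
dosage *exactly* at every position in the allele table's variant index;
positions absent from the VCF count as homozygous reference. The
all-reference genotype therefore always yields (\*1, \*1), and a dosage
pattern that no pair can explain (e.g. three heterozygous singleton
variants) yields a no-call rather than a guess. Phased genotypes
constrain the assignment: a pair survives only if one orientation of its
two haplotypes matches every phased site.

When several pairs explain the data (unphased het–het sites), the
selection policy ranks by (1) total defining variants explained by
non-reference alleles, (2) fewest distinct non-reference alleles, (3)
lexicographic label order as a deterministic last resort. All
equally-scoring alternatives are preserved on the call
(`unphased_ambiguity` flag) rather than discarded — read-level tools
resolve these internally, but at genotype level the ambiguity is real
and should be visible. Calling is entirely deterministic.

### Copy number

Copy-number rewriting treats the diploid call as the base: CN 2 is
identity; CN 0 is \*5/\*5; CN 1 keeps one allele against \*5 — because a
hemizygous site presents as *homozygous* to a genotype caller, the
expected diploid base call is homozygous, and the simulator writes its
deleted-haplotype genotypes the same way. For CN ≥ 3 the extra copies
must be assigned to one allele of a heterozygous call, which
genotype-level data cannot resolve; the duplication policy (duplicate
the higher-activity allele by default; "lower" and "ambiguous" variants
available) is configurable precisely because published pipelines do not
state their choice, and any heterozygous rewrite is flagged
`cn_ambiguity`. Hybrid/fusion alleles are out of scope.

## Phenotype translation

CYP2D6 uses the activity score: the multiplicity-weighted sum of allele
activity values (deletion = 0). The shipped bins — 0 → PM, (0, 1] → IM,
(1, 2.25] → NM, > 2.25 → UM — follow the consensus convention in which a
single functional copy (score 1.0, e.g. \*1/\*4 or \*1/\*5) is an
intermediate metabolizer. The bins partition [0, ∞), so translation is
total; an uncertain-function allele makes the whole score, and hence the
phenotype, Indeterminate.

The categorical genes map the unordered pair of function classes through
per-gene rules. RM (rapid) is restricted to CYP2C19
(normal + increased); CYP2B6 and CYP3A4 have no RM in the shipped
config. A pair absent from the config is a hard error — translation
must never silently default.

Indeterminate samples are excluded from actionable numerators but kept
in denominators, so reported percentages are per total cohort.

## Guideline rules

Single-gene drugs carry an actionable phenotype set (e.g. fluvoxamine:
{PM}; haloperidol: {PM, UM}; zuclopenthixol: {PM, IM, UM}, which by
construction contains both the haloperidol and pimozide sets). Two
drugs use combined two-gene matrices: sertraline over CYP2C19×CYP2B6
(categories A–G) and the shared tricyclic rule over CYP2C19×CYP2D6
(categories A–E, with amitriptyline's rule reused for clomipramine,
doxepin, imipramine and trimipramine). Only the anchor cells whose
category is fixed by published guideline wording are treated as fixed
points in tests — e.g. (CYP2C19 PM, CYP2B6 PM) → G, (CYP2C19 RM,
CYP2D6 NM) → B, (CYP2C19 NM, CYP2D6 IM) → E; the remaining cells are
shipped defaults that a deployment can edit, and validation enforces
totality of every matrix over its phenotype grid.

Two design choices deserve a note. First, the sertraline matrix's
category A ("initiate recommended dose; act only if response is
inadequate") is classed as standard care: in the same cohort the
sertraline-actionable fraction must be able to fall below the
CYP2C19-actionable fraction, which is only arithmetically possible if
increased-function CYP2C19 statuses are not sertraline-actionable.
Second, for CYP2B6-PM combinations the default maps (CYP2C19 NM, PM) to
the 25%-reduction category E and reserves the 50%-reduction category F
for (CYP2C19 IM, PM); published text does not determine the E/F split
for every cell, so it lives in config.

## Statistics

Two-cohort comparison uses the pooled two-proportion z-test without
continuity correction, chosen so that z² equals the uncorrected χ²
statistic on the same 2×2 table — an identity the tests verify to
machine precision. The difference CI is Wald at a configurable level;
the odds ratio is the cross product with a Woolf log-scale CI and the
Haldane–Anscombe +0.5 correction (flagged) at zero cells. p-values are
never reported as exactly 0: they are floored at the smallest positive
double and flagged. Benjamini–Hochberg correction runs across the drug
list; `m` defaults to the number of drugs compared (14 in the shipped
rule set) and is configurable, and reports carry both the BH threshold
flag and a genome-wide (5×10⁻⁸) flag, since population studies commonly
report both tiers. Degenerate tables (both proportions 0 or 1) return
z = 0, p = 1 with a flag rather than NaN.

At very small counts the normal approximation is known to drift from
resampling nulls; the suite pins the z-test p to within 10% of a 10⁶
replicate parametric Monte-Carlo null on |p̂₁ − p̂₂| rather than to a
margin-conditioned permutation null, which answers a different
(conditional) question.

## The simulator: what it emulates, and what it does not

`simulateCohort()` draws two haplotypes per gene i.i.d. from a
frequency profile — Hardy–Weinberg random mating — then applies
independent per-haplotype CYP2D6 deletion/duplication events, writes an
unphased (optionally phased) VCF over the allele table's variants plus
the CN sidecar, and keeps truth diplotypes, truth phenotypes (computed
by the package's own phenotyper, so truth is self-consistent by
construction) and per-drug truth labels.

The three shipped profiles are *illustrative*: their allele frequencies
were chosen once so that the resulting phenotype mixtures match the
magnitude of published population percentages (CYP2D6 PM near 1.2%,
CYP3A4 PM near 0.1%, CYP2C19-actionable near 59% for the QGP-like
profile; a decreased-function-heavy CYP2D6 for the 1KG-like profile so
the modal non-standard TCA category flips from "alternative drug" to
"25% dose reduction"; a no-function-heavy CYP2D6 for the EU-like
profile). They are not estimates of any cohort's unpublished
frequencies. `profileFromPhenotypeTargets()` inverts HWE numerically
(deterministic Nelder-Mead over softmax-parameterised class
frequencies) when a user wants a profile hitting stated phenotype
targets; it reports its residual and refuses infeasible targets.

The simulator does **not** model linkage disequilibrium between genes,
population substructure or admixture, genotyping error, or novel/rare
alleles. Consequently, passing recovery tests show the *matching
algorithm* is correct on separable inputs — they do not show that real
cohorts are free of ambiguity: real allele definitions share variants,
and real CYP2D6 structural variation is richer than an integer copy
number. The packaged 490-allele table uses synthetic coordinates on
per-gene miniature contigs and pairwise variant-disjoint definitions;
overlap handling is exercised by dedicated small tables in the test
suite instead.

## Numerical and operational choices

* Coordinates are 1-based throughout (VCF POS convention); variant keys
  are `chrom:pos:ref:alt` strings. The loader records a declared build
  string; inputs must share it.
* Sub-alleles are collapsed to core alleles; the translation layer
  operates on core alleles only.
* VCF variants inside a gene region but absent from the allele index are
  ignored and counted; more than 5 such non-reference genotypes per gene
  per sample raises a possible-novel-allele warning.
* Identical genotype profiles within a cohort are called once and
  reused, so cohort size adds little beyond VCF parsing; the test suite
  and acceptance script run cohorts up to n = 14,354 (the published
  cohort's size) in minutes and use n = 500–10,000 for property checks,
  sizes at which binomial standard errors are small relative to the
  tested effects.
* The pipeline's run log contains stage counts only — no timestamps —
  so a whole report bundle is byte-identical under identical inputs and
  seed.
* Stochastic tests fix their seeds and state tolerances in units of the
  relevant binomial/Monte-Carlo standard error (typically 3–3.5 SE).

## Known limitations

Phenoconversion (inhibitor co-medication), substrate-specific activity
scores, dose arithmetic in mg, pediatric rules, read-level evidence and
CYP2D6 hybrid genes are out of scope. Phenotype translation reflects
the shipped configuration's snapshot of curated knowledge; deployments
should review the config against current guideline releases before
clinical use.
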