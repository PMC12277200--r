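#' @import methods
NULL

## Controlled vocabularies used throughout the package.

#' Supported pharmacogenes
#'
#' The four cytochrome P450 genes covered by the package: CYP2C19, CYP2D6,
#' CYP2B6 and CYP3A4. All allele tables, diplotype calls and rule
#' configurations are restricted to this set.
#'
#' @return Character vector of gene symbols.
#' @export
#' @examples
#' pgxGenes()
pgxGenes <- function() c("CYP2C19", "CYP2D6", "CYP2B6", "CYP3A4")

#' Allele function classes
#'
#' Curated function classes a star allele may carry: \code{normal},
#' \code{decreased}, \code{no_function}, \code{increased}, \code{uncertain}.
#'
#' @return Character vector of class labels.
#' @export
functionClasses <- function()
  c("normal", "decreased", "no_function", "increased", "uncertain")

#' Metabolizer phenotype labels
#'
#' Ultrarapid (UM), rapid (RM), normal (NM), intermediate (IM), poor (PM)
#' and Indeterminate. RM is used for CYP2C19 only.
#'
#' @param gene Optional gene symbol; when given, only the labels that gene
#'   can take (excluding Indeterminate) are returned.
#' @return Character vector of phenotype labels.
#' @export
phenotypeLevels <- function(gene = NULL) {
  if (is.null(gene))
    return(c("UM", "RM", "NM", "IM", "PM", "Indeterminate"))
  gene <- match.arg(gene, pgxGenes())
  if (gene == "CYP2C19") c("UM", "RM", "NM", "IM", "PM")
  else c("UM", "NM", "IM", "PM")
}

## ---------------------------------------------------------------------------
## AlleleTable

#' AlleleTable: indexed star-allele definitions
#'
#' Holds validated star-allele definitions for one or more of the four
#' supported genes, together with an inverted variant index mapping each
#' defining variant (a \code{chrom:pos:ref:alt} key) to the alleles that
#' contain it. Construct with [readAlleleTable()] or [newAlleleTable()].
#'
#' @slot alleles data.frame with columns \code{gene}, \code{allele},
#'   \code{function_class}, \code{activity} (numeric, \code{NA} when
#'   uncertain or not applicable) and list-column \code{variants}
#'   (character vectors of variant keys).
#' @slot variantIndex named list: variant key -> character vector of
#'   \code{"gene|allele"} identifiers.
#' @slot build Declared genome build label; inputs must share it.
#'
#' @name AlleleTable-class
#' @aliases AlleleTable
#' @exportClass AlleleTable
setClass("AlleleTable",
  representation(alleles = "data.frame", variantIndex = "list",
                 build = "character"))

validAlleleTable <- function(object) {
  msgs <- character()
  al <- object@alleles
  need <- c("gene", "allele", "function_class", "activity", "variants")
  if (!all(need %in% names(al)))
    return(paste("alleles slot must have columns",
                 paste(need, collapse = ", ")))
  if (!all(al$gene %in% pgxGenes()))
    msgs <- c(msgs, paste("unknown gene(s):",
                          paste(setdiff(unique(al$gene), pgxGenes()),
                                collapse = ", ")))
  if (!all(al$function_class %in% functionClasses()))
    msgs <- c(msgs, paste("unknown function class(es):",
                          paste(setdiff(unique(al$function_class),
                                        functionClasses()), collapse = ", ")))
  dup <- duplicated(paste(al$gene, al$allele))
  if (any(dup))
    msgs <- c(msgs, paste("duplicate allele name within gene:",
                          paste(unique(paste(al$gene, al$allele)[dup]),
                                collapse = ", ")))
  for (g in unique(al$gene)) {
    sub <- al[al$gene == g, ]
    i1 <- which(sub$allele == "*1")
    if (length(i1) != 1L) {
      msgs <- c(msgs, paste0(g, ": reference allele *1 must be present"))
    } else {
      if (length(sub$variants[[i1]]) != 0L)
        msgs <- c(msgs, paste0(g, ": *1 must have no defining variants"))
      if (sub$function_class[i1] != "normal")
        msgs <- c(msgs, paste0(g, ": *1 must be function class 'normal'"))
    }
  }
  d6 <- al[al$gene == "CYP2D6", ]
  bad <- d6$function_class != "uncertain" & is.na(d6$activity)
  if (any(bad))
    msgs <- c(msgs, paste("CYP2D6 alleles missing activity value:",
                          paste(d6$allele[bad], collapse = ", ")))
  ## index must be the exact inverse of the definitions
  expect <- buildVariantIndex(al)
  idx <- object@variantIndex
  sorted <- function(l) l[order(names(l))]
  if (length(expect) != length(idx) ||
      (length(idx) > 0L && !identical(sorted(expect), sorted(idx))))
    msgs <- c(msgs, "variantIndex is not the inverse of the definitions")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
}
setValidity("AlleleTable", validAlleleTable)

buildVariantIndex <- function(alleles) {
  idx <- list()
  for (i in seq_len(nrow(alleles))) {
    id <- paste(alleles$gene[i], alleles$allele[i], sep = "|")
    for (v in alleles$variants[[i]]) idx[[v]] <- c(idx[[v]], id)
  }
  idx
}

#' Construct an AlleleTable from a definitions data.frame
#'
#' Lower-level constructor used by [readAlleleTable()]; builds the variant
#' index and runs validity checks.
#'
#' @param alleles data.frame with columns \code{gene}, \code{allele},
#'   \code{function_class}, \code{activity} and list-column \code{variants}.
#' @param build Genome build label (default \code{"synthetic"}).
#' @return A validated [AlleleTable-class] object.
#' @export
newAlleleTable <- function(alleles, build = "synthetic") {
  rownames(alleles) <- NULL
  new("AlleleTable", alleles = alleles,
      variantIndex = buildVariantIndex(alleles), build = build)
}

#' @describeIn AlleleTable-class genes present in the table
#' @param x,object An \code{AlleleTable}.
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' @rdname AlleleTable-class
#' @export
setMethod("genes", "AlleleTable", function(x) unique(x@alleles$gene))

#' @describeIn AlleleTable-class total number of alleles
#' @export
setGeneric("nAlleles", function(x, gene = NULL) standardGeneric("nAlleles"))

#' @rdname AlleleTable-class
#' @param gene Optional gene symbol to restrict the count.
#' @export
setMethod("nAlleles", "AlleleTable", function(x, gene = NULL) {
  if (is.null(gene)) nrow(x@alleles) else sum(x@alleles$gene == gene)
})

#' @describeIn AlleleTable-class allele names for one gene
#' @export
setGeneric("alleleNames", function(x, gene) standardGeneric("alleleNames"))

#' @rdname AlleleTable-class
#' @export
setMethod("alleleNames", "AlleleTable", function(x, gene) {
  if (!gene %in% x@alleles$gene) stop("unknown gene: ", gene)
  x@alleles$allele[x@alleles$gene == gene]
})

#' @describeIn AlleleTable-class the variant index (key -> "gene|allele")
#' @export
setGeneric("variantIndex", function(x) standardGeneric("variantIndex"))

#' @rdname AlleleTable-class
#' @export
setMethod("variantIndex", "AlleleTable", function(x) x@variantIndex)

#' @describeIn AlleleTable-class declared genome build
#' @export
setGeneric("genomeBuild", function(x) standardGeneric("genomeBuild"))

#' @rdname AlleleTable-class
#' @export
setMethod("genomeBuild", "AlleleTable", function(x) x@build)

#' Look up one allele definition
#'
#' @param table An [AlleleTable-class].
#' @param gene Gene symbol.
#' @param allele Star-allele name, e.g. \code{"*4"}.
#' @return A list with elements \code{gene}, \code{allele},
#'   \code{function_class}, \code{activity}, \code{variants}.
#' @export
alleleDefinition <- function(table, gene, allele) {
  i <- which(table@alleles$gene == gene & table@alleles$allele == allele)
  if (length(i) != 1L)
    stop("allele ", allele, " not found for gene ", gene)
  list(gene = gene, allele = allele,
       function_class = table@alleles$function_class[i],
       activity = table@alleles$activity[i],
       variants = table@alleles$variants[[i]])
}

setMethod("show", "AlleleTable", function(object) {
  cat("AlleleTable (build ", object@build, ")\n", sep = "")
  tab <- table(object@alleles$gene)
  for (g in names(tab)) cat("  ", g, ": ", tab[[g]], " alleles\n", sep = "")
  cat("  total: ", nrow(object@alleles), " alleles, ",
      length(object@variantIndex), " indexed variants\n", sep = "")
})

## ---------------------------------------------------------------------------
## PhenotypeConfig

#' PhenotypeConfig: diplotype-to-phenotype translation rules
#'
#' Carries the CYP2D6 activity-score bins and, for the categorical genes,
#' the unordered function-class-pair translation rules. Construct with
#' [readPhenotypeConfig()] or [defaultPhenotypeConfig()].
#'
#' @slot bins data.frame with columns \code{max} (upper bin edge, inclusive;
#'   last row \code{Inf}) and \code{phenotype}; score 0 falls in the first
#'   bin. Bins partition \code{[0, Inf)}.
#' @slot pairRules named list: gene -> named list mapping sorted
#'   \code{"classA+classB"} keys to phenotype labels.
#'
#' @name PhenotypeConfig-class
#' @aliases PhenotypeConfig
#' @exportClass PhenotypeConfig
setClass("PhenotypeConfig",
  representation(bins = "data.frame", pairRules = "list"))

setValidity("PhenotypeConfig", function(object) {
  msgs <- character()
  b <- object@bins
  if (!all(c("max", "phenotype") %in% names(b)))
    return("bins must have columns max, phenotype")
  if (is.unsorted(b$max, strictly = TRUE))
    msgs <- c(msgs, "bin upper edges must be strictly increasing")
  if (!is.infinite(b$max[nrow(b)]))
    msgs <- c(msgs, "last bin must extend to Inf")
  if (b$max[1] < 0) msgs <- c(msgs, "first bin edge must be >= 0")
  if (!all(b$phenotype %in% phenotypeLevels()))
    msgs <- c(msgs, "unknown phenotype label in bins")
  for (g in names(object@pairRules)) {
    if (!g %in% pgxGenes()) msgs <- c(msgs, paste("unknown gene", g))
    vals <- unlist(object@pairRules[[g]])
    if (!all(vals %in% phenotypeLevels()))
      msgs <- c(msgs, paste(g, "pair rule maps to unknown phenotype"))
    if (g != "CYP2C19" && any(vals == "RM"))
      msgs <- c(msgs, paste("RM phenotype is restricted to CYP2C19, used for", g))
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

setMethod("show", "PhenotypeConfig", function(object) {
  cat("PhenotypeConfig\n  CYP2D6 activity-score bins:\n")
  lo <- c(-Inf, object@bins$max[-nrow(object@bins)])
  for (i in seq_len(nrow(object@bins)))
    cat(sprintf("    (%s, %s] -> %s\n",
                format(max(lo[i], 0)), format(object@bins$max[i]),
                object@bins$phenotype[i]))
  cat("  categorical rules for:",
      paste(names(object@pairRules), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## DrugRuleSet

#' DrugRuleSet: per-drug actionability rules
#'
#' A validated collection of drug rules. Single-gene rules carry a set of
#' actionable phenotypes; two-gene rules carry a total recommendation
#' matrix over phenotype pairs plus the set of standard-care category
#' labels (a pair is actionable iff its category is not standard care).
#' Construct with [readDrugRules()].
#'
#' @slot rules named list of rule lists with elements \code{drug},
#'   \code{source}, \code{genes}, and either \code{actionable} (single-gene)
#'   or \code{matrix}, \code{categories}, \code{standard_categories}
#'   (two-gene); optional \code{aliases}.
#'
#' @name DrugRuleSet-class
#' @aliases DrugRuleSet
#' @exportClass DrugRuleSet
setClass("DrugRuleSet", representation(rules = "list"))

setValidity("DrugRuleSet", function(object) {
  msgs <- character()
  for (nm in names(object@rules)) {
    r <- object@rules[[nm]]
    if (!all(r$genes %in% pgxGenes())) {
      msgs <- c(msgs, paste(nm, "references unknown gene")); next
    }
    if (!r$source %in% c("CPIC", "DPWG"))
      msgs <- c(msgs, paste(nm, "source must be CPIC or DPWG"))
    if (length(r$genes) == 1L) {
      bad <- setdiff(r$actionable, phenotypeLevels(r$genes))
      if (length(bad))
        msgs <- c(msgs, paste0(nm, ": unknown phenotype label(s) ",
                               paste(bad, collapse = ", ")))
    } else if (length(r$genes) == 2L) {
      lev1 <- phenotypeLevels(r$genes[1])
      lev2 <- phenotypeLevels(r$genes[2])
      want <- as.vector(outer(lev1, lev2, paste, sep = "+"))
      missing <- setdiff(want, names(r$matrix))
      if (length(missing))
        msgs <- c(msgs, paste0(nm, ": matrix not total, missing pair(s) ",
                               paste(missing, collapse = ", ")))
      extra <- setdiff(names(r$matrix), want)
      if (length(extra))
        msgs <- c(msgs, paste0(nm, ": matrix has unknown pair(s) ",
                               paste(extra, collapse = ", ")))
      cats <- unique(unlist(r$matrix))
      if (!all(cats %in% names(r$categories)))
        msgs <- c(msgs, paste0(nm, ": matrix uses undescribed category"))
      if (anyDuplicated(names(r$categories)))
        msgs <- c(msgs, paste0(nm, ": duplicate category label"))
      if (!all(r$standard_categories %in% names(r$categories)))
        msgs <- c(msgs, paste0(nm, ": unknown standard-care category"))
    } else {
      msgs <- c(msgs, paste(nm, "must use one or two genes"))
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' @describeIn DrugRuleSet-class drug names in the set
#' @param x,object A \code{DrugRuleSet}.
#' @export
setGeneric("drugs", function(x) standardGeneric("drugs"))

#' @rdname DrugRuleSet-class
#' @export
setMethod("drugs", "DrugRuleSet", function(x) names(x@rules))

#' Extract one drug rule
#'
#' @param rules A [DrugRuleSet-class].
#' @param drug Drug name (or an alias, e.g. \code{"imipramine"} resolves
#'   to the shared TCA rule).
#' @return The rule as a list.
#' @export
drugRule <- function(rules, drug) {
  if (drug %in% names(rules@rules)) return(rules@rules[[drug]])
  for (r in rules@rules)
    if (!is.null(r$aliases) && drug %in% r$aliases) return(r)
  stop("no rule for drug: ", drug)
}

setMethod("show", "DrugRuleSet", function(object) {
  cat("DrugRuleSet with", length(object@rules), "drug rules\n")
  for (nm in names(object@rules)) {
    r <- object@rules[[nm]]
    cat(sprintf("  %-24s %-4s %s%s\n", nm, r$source,
                paste(r$genes, collapse = " x "),
                if (length(r$genes) == 2L) " [matrix]" else
                  paste0(" {", paste(r$actionable, collapse = ","), "}")))
  }
})

## ---------------------------------------------------------------------------
## FrequencyProfile

#' FrequencyProfile: star-allele frequencies for cohort simulation
#'
#' Per-gene star-allele haplotype frequencies plus CYP2D6 copy-number
#' event rates, used by [simulateCohort()] to draw Hardy-Weinberg
#' diplotypes. Construct with [readFrequencyProfile()],
#' [defaultProfile()] or [newFrequencyProfile()].
#'
#' @slot label Profile label (e.g. \code{"QGP-like"}).
#' @slot frequencies named list: gene -> named numeric vector of allele
#'   frequencies summing to 1 (tolerance 1e-9).
#' @slot cnDeletionRate Per-haplotype probability of a CYP2D6 whole-gene
#'   deletion event.
#' @slot cnDuplicationRate Per-haplotype probability of a CYP2D6
#'   duplication event.
#'
#' @name FrequencyProfile-class
#' @aliases FrequencyProfile
#' @exportClass FrequencyProfile
setClass("FrequencyProfile",
  representation(label = "character", frequencies = "list",
                 cnDeletionRate = "numeric", cnDuplicationRate = "numeric"))

setValidity("FrequencyProfile", function(object) {
  msgs <- character()
  for (g in names(object@frequencies)) {
    if (!g %in% pgxGenes()) msgs <- c(msgs, paste("unknown gene", g))
    f <- object@frequencies[[g]]
    if (any(f < 0)) msgs <- c(msgs, paste(g, "has negative frequency"))
    if (abs(sum(f) - 1) > 1e-9)
      msgs <- c(msgs, sprintf("%s frequencies sum to %.12f, not 1", g, sum(f)))
  }
  for (r in c(object@cnDeletionRate, object@cnDuplicationRate))
    if (r < 0 || r > 1) msgs <- c(msgs, "CN event rate outside [0,1]")
  if (object@cnDeletionRate + object@cnDuplicationRate > 1)
    msgs <- c(msgs, "CN deletion + duplication rates exceed 1")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a FrequencyProfile
#'
#' @param label Profile label.
#' @param frequencies Named list gene -> named numeric allele frequencies.
#' @param cnDeletionRate,cnDuplicationRate Per-haplotype CYP2D6
#'   copy-number event probabilities.
#' @return A validated [FrequencyProfile-class].
#' @export
newFrequencyProfile <- function(label, frequencies,
                                cnDeletionRate = 0,
                                cnDuplicationRate = 0) {
  new("FrequencyProfile", label = label, frequencies = frequencies,
      cnDeletionRate = cnDeletionRate, cnDuplicationRate = cnDuplicationRate)
}

setMethod("show", "FrequencyProfile", function(object) {
  cat("FrequencyProfile:", object@label, "\n")
  for (g in names(object@frequencies)) {
    f <- object@frequencies[[g]]
    cat("  ", g, ": ", paste0(names(f), "=", signif(f, 3), collapse = " "),
        "\n", sep = "")
  }
  cat(sprintf("  CYP2D6 CN rates: deletion %.3g, duplication %.3g\n",
              object@cnDeletionRate, object@cnDuplicationRate))
})

## ---------------------------------------------------------------------------
## CohortSummary

#' CohortSummary: per-drug actionable counts for one cohort
#'
#' Produced by [summarizeCohort()]. Percentages are kept at full precision
#' in the \code{stats} slot; report writers round to one decimal.
#'
#' @slot label Cohort label.
#' @slot n Cohort size.
#' @slot stats data.frame with columns \code{drug}, \code{actionable}
#'   (count), \code{proportion}, \code{percent}, \code{flagged}
#'   (indeterminate-excluded count).
#' @slot histograms named list: drug -> named integer category histogram
#'   (two-gene drugs only).
#'
#' @name CohortSummary-class
#' @aliases CohortSummary
#' @exportClass CohortSummary
setClass("CohortSummary",
  representation(label = "character", n = "integer", stats = "data.frame",
                 histograms = "list"))

setValidity("CohortSummary", function(object) {
  s <- object@stats
  if (object@n < 1L) return("cohort size must be >= 1")
  if (any(s$actionable < 0 | s$actionable > object@n))
    return("actionable count outside [0, n]")
  TRUE
})

#' @describeIn CohortSummary-class cohort size
#' @param x,object A \code{CohortSummary}.
#' @export
setGeneric("cohortSize", function(x) standardGeneric("cohortSize"))

#' @rdname CohortSummary-class
#' @export
setMethod("cohortSize", "CohortSummary", function(x) x@n)

#' @describeIn CohortSummary-class the per-drug stats table
#' @export
setGeneric("cohortStats", function(x) standardGeneric("cohortStats"))

#' @rdname CohortSummary-class
#' @export
setMethod("cohortStats", "CohortSummary", function(x) x@stats)

setMethod("show", "CohortSummary", function(object) {
  cat("CohortSummary '", object@label, "' (n = ", object@n, ")\n", sep = "")
  s <- object@stats
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-24s n = %6d  %5.1f%%\n", s$drug[i], s$actionable[i],
                s$percent[i]))
})
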