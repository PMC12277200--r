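## Guideline engine: per-drug actionability and combined two-gene
## recommendation categories (sertraline: CYP2C19 x CYP2B6; tricyclic
## antidepressants: CYP2C19 x CYP2D6).
##
## Rules are data, not code: the shipped YAML carries each drug's source
## consortium, gene(s), actionable phenotype set (single-gene drugs) or a
## total recommendation matrix with category texts and the standard-care
## category labels (two-gene drugs). A two-gene pair is actionable iff its
## matrix cell is not a standard-care category.

#' Read a drug rule configuration
#'
#' @param path YAML path with a top-level \code{drugs} mapping; see the
#'   packaged \code{inst/extdata/drug_rules.yaml} for the schema.
#' @return A validated [DrugRuleSet-class]. A two-gene matrix that is not
#'   total over the phenotype grid (Indeterminate excluded) is a
#'   validation error naming the missing pair.
#' @export
readDrugRules <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$drugs)) stop("rule config must have a top-level 'drugs' map")
  rules <- lapply(names(y$drugs), function(nm) {
    r <- y$drugs[[nm]]
    r$drug <- nm
    r$genes <- unlist(r$genes)
    if (!is.null(r$actionable)) r$actionable <- unlist(r$actionable)
    if (!is.null(r$aliases)) r$aliases <- unlist(r$aliases)
    if (!is.null(r$standard_categories))
      r$standard_categories <- unlist(r$standard_categories)
    r
  })
  names(rules) <- names(y$drugs)
  new("DrugRuleSet", rules = rules)
}

#' The packaged default drug rules
#'
#' Citalopram/escitalopram, sertraline, paroxetine, fluvoxamine,
#' venlafaxine, vortioxetine, the shared TCA rule (amitriptyline with
#' clomipramine/doxepin/imipramine/trimipramine as aliases), aripiprazole,
#' brexpiprazole, haloperidol, risperidone, pimozide, zuclopenthixol and
#' quetiapine.
#'
#' @return A [DrugRuleSet-class].
#' @export
defaultDrugRules <- function() {
  readDrugRules(system.file("extdata", "drug_rules.yaml",
                            package = "pgxCohort"))
}

#' Dump a rule set back to YAML
#'
#' Round-trips with [readDrugRules()].
#'
#' @param rules A [DrugRuleSet-class].
#' @param path Output YAML path.
#' @return Invisibly, \code{path}.
#' @export
writeDrugRules <- function(rules, path) {
  dump <- lapply(rules@rules, function(r) {
    r$drug <- NULL
    r
  })
  yaml::write_yaml(list(drugs = dump), path)
  invisible(path)
}

ruleCategory <- function(rule, phenotypes) {
  key <- paste(phenotypes[[rule$genes[1]]], phenotypes[[rule$genes[2]]],
               sep = "+")
  cat <- rule$matrix[[key]]
  if (is.null(cat)) stop("no matrix cell for phenotype pair ", key,
                         " in rule ", rule$drug)
  cat
}

#' Is a sample actionable for a drug?
#'
#' Single-gene rules test membership of the gene's phenotype in the rule's
#' actionable set. Two-gene rules look the phenotype pair up in the
#' recommendation matrix; the sample is actionable iff the category is not
#' standard care. Indeterminate phenotypes are never actionable and are
#' reported through the \code{"flagged"} attribute of cohort
#' classifications.
#'
#' @param rule A rule list from [drugRule()].
#' @param phenotypes Named character vector/list: gene -> phenotype.
#' @return Logical scalar.
#' @export
#' @examples
#' rules <- defaultDrugRules()
#' isActionable(drugRule(rules, "citalopram_escitalopram"),
#'              c(CYP2C19 = "RM"))
isActionable <- function(rule, phenotypes) {
  missing <- setdiff(rule$genes, names(phenotypes))
  if (length(missing))
    stop("rule ", rule$drug, " requires phenotype(s) for ",
         paste(missing, collapse = ", "))
  ph <- vapply(rule$genes, function(g) as.character(phenotypes[[g]]), "")
  if (any(ph == "Indeterminate")) return(FALSE)
  if (length(rule$genes) == 1L) return(ph %in% rule$actionable)
  !(ruleCategory(rule, as.list(stats::setNames(ph, rule$genes))) %in%
      rule$standard_categories)
}

recommendationFor <- function(rule, phenotypes) {
  ph <- vapply(rule$genes, function(g) as.character(phenotypes[[g]]), "")
  if (any(ph == "Indeterminate"))
    return(list(label = NA_character_, text = NA_character_,
                flagged = TRUE))
  lab <- ruleCategory(rule, as.list(stats::setNames(ph, rule$genes)))
  list(label = lab, text = rule$categories[[lab]], flagged = FALSE)
}

#' Sertraline recommendation from combined CYP2C19 x CYP2B6 status
#'
#' Matrix lookup in the sertraline rule. Indeterminate input gives a
#' no-recommendation result with \code{flagged = TRUE}.
#'
#' @param c19 CYP2C19 phenotype label.
#' @param b6 CYP2B6 phenotype label.
#' @param rule The sertraline rule (default from the packaged config).
#' @return List with \code{label} (category letter), \code{text} and
#'   \code{flagged}.
#' @export
sertralineRecommendation <- function(c19, b6,
                                     rule = drugRule(defaultDrugRules(),
                                                     "sertraline")) {
  recommendationFor(rule, list(CYP2C19 = c19, CYP2B6 = b6))
}

#' TCA recommendation from combined CYP2C19 x CYP2D6 status
#'
#' Matrix lookup in the shared tricyclic-antidepressant rule
#' (amitriptyline; also used for clomipramine, doxepin, imipramine and
#' trimipramine).
#'
#' @param c19 CYP2C19 phenotype label.
#' @param d6 CYP2D6 phenotype label.
#' @param rule The TCA rule (default from the packaged config).
#' @return List with \code{label}, \code{text}, \code{flagged}.
#' @export
tcaRecommendation <- function(c19, d6,
                              rule = drugRule(defaultDrugRules(),
                                              "amitriptyline")) {
  recommendationFor(rule, list(CYP2C19 = c19, CYP2D6 = d6))
}

#' Classify a phenotyped cohort against every drug rule
#'
#' @param phenotypes data.frame from [phenotypeCohort()] (long format:
#'   \code{sample_id}, \code{gene}, \code{phenotype}).
#' @param rules A [DrugRuleSet-class].
#' @return data.frame \code{sample_id}, \code{drug}, \code{actionable}
#'   (logical), \code{category} (two-gene drugs; NA otherwise),
#'   \code{flagged} (TRUE when an Indeterminate phenotype blocked the
#'   rule). Errors if a rule's gene has no phenotype column, naming the
#'   drug and gene.
#' @export
classifyCohort <- function(phenotypes, rules) {
  samples <- unique(phenotypes$sample_id)
  ## wide sample x gene phenotype matrix
  wide <- matrix(NA_character_, nrow = length(samples),
                 ncol = length(unique(phenotypes$gene)),
                 dimnames = list(samples, unique(phenotypes$gene)))
  wide[cbind(match(phenotypes$sample_id, samples),
             match(phenotypes$gene, colnames(wide)))] <- phenotypes$phenotype
  perDrug <- lapply(drugs(rules), function(drug) {
    rule <- rules@rules[[drug]]
    for (g in rule$genes) {
      if (!g %in% colnames(wide) || anyNA(wide[, g]))
        stop("drug ", drug, " requires gene ", g,
             " but phenotypes for it are missing")
    }
    if (length(rule$genes) == 2L) {
      key <- paste(wide[, rule$genes[1]], wide[, rule$genes[2]], sep = "+")
      ind <- wide[, rule$genes[1]] == "Indeterminate" |
             wide[, rule$genes[2]] == "Indeterminate"
      lut <- unlist(rule$matrix)
      bad <- !ind & !(key %in% names(lut))
      if (any(bad))
        stop("no matrix cell for phenotype pair ", key[bad][1],
             " in rule ", drug)
      cat <- ifelse(ind, NA_character_, lut[key])
      act <- !ind & !(cat %in% rule$standard_categories)
    } else {
      ph <- wide[, rule$genes]
      ind <- ph == "Indeterminate"
      cat <- rep(NA_character_, length(ph))
      act <- !ind & ph %in% rule$actionable
    }
    data.frame(sample_id = samples, drug = drug, actionable = act,
               category = cat, flagged = ind, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, perDrug)
  rownames(out) <- NULL
  out
}
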