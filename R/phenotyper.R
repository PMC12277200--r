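## Phenotyper: diplotype -> metabolizer phenotype translation.
## CYP2D6 uses multiplicity-weighted activity-score arithmetic with
## configurable score bins; CYP2C19/CYP2B6/CYP3A4 use categorical
## function-class-pair rules.

#' Read a phenotype translation config
#'
#' YAML with keys \code{cyp2d6_bins} (list of \code{max}/\code{phenotype}
#' pairs; upper edges inclusive, last edge \code{.inf}) and
#' \code{pair_rules} (gene -> \code{"classA+classB"} -> phenotype, keys
#' with the two classes in sorted order).
#'
#' @param path YAML path.
#' @return A validated [PhenotypeConfig-class].
#' @export
readPhenotypeConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$cyp2d6_bins) || is.null(y$pair_rules))
    stop("phenotype config must define cyp2d6_bins and pair_rules")
  bins <- data.frame(
    max = vapply(y$cyp2d6_bins, function(b) as.numeric(b$max), 0),
    phenotype = vapply(y$cyp2d6_bins, function(b) b$phenotype, ""),
    stringsAsFactors = FALSE)
  new("PhenotypeConfig", bins = bins, pairRules = y$pair_rules)
}

#' The packaged default phenotype config
#'
#' CYP2D6 bins follow the consensus activity-score convention: score 0 is
#' PM, (0, 1] is IM (so score 1.0, e.g. *1/*4, is IM), (1, 2.25] is NM,
#' above 2.25 is UM. Categorical rules for CYP2C19 include RM
#' (normal + increased); CYP2B6 and CYP3A4 have no RM.
#'
#' @return A [PhenotypeConfig-class].
#' @export
defaultPhenotypeConfig <- function() {
  readPhenotypeConfig(system.file("extdata", "phenotype_config.yaml",
                                  package = "pgxCohort"))
}

#' CYP2D6 activity score of a diplotype call
#'
#' Multiplicity-weighted sum of allele activity values; the deletion
#' allele \code{*5} contributes 0. If any contributing allele has
#' uncertain function the score is \code{NA} (indeterminate).
#'
#' @param call A \code{DiplotypeCall} for CYP2D6.
#' @param table An [AlleleTable-class].
#' @return Numeric score, or \code{NA} when uncertain.
#' @export
#' @examples
#' tab <- readAlleleTable(system.file("extdata", "allele_definitions.tsv",
#'                                    package = "pgxCohort"))
#' # *1/*10 -> 1 + 0.25
#' cyp2d6ActivityScore(
#'   selectDiplotype(list(c("*1", "*10")), "CYP2D6", tab), tab)
cyp2d6ActivityScore <- function(call, table) {
  if (call$gene != "CYP2D6") stop("activity scores apply to CYP2D6 only")
  if ("no_call" %in% call$flags) stop("cannot score a no-call")
  total <- 0
  for (i in c("a", "b")) {
    allele <- call[[paste0("allele_", i)]]
    mult <- call[[paste0("mult_", i)]]
    if (mult == 0L) next
    def <- alleleDefinition(table, "CYP2D6", allele)
    if (def$function_class == "uncertain") return(NA_real_)
    total <- total + mult * def$activity
  }
  total
}

#' Map an activity score to a metabolizer phenotype
#'
#' Deterministic bin lookup; the bins partition \code{[0, Inf)} so every
#' non-negative score maps to exactly one phenotype. \code{NA} (uncertain)
#' maps to Indeterminate.
#'
#' @param score Numeric activity score(s); \code{NA} allowed.
#' @param config A [PhenotypeConfig-class].
#' @return Character vector of phenotype labels.
#' @export
scoreToPhenotype <- function(score, config = defaultPhenotypeConfig()) {
  vapply(score, function(s) {
    if (is.na(s)) return("Indeterminate")
    if (s < 0) stop("activity score must be non-negative")
    config@bins$phenotype[which(s <= config@bins$max)[1]]
  }, "")
}

#' Categorical phenotype for CYP2C19, CYP2B6 or CYP3A4
#'
#' Maps the unordered pair of the two alleles' function classes through
#' the config's pair rules. Any uncertain-function allele gives
#' Indeterminate. A function-class pair absent from the config is an
#' error, never a silent fallback.
#'
#' @param gene One of CYP2C19, CYP2B6, CYP3A4.
#' @param call A \code{DiplotypeCall}.
#' @param table An [AlleleTable-class].
#' @param config A [PhenotypeConfig-class].
#' @return Phenotype label.
#' @export
categoricalPhenotype <- function(gene, call, table,
                                 config = defaultPhenotypeConfig()) {
  if (!gene %in% c("CYP2C19", "CYP2B6", "CYP3A4"))
    stop("categorical translation applies to CYP2C19/CYP2B6/CYP3A4")
  if ("no_call" %in% call$flags) return("Indeterminate")
  cls <- vapply(c(call$allele_a, call$allele_b), function(a)
    alleleDefinition(table, gene, a)$function_class, "")
  if (any(cls == "uncertain")) return("Indeterminate")
  key <- paste(sort(cls), collapse = "+")
  rules <- config@pairRules[[gene]]
  if (is.null(rules) || is.null(rules[[key]]))
    stop("no ", gene, " translation rule for function-class pair '", key,
         "'; the phenotype config must be total")
  rules[[key]]
}

#' Phenotype every call in a cohort
#'
#' @param calls data.frame from [callCohort()].
#' @param table An [AlleleTable-class].
#' @param config A [PhenotypeConfig-class].
#' @return data.frame \code{sample_id}, \code{gene}, \code{diplotype},
#'   \code{activity_score} (CYP2D6 only), \code{phenotype}.
#' @export
phenotypeCohort <- function(calls, table, config = defaultPhenotypeConfig()) {
  out <- calls[, c("sample_id", "gene", "diplotype")]
  out$activity_score <- NA_real_
  out$phenotype <- NA_character_
  cache <- list()
  for (i in seq_len(nrow(calls))) {
    g <- calls$gene[i]
    key <- paste0(g, "|", calls$diplotype[i])
    if (is.null(cache[[key]])) {
      call <- newDiplotypeCall(g, calls$allele_a[i], calls$mult_a[i],
                               calls$allele_b[i], calls$mult_b[i],
                               flags = strsplit(calls$flags[i], ",")[[1]])
      cache[[key]] <- if ("no_call" %in% call$flags) {
        list(score = NA_real_, phenotype = "Indeterminate")
      } else if (g == "CYP2D6") {
        s <- cyp2d6ActivityScore(call, table)
        list(score = s, phenotype = scoreToPhenotype(s, config))
      } else {
        list(score = NA_real_,
             phenotype = categoricalPhenotype(g, call, table, config))
      }
    }
    out$activity_score[i] <- cache[[key]]$score
    out$phenotype[i] <- cache[[key]]$phenotype
  }
  out
}

#' Enumerate the diplotype -> phenotype landscape
#'
#' Exhaustively enumerates diplotype combinations of a gene's alleles and
#' their phenotypes. At copy number 2 the combinations are the unordered
#' allele pairs, n(n+1)/2 of them for n alleles; \code{maxCn} > 2 adds,
#' for CYP2D6, the multiplicity splits (cn-1, 1) for every ordered allele
#' pair at each copy number up to \code{maxCn}.
#'
#' @param table An [AlleleTable-class].
#' @param gene Gene symbol (default CYP2D6).
#' @param config A [PhenotypeConfig-class].
#' @param maxCn Maximum total copy number (>= 2).
#' @return data.frame \code{diplotype}, \code{cn}, \code{activity_score},
#'   \code{phenotype}; the combination count is \code{nrow} of the result.
#' @export
phenotypeLandscape <- function(table, gene = "CYP2D6",
                               config = defaultPhenotypeConfig(),
                               maxCn = 2L) {
  if (maxCn < 2L) stop("maxCn must be >= 2")
  alleles <- alleleNames(table, gene)
  alleles <- setdiff(alleles, "*5")
  rows <- list()
  addRow <- function(a, ma, b, mb, cn) {
    call <- newDiplotypeCall(gene, a, ma, b, mb)
    if (gene == "CYP2D6") {
      s <- cyp2d6ActivityScore(call, table)
      ph <- scoreToPhenotype(s, config)
    } else {
      s <- NA_real_
      ph <- categoricalPhenotype(gene, call, table, config)
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      diplotype = call$diplotype, cn = cn, activity_score = s,
      phenotype = ph, stringsAsFactors = FALSE)
  }
  n <- length(alleles)
  for (i in seq_len(n))
    for (j in i:n)
      addRow(alleles[i], 1L, alleles[j], 1L, 2L)
  if (gene == "CYP2D6" && maxCn > 2L) {
    for (cn in 3:maxCn)
      for (i in seq_len(n))
        for (j in seq_len(n))
          addRow(alleles[i], cn - 1L, alleles[j], 1L, cn)
  }
  out <- unique(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}
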