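## End-to-end driver: calls -> phenotypes -> actionability -> summary
## (and, with a second cohort, a comparison table). All outputs are plain
## TSV; identical inputs give byte-identical bundles (the run log carries
## stage counts, no timestamps).

writeTsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

processCohort <- function(vcf, cn, label, table, phenoConfig, rules,
                          outDir, duplicationPolicy, logLines) {
  calls <- callCohort(vcf, table, cnSidecar = cn,
                      duplicationPolicy = duplicationPolicy)
  lg <- attr(calls, "log")
  logLines(c(sprintf("[%s] call: %d samples, %d no_call, %d unphased_ambiguity, %d cn_ambiguity, %d ignored variants",
                     label, lg$n_samples, lg$no_call, lg$unphased_ambiguity,
                     lg$cn_ambiguity, lg$ignored_variants)))
  writeTsv(calls, file.path(outDir, paste0(label, "_diplotypes.tsv")))
  pheno <- phenotypeCohort(calls, table, phenoConfig)
  writeTsv(pheno, file.path(outDir, paste0(label, "_phenotypes.tsv")))
  cls <- classifyCohort(pheno, rules)
  writeTsv(cls, file.path(outDir, paste0(label, "_classification.tsv")))
  summ <- summarizeCohort(cls, label)
  s <- cohortStats(summ)
  tab1 <- data.frame(
    drug = s$drug,
    source = vapply(s$drug, function(d) rules@rules[[d]]$source, ""),
    genes = vapply(s$drug, function(d)
      paste(rules@rules[[d]]$genes, collapse = "+"), ""),
    n = cohortSize(summ), actionable = s$actionable,
    percent = sprintf("%.1f", s$percent), flagged = s$flagged,
    stringsAsFactors = FALSE)
  writeTsv(tab1, file.path(outDir, paste0(label, "_summary.tsv")))
  hrows <- list()
  for (d in names(summ@histograms)) {
    h <- summ@histograms[[d]]
    hrows[[d]] <- data.frame(drug = d, category = names(h),
                             count = as.integer(h), stringsAsFactors = FALSE)
  }
  if (length(hrows))
    writeTsv(do.call(rbind, hrows),
             file.path(outDir, paste0(label, "_categories.tsv")))
  logLines(c(sprintf("[%s] classify: %d samples x %d drugs",
                     label, cohortSize(summ), nrow(s))))
  summ
}

#' Run the full actionability pipeline
#'
#' Executes every stage on one cohort (and optionally a second for
#' comparison): diplotype calling, phenotyping, per-drug actionability
#' classification, a per-cohort summary in the style of a
#' population-actionability table, per-category histograms for the
#' two-gene drugs, and - when a second cohort is given - a comparison
#' table with z-tests, odds ratios and BH-adjusted p-values. Instead of a
#' VCF, a cohort may be simulated in place via the \code{simulate} entry.
#'
#' @param config A list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{out}{output directory (required).}
#'     \item{alleles, phenotype_config, rules}{paths; packaged defaults
#'       when omitted.}
#'     \item{cohorts}{list of cohort entries, each with \code{label} and
#'       either \code{vcf} (+ optional \code{cn}) or \code{simulate}
#'       (\code{profile} name or path, \code{n}, \code{seed},
#'       optional \code{phased}).}
#'     \item{duplication_policy}{\code{"higher"} (default), \code{"lower"}
#'       or \code{"ambiguous"}.}
#'     \item{m, alpha, alpha_genomewide, ci_level}{comparison settings.}
#'   }
#' @return Invisibly, a list with the per-cohort [CohortSummary-class]
#'   objects, the comparison data.frame (or NULL) and the output paths.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out)) stop("config$out (output directory) is required")
  if (is.null(config$cohorts) || !length(config$cohorts))
    stop("config$cohorts must list at least one cohort")
  outDir <- config$out
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  table <- if (is.null(config$alleles)) {
    readAlleleTable(system.file("extdata", "allele_definitions.tsv",
                                package = "pgxCohort"))
  } else readAlleleTable(config$alleles)
  phenoConfig <- if (is.null(config$phenotype_config))
    defaultPhenotypeConfig() else readPhenotypeConfig(config$phenotype_config)
  rules <- if (is.null(config$rules)) defaultDrugRules()
           else readDrugRules(config$rules)
  dupPolicy <- config$duplication_policy %||% "higher"

  log <- character()
  logLines <- function(x) log <<- c(log, x)
  logLines(sprintf("pgxCohort pipeline: %d alleles, %d drug rules",
                   nAlleles(table), length(drugs(rules))))

  summaries <- list()
  for (co in config$cohorts) {
    label <- co$label %||% "cohort"
    if (!is.null(co$simulate)) {
      sm <- co$simulate
      prof <- if (file.exists(sm$profile %||% ""))
        readFrequencyProfile(sm$profile) else defaultProfile(sm$profile)
      sim <- simulateCohort(prof, sm$n, sm$seed, table,
                            dir = outDir, phased = isTRUE(sm$phased),
                            config = phenoConfig, prefix = label)
      vcf <- sim$vcf; cn <- sim$cn
      logLines(sprintf("[%s] simulate: n=%d seed=%d profile=%s",
                       label, sm$n, sm$seed, prof@label))
    } else {
      vcf <- co$vcf; cn <- co$cn
      if (is.null(vcf) || !file.exists(vcf))
        stop("cohort '", label, "': VCF not found: ", vcf %||% "<missing>")
    }
    summaries[[label]] <- processCohort(vcf, cn, label, table, phenoConfig,
                                        rules, outDir, dupPolicy, logLines)
  }

  comparison <- NULL
  if (length(summaries) >= 2L) {
    comparison <- compareCohorts(
      summaries[[1]], summaries[[2]],
      m = config$m %||% NULL,
      alpha = config$alpha %||% 0.05,
      alphaGenomewide = config$alpha_genomewide %||% 5e-8,
      conf.level = config$ci_level %||% 0.95)
    writeTsv(comparison, file.path(outDir, "comparison.tsv"))
    logLines(sprintf("compare: %d drugs, %d significant after BH",
                     nrow(comparison), sum(comparison$significant)))
  }
  writeLines(log, file.path(outDir, "log.txt"))
  invisible(list(summaries = summaries, comparison = comparison,
                 out = outDir))
}
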