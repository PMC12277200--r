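## Synthetic cohorts: star-allele frequency profiles -> Hardy-Weinberg
## diplotypes -> genotype VCF + CYP2D6 copy-number sidecar, with truth
## labels for every downstream stage.

#' Read a frequency profile
#'
#' YAML with keys \code{label}, \code{frequencies} (gene -> allele ->
#' frequency) and \code{cn_deletion_rate} / \code{cn_duplication_rate}
#' (per-haplotype CYP2D6 event probabilities).
#'
#' @param path YAML path.
#' @return A validated [FrequencyProfile-class].
#' @export
readFrequencyProfile <- function(path) {
  y <- yaml::read_yaml(path)
  freqs <- lapply(y$frequencies, function(f) unlist(f))
  newFrequencyProfile(label = y$label, frequencies = freqs,
                      cnDeletionRate = y$cn_deletion_rate %||% 0,
                      cnDuplicationRate = y$cn_duplication_rate %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Packaged illustrative frequency profiles
#'
#' Three shipped profiles: \code{"qgp_like"} (high CYP2C19
#' increased-function frequency), \code{"1kg_like"} (higher CYP2D6
#' decreased-function frequency) and \code{"eu_like"} (higher CYP2D6
#' no-function frequency). They are calibrated to the magnitude of
#' published phenotype percentages only, not to any cohort's unpublished
#' allele frequencies.
#'
#' @param name One of \code{"qgp_like"}, \code{"1kg_like"},
#'   \code{"eu_like"}.
#' @return A [FrequencyProfile-class].
#' @export
defaultProfile <- function(name = c("qgp_like", "1kg_like", "eu_like")) {
  name <- match.arg(name)
  readFrequencyProfile(system.file("extdata", "profiles",
                                   paste0(name, ".yaml"),
                                   package = "pgxCohort"))
}

#' Draw Hardy-Weinberg diplotypes with truth labels
#'
#' Haplotypes are drawn i.i.d. per gene from the profile frequencies
#' (Hardy-Weinberg random mating); CYP2D6 haplotypes then independently
#' suffer a whole-gene deletion or a duplication at the profile's rates.
#' Uses the current RNG state; callers control the seed.
#'
#' @param profile A [FrequencyProfile-class].
#' @param n Number of samples (>= 1).
#' @return List with \code{haplotypes} (per gene, a list of two character
#'   vectors of allele names), \code{mult} (CYP2D6 per-haplotype
#'   multiplicity: 0 deleted, 1 normal, 2 duplicated), \code{cn}
#'   (per-sample CYP2D6 copy number) and \code{truth} (data.frame
#'   \code{sample_id}, \code{gene}, \code{diplotype}, \code{allele_a},
#'   \code{mult_a}, \code{allele_b}, \code{mult_b}).
#' @export
simulateDiplotypes <- function(profile, n) {
  stopifnot(n >= 1)
  validObject(profile)
  samples <- sprintf("S%05d", seq_len(n))
  haps <- list(); rows <- list()
  mult <- NULL; cn <- NULL
  for (g in names(profile@frequencies)) {
    f <- profile@frequencies[[g]]
    h1 <- sample(names(f), n, replace = TRUE, prob = f)
    h2 <- sample(names(f), n, replace = TRUE, prob = f)
    m1 <- rep(1L, n); m2 <- rep(1L, n)
    if (g == "CYP2D6" &&
        (profile@cnDeletionRate > 0 || profile@cnDuplicationRate > 0)) {
      u1 <- stats::runif(n); u2 <- stats::runif(n)
      pd <- profile@cnDeletionRate; pu <- profile@cnDuplicationRate
      m1 <- ifelse(u1 < pd, 0L, ifelse(u1 < pd + pu, 2L, 1L))
      m2 <- ifelse(u2 < pd, 0L, ifelse(u2 < pd + pu, 2L, 1L))
    }
    haps[[g]] <- list(h1 = h1, h2 = h2)
    if (g == "CYP2D6") {
      mult <- cbind(m1, m2)
      cn <- m1 + m2
    }
    dip <- character(n); aa <- character(n); ma <- integer(n)
    ab <- character(n); mb <- integer(n)
    for (i in seq_len(n)) {
      if (g == "CYP2D6") {
        pair <- truthPair(h1[i], m1[i], h2[i], m2[i])
      } else {
        pair <- list(a = h1[i], ma = 1L, b = h2[i], mb = 1L)
      }
      aa[i] <- pair$a; ma[i] <- pair$ma
      ab[i] <- pair$b; mb[i] <- pair$mb
      dip[i] <- diplotypeString(pair$a, pair$ma, pair$b, pair$mb)
    }
    rows[[g]] <- data.frame(sample_id = samples, gene = g, diplotype = dip,
                            allele_a = aa, mult_a = ma, allele_b = ab,
                            mult_b = mb, flags = "", alternatives = "",
                            stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  list(haplotypes = haps, mult = mult,
       cn = if (is.null(cn)) rep(2L, n) else cn,
       truth = truth, samples = samples)
}

## canonical (allele, multiplicity) pair for a CYP2D6 sample whose two
## haplotypes carry multiplicities 0 (deleted) / 1 / 2 (duplicated)
truthPair <- function(a1, m1, a2, m2) {
  if (m1 == 0L && m2 == 0L) return(list(a = "*5", ma = 1L, b = "*5", mb = 1L))
  if (m1 == 0L) return(list(a = a2, ma = m2, b = "*5", mb = 1L))
  if (m2 == 0L) return(list(a = a1, ma = m1, b = "*5", mb = 1L))
  list(a = a1, ma = m1, b = a2, mb = m2)
}

#' Simulate a cohort to disk: VCF, CN sidecar and truth tables
#'
#' Draws a Hardy-Weinberg cohort with [simulateDiplotypes()] and writes
#' (a) an unphased (or phased) VCF 4.2 covering every variant in the
#' allele table's index, (b) a CYP2D6 copy-number sidecar TSV and (c) a
#' truth TSV with the true diplotypes and the phenotypes derived from
#' them. Genotypes are written presence-based per haplotype; when exactly
#' one CYP2D6 haplotype is deleted the remaining haplotype's variants are
#' written homozygous (hemizygous sites present as homozygous to genotype
#' callers), and a fully deleted gene is written all-reference. The seed
#' is recorded in the VCF header; identical seeds give byte-identical
#' outputs.
#'
#' @param profile A [FrequencyProfile-class].
#' @param n Number of samples.
#' @param seed Integer RNG seed.
#' @param table An [AlleleTable-class]; every profile allele must exist in
#'   it.
#' @param dir Output directory (created if needed).
#' @param phased Write phased genotypes (default FALSE).
#' @param config [PhenotypeConfig-class] used for the truth phenotypes.
#' @param prefix File-name prefix (default \code{"cohort"}).
#' @return List with \code{vcf}, \code{cn}, \code{truth} (file paths),
#'   \code{truth_calls}, \code{truth_phenotypes} (data.frames) and
#'   \code{samples}.
#' @export
simulateCohort <- function(profile, n, seed, table, dir,
                           phased = FALSE,
                           config = defaultPhenotypeConfig(),
                           prefix = "cohort") {
  for (g in names(profile@frequencies)) {
    bad <- setdiff(names(profile@frequencies[[g]]), alleleNames(table, g))
    if (length(bad))
      stop("profile allele(s) absent from table for ", g, ": ",
           paste(bad, collapse = ", "))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(seed))
  sim <- simulateDiplotypes(profile, n)
  samples <- sim$samples

  vcfPath <- file.path(dir, paste0(prefix, ".vcf"))
  writeCohortVcf(sim, table, vcfPath, phased = phased, seed = seed,
                 label = profile@label)
  cnPath <- file.path(dir, paste0(prefix, "_cn.tsv"))
  utils::write.table(
    data.frame(sample_id = samples, gene = "CYP2D6", copy_number = sim$cn),
    cnPath, sep = "\t", quote = FALSE, row.names = FALSE)

  truthPheno <- phenotypeCohort(sim$truth, table, config)
  truthPath <- file.path(dir, paste0(prefix, "_truth.tsv"))
  truth <- merge(sim$truth[, c("sample_id", "gene", "diplotype")],
                 truthPheno[, c("sample_id", "gene", "phenotype")],
                 by = c("sample_id", "gene"), sort = FALSE)
  truth <- truth[order(truth$sample_id, truth$gene), ]
  utils::write.table(truth, truthPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(vcf = vcfPath, cn = cnPath, truth = truthPath,
       truth_calls = sim$truth, truth_phenotypes = truthPheno,
       samples = samples)
}

## deterministic minimal VCF writer for the synthetic contigs
writeCohortVcf <- function(sim, table, path, phased = FALSE, seed = NA,
                           label = "") {
  keys <- names(table@variantIndex)
  pk <- parseVariantKey(keys)
  ord <- order(match(pk$chrom, unique(pk$chrom)), pk$pos, pk$ref, pk$alt)
  keys <- keys[ord]; pk <- pk[ord, ]
  geneOf <- vapply(table@variantIndex, function(a) sub("\\|.*$", "", a[1]), "")
  samples <- sim$samples
  n <- length(samples)
  sep <- if (phased) "|" else "/"

  gtRows <- character(length(keys))
  for (r in seq_along(keys)) {
    k <- keys[r]
    g <- geneOf[[k]]
    h <- sim$haplotypes[[g]]
    inAllele <- function(al) {
      def <- table@alleles$variants[
        table@alleles$gene == g & table@alleles$allele == al][[1]]
      k %in% def
    }
    carriers <- stats::setNames(
      vapply(unique(c(h$h1, h$h2)), inAllele, logical(1)),
      unique(c(h$h1, h$h2)))
    c1 <- carriers[h$h1]; c2 <- carriers[h$h2]
    if (g == "CYP2D6" && !is.null(sim$mult)) {
      del1 <- sim$mult[, 1] == 0L; del2 <- sim$mult[, 2] == 0L
      bothDel <- del1 & del2
      ## one deleted haplotype: remaining haplotype presents homozygous
      c1 <- ifelse(del1 & !del2, c2, c1)
      c2 <- ifelse(del2 & !del1, c1, c2)
      c1[bothDel] <- FALSE; c2[bothDel] <- FALSE
    }
    gtRows[r] <- paste(paste0(as.integer(c1), sep, as.integer(c2)),
                       collapse = "\t")
  }

  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=pgxCohort simulateCohort",
    paste0("##pgxCohortSeed=", seed),
    paste0("##pgxCohortProfile=", label),
    paste0("##contig=<ID=", unique(pk$chrom), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")), con)
  for (r in seq_along(keys))
    writeLines(paste(pk$chrom[r], pk$pos[r], ".", pk$ref[r], pk$alt[r],
                     ".", "PASS", ".", "GT", gtRows[r], sep = "\t"), con)
  invisible(path)
}

#' Fit a frequency profile to phenotype-frequency targets
#'
#' Least-squares fit, under Hardy-Weinberg, of function-class haplotype
#' frequencies whose diplotype mixture matches target phenotype
#' frequencies for one gene. Each function class is represented by its
#' first (lowest-numbered) allele in the table; for CYP2D6 the class's
#' activity value is that allele's. The fit is a deterministic
#' Nelder-Mead search over softmax-parameterised class frequencies from
#' several fixed starting points.
#'
#' @param targets Named numeric vector: phenotype label -> target
#'   frequency in [0, 1] (phenotypes not named are unconstrained).
#' @param gene Gene symbol.
#' @param table An [AlleleTable-class].
#' @param config A [PhenotypeConfig-class].
#' @param tol Maximum tolerated absolute residual per target (default
#'   0.005); infeasible targets error with the best residual reported.
#' @param label Label for the returned profile.
#' @return A [FrequencyProfile-class] with attribute \code{"residual"}
#'   (max absolute deviation from the targets).
#' @export
#' @examples
#' tab <- readAlleleTable(system.file("extdata", "allele_definitions.tsv",
#'                                    package = "pgxCohort"))
#' # PM = 1.21% under HWE needs a no-function haplotype frequency of 0.11
#' prof <- profileFromPhenotypeTargets(c(PM = 0.0121), "CYP2D6", tab)
profileFromPhenotypeTargets <- function(targets, gene, table,
                                        config = defaultPhenotypeConfig(),
                                        tol = 0.005,
                                        label = "fitted") {
  sub <- table@alleles[table@alleles$gene == gene &
                       table@alleles$function_class != "uncertain", ]
  sub <- sub[sub$allele != "*5", ]
  classes <- unique(sub$function_class)
  rep_allele <- vapply(classes, function(cl) {
    cand <- sub$allele[sub$function_class == cl]
    cand[order(starNumber(cand), cand)][1]
  }, "")
  k <- length(classes)
  if (k < 2L && length(targets) > 0 && any(targets < 1))
    stop("need at least two function classes to fit non-trivial targets")

  phenoOfPair <- function(i, j) {
    if (gene == "CYP2D6") {
      act <- vapply(rep_allele, function(a)
        alleleDefinition(table, gene, a)$activity, 0)
      scoreToPhenotype(act[i] + act[j], config)
    } else {
      key <- paste(sort(c(classes[i], classes[j])), collapse = "+")
      config@pairRules[[gene]][[key]] %||%
        stop("phenotype config not total for ", gene, " pair ", key)
    }
  }
  pairPheno <- matrix("", k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    pairPheno[i, j] <- phenoOfPair(i, j)

  mixture <- function(f) {
    probs <- outer(f, f)
    tapply(as.vector(probs), as.vector(pairPheno), sum)
  }
  getOr0 <- function(v, nm) if (nm %in% names(v)) v[[nm]] else 0
  objective <- function(theta) {
    f <- exp(theta - max(theta)); f <- f / sum(f)
    mix <- mixture(f)
    sum(vapply(names(targets), function(ph)
      (getOr0(mix, ph) - targets[[ph]])^2, 0))
  }
  starts <- c(list(rep(0, k)),
              lapply(seq_len(k), function(i) { v <- rep(0, k); v[i] <- 3; v }))
  best <- NULL
  for (s in starts) {
    fit <- stats::optim(s, objective, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  f <- exp(best$par - max(best$par)); f <- f / sum(f)
  mix <- mixture(f)
  resid <- max(vapply(names(targets), function(ph)
    abs(getOr0(mix, ph) - targets[[ph]]), 0))
  if (resid > tol)
    stop(sprintf(
      "targets infeasible under HWE with the available classes; best residual %.4g exceeds tolerance %.4g",
      resid, tol))
  freqs <- stats::setNames(as.numeric(f), rep_allele)
  freqs <- freqs / sum(freqs)
  prof <- newFrequencyProfile(label,
                              stats::setNames(list(freqs), gene))
  attr(prof, "residual") <- resid
  prof
}
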