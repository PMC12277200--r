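## Star caller: per-gene diplotype assignment from genotype-level input,
## with CYP2D6 copy-number handling and unphased-ambiguity bookkeeping.
##
## Calling is genotype-exact: a candidate diplotype is an unordered allele
## pair whose combined defining variants reproduce the observed alternate
## dosage at every indexed position. The CYP2D6 deletion allele *5 carries
## no variants and enters only through the copy-number step, never through
## diploid enumeration.

starNumber <- function(allele) {
  n <- suppressWarnings(as.numeric(sub("^\\*([0-9]+).*$", "\\1", allele)))
  ifelse(is.na(n), Inf, n)
}

orderAlleles <- function(alleles) alleles[order(starNumber(alleles), alleles)]

#' Format a diplotype label
#'
#' @param alleleA,alleleB Allele names.
#' @param multA,multB Copy multiplicities (\code{"*1x2"} style for > 1).
#' @return Diplotype string such as \code{"*1/*4"} or \code{"*1x2/*4"}.
#' @export
diplotypeString <- function(alleleA, multA = 1L, alleleB = alleleA,
                            multB = 1L) {
  lab <- function(a, m) if (m > 1L) paste0(a, "x", m) else a
  ord <- order(starNumber(c(alleleA, alleleB)), c(alleleA, alleleB),
               -c(multA, multB))
  a <- c(alleleA, alleleB)[ord]; m <- c(multA, multB)[ord]
  paste0(lab(a[1], m[1]), "/", lab(a[2], m[2]))
}

newDiplotypeCall <- function(gene, alleleA = NA_character_, multA = 0L,
                             alleleB = NA_character_, multB = 0L,
                             flags = character(),
                             alternatives = character()) {
  structure(list(gene = gene, allele_a = alleleA, mult_a = as.integer(multA),
                 allele_b = alleleB, mult_b = as.integer(multB),
                 flags = flags, alternatives = alternatives,
                 diplotype = if (is.na(alleleA)) NA_character_ else
                   diplotypeString(alleleA, multA, alleleB, multB)),
            class = "DiplotypeCall")
}

#' @export
print.DiplotypeCall <- function(x, ...) {
  cat(x$gene, ": ", if (is.na(x$diplotype)) "no call" else x$diplotype, sep = "")
  if (length(x$flags)) cat(" [", paste(x$flags, collapse = ","), "]", sep = "")
  if (length(x$alternatives))
    cat(" alternatives:", paste(x$alternatives, collapse = ", "))
  cat("\n")
  invisible(x)
}

## dosage + phase extraction from a per-key genotype vector.
## Genotype strings are key-specific: "1" means this key's alternate allele.
gtDosage <- function(genotypes, keys) {
  dos <- stats::setNames(integer(length(keys)), keys)
  phase <- list()
  for (k in intersect(names(genotypes), keys)) {
    g <- genotypes[[k]]
    if (is.na(g) || g %in% c(".", "./.", ".|.")) next
    al <- strsplit(g, "[/|]")[[1]]
    dos[[k]] <- sum(al == "1")
    if (grepl("|", g, fixed = TRUE) && length(al) == 2L)
      phase[[k]] <- as.integer(al == "1")
  }
  list(dosage = dos, phase = phase)
}

#' Enumerate candidate diplotypes for one gene
#'
#' Returns every unordered allele pair whose combined defining variants
#' exactly reproduce the sample's observed alternate dosage at every
#' indexed position (heterozygous = 1, homozygous = 2). Positions of the
#' gene's variant index absent from \code{genotypes} are taken as
#' homozygous reference. Phased genotypes (\code{"0|1"}) constrain the
#' assignment: a pair is kept only if some orientation of its two
#' haplotypes matches every phased site. The all-reference input always
#' yields \code{(*1, *1)}; a dosage pattern no pair can explain yields an
#' empty list (the caller then emits a no-call). The CYP2D6 deletion
#' allele \code{*5} is excluded (it is applied by [applyCopyNumber()]).
#'
#' @param genotypes Named character vector: variant key -> genotype string
#'   (\code{"0/0"}, \code{"0/1"}, \code{"1/1"}, phased variants thereof),
#'   where \code{"1"} denotes that key's alternate allele.
#' @param gene Gene symbol.
#' @param table An [AlleleTable-class].
#' @return List of length-2 character vectors (allele pairs, canonically
#'   ordered).
#' @export
enumerateDiplotypes <- function(genotypes, gene, table) {
  if (!gene %in% table@alleles$gene) stop("unknown gene: ", gene)
  sub <- table@alleles[table@alleles$gene == gene, ]
  sub <- sub[sub$allele != "*5", , drop = FALSE]
  keys <- unique(unlist(sub$variants))
  dp <- gtDosage(genotypes, keys)
  dos <- dp$dosage; phase <- dp$phase
  observed <- names(dos)[dos > 0L]

  comp <- which(vapply(sub$variants, function(v) all(v %in% observed),
                       logical(1)))
  vsets <- sub$variants[comp]
  anames <- sub$allele[comp]
  out <- list()
  for (i in seq_along(comp)) {
    for (j in i:length(comp)) {
      ok <- TRUE
      for (k in observed) {
        if ((k %in% vsets[[i]]) + (k %in% vsets[[j]]) != dos[[k]]) {
          ok <- FALSE; break
        }
      }
      if (!ok) next
      if (length(phase)) {
        orientA <- all(vapply(names(phase), function(k)
          (k %in% vsets[[i]]) == (phase[[k]][1] == 1L) &&
          (k %in% vsets[[j]]) == (phase[[k]][2] == 1L), logical(1)))
        orientB <- all(vapply(names(phase), function(k)
          (k %in% vsets[[j]]) == (phase[[k]][1] == 1L) &&
          (k %in% vsets[[i]]) == (phase[[k]][2] == 1L), logical(1)))
        if (!orientA && !orientB) next
      }
      out[[length(out) + 1L]] <- orderAlleles(c(anames[i], anames[j]))
    }
  }
  unique(out)
}

#' Select one diplotype from the candidate set
#'
#' Default ranking: (1) maximal total number of defining variants explained
#' by named non-reference alleles; (2) fewest distinct non-reference
#' alleles; (3) lexicographic diplotype-label order as a deterministic
#' final tie-break. Candidates tied on criteria (1)-(2) are preserved in
#' \code{alternatives} and the call is flagged \code{unphased_ambiguity}.
#' An empty candidate list yields a \code{no_call}.
#'
#' @param candidates List of allele pairs from [enumerateDiplotypes()].
#' @param gene Gene symbol.
#' @param table An [AlleleTable-class].
#' @return A \code{DiplotypeCall} (list with fields \code{gene},
#'   \code{allele_a}, \code{mult_a}, \code{allele_b}, \code{mult_b},
#'   \code{flags}, \code{alternatives}, \code{diplotype}).
#' @export
selectDiplotype <- function(candidates, gene, table) {
  if (!length(candidates))
    return(newDiplotypeCall(gene, flags = "no_call"))
  sub <- table@alleles[table@alleles$gene == gene, ]
  nvar <- stats::setNames(vapply(sub$variants, length, 0L), sub$allele)
  explained <- vapply(candidates, function(p)
    sum(nvar[p[p != "*1"]]), numeric(1))
  nNonRef <- vapply(candidates, function(p)
    length(unique(p[p != "*1"])), numeric(1))
  labels <- vapply(candidates, function(p)
    diplotypeString(p[1], 1L, p[2], 1L), "")
  ord <- order(-explained, nNonRef, labels)
  best <- ord[1]
  ## equally-scoring = same number of explained variants; parsimony and
  ## name order only choose the representative
  ties <- which(explained == explained[best])
  alts <- setdiff(labels[ties], labels[best])
  flags <- if (length(alts)) "unphased_ambiguity" else character()
  p <- candidates[[best]]
  newDiplotypeCall(gene, p[1], 1L, p[2], 1L, flags = flags,
                   alternatives = sort(alts))
}

#' Apply a CYP2D6 copy number to a diploid call
#'
#' Rewrites a diploid (CN = 2) CYP2D6 call for the sample's measured gene
#' copy number. CN 1 keeps one allele and pairs it with the whole-gene
#' deletion \code{*5} (a homozygous-looking diploid call is the expected
#' input, since hemizygous variant sites present as homozygous to a
#' genotype caller); CN 0 gives \code{*5/*5}; CN >= 3 assigns the extra
#' copies to one allele. For a heterozygous call the duplicated allele is
#' chosen by \code{policy}: \code{"higher"} (default) duplicates the
#' higher-activity allele, \code{"lower"} the lower-activity one, and
#' \code{"ambiguous"} behaves like \code{"higher"} while recording the
#' other assignment; any heterozygous CN != 2 rewrite is flagged
#' \code{cn_ambiguity}.
#'
#' @param call A \code{DiplotypeCall} for CYP2D6 (diploid).
#' @param cn Integer copy number >= 0.
#' @param table An [AlleleTable-class] (activity values for the policy).
#' @param policy One of \code{"higher"}, \code{"lower"}, \code{"ambiguous"}.
#' @return The rewritten \code{DiplotypeCall}.
#' @export
applyCopyNumber <- function(call, cn, table,
                            policy = c("higher", "lower", "ambiguous")) {
  policy <- match.arg(policy)
  if (!is.numeric(cn) || length(cn) != 1L || is.na(cn) || cn < 0 ||
      cn != round(cn))
    stop("copy number must be a single integer >= 0")
  cn <- as.integer(cn)
  if (call$gene != "CYP2D6") stop("copy-number rewrite applies to CYP2D6 only")
  if ("no_call" %in% call$flags || cn == 2L) return(call)
  if (cn == 0L)
    return(newDiplotypeCall("CYP2D6", "*5", 1L, "*5", 1L, flags = call$flags))

  act <- function(a) {
    v <- table@alleles$activity[table@alleles$gene == "CYP2D6" &
                                table@alleles$allele == a]
    if (!length(v)) stop("allele ", a, " absent from table")
    if (is.na(v)) -Inf else v
  }
  a <- call$allele_a; b <- call$allele_b
  het <- !identical(a, b)
  flags <- union(call$flags, if (het) "cn_ambiguity" else character())

  if (cn == 1L) {
    if (!het) return(newDiplotypeCall("CYP2D6", a, 1L, "*5", 1L,
                                      flags = call$flags))
    ## heterozygous diploid call under CN=1: no allele is at full dosage;
    ## keep the one explaining more variants, deterministically.
    nv <- vapply(c(a, b), function(x)
      length(alleleDefinition(table, "CYP2D6", x)$variants), 0L)
    keep <- c(a, b)[order(-nv, starNumber(c(a, b)))][1]
    return(newDiplotypeCall("CYP2D6", keep, 1L, "*5", 1L, flags = flags,
                            alternatives = diplotypeString(
                              setdiff(c(a, b), keep)[1], 1L, "*5", 1L)))
  }

  ## cn >= 3
  if (!het)
    return(newDiplotypeCall("CYP2D6", a, cn - 1L, a, 1L, flags = call$flags))
  pick <- if (policy == "lower") {
    c(a, b)[order(c(act(a), act(b)), starNumber(c(a, b)))][1]
  } else {
    c(a, b)[order(-c(act(a), act(b)), starNumber(c(a, b)))][1]
  }
  other <- setdiff(c(a, b), pick)[1]
  alts <- diplotypeString(other, cn - 1L, pick, 1L)
  newDiplotypeCall("CYP2D6", pick, cn - 1L, other, 1L, flags = flags,
                   alternatives = if (policy == "ambiguous") alts
                                  else character())
}

readCnSidecar <- function(path, samples) {
  cn <- utils::read.delim(path, colClasses = c(copy_number = "integer"))
  need <- c("sample_id", "gene", "copy_number")
  if (!all(need %in% names(cn)))
    stop("CN sidecar must have columns ", paste(need, collapse = ", "))
  bad <- setdiff(cn$sample_id, samples)
  if (length(bad))
    stop("CN sidecar sample(s) absent from VCF: ",
         paste(bad, collapse = ", "))
  if (any(cn$gene != "CYP2D6"))
    stop("copy number is supported for CYP2D6 only")
  if (any(cn$copy_number < 0)) stop("negative copy number")
  cn
}

## Map VCF records to per-gene genotype matrices (variant key x sample) of
## key-specific GT strings ("1" = that key's alternate allele). Diploid GT
## assumed; phasing separators preserved. Also counts non-reference
## genotypes at positions inside a gene region but absent from the index.
vcfGenotypes <- function(path, table) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  samples <- colnames(v@gt)[-1]
  idx <- table@variantIndex
  idxChrom <- sub(":.*$", "", names(idx))
  idxGene <- vapply(idx, function(a) sub("\\|.*$", "", a[1]), "")
  chrom2gene <- tapply(idxGene, idxChrom, function(x) x[1])

  gts <- stats::setNames(vector("list", length(genes(table))), genes(table))
  for (g in genes(table)) {
    keys <- unique(unlist(
      table@alleles$variants[table@alleles$gene == g]))
    gts[[g]] <- matrix("0/0", nrow = length(keys), ncol = length(samples),
                       dimnames = list(keys, samples))
  }
  ignored <- matrix(0L, nrow = length(samples), ncol = length(genes(table)),
                    dimnames = list(samples, genes(table)))
  if (nrow(fix) == 0L)
    return(list(genotypes = gts, samples = samples, ignored = ignored,
                empty = TRUE))

  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, samples))
  for (r in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[r], ",", fixed = TRUE)[[1]]
    raw <- gt[r, ]
    raw[is.na(raw)] <- "./."
    sep <- ifelse(grepl("|", raw, fixed = TRUE), "|", "/")
    sp <- strsplit(raw, "[/|]")
    a1 <- vapply(sp, function(x) x[1], "")
    a2 <- vapply(sp, function(x) if (length(x) > 1L) x[2] else ".", "")
    for (j in seq_along(alts)) {
      key <- paste(fix$CHROM[r], fix$POS[r], fix$REF[r], alts[j], sep = ":")
      c1 <- ifelse(a1 == as.character(j), "1", ifelse(a1 == ".", ".", "0"))
      c2 <- ifelse(a2 == as.character(j), "1", ifelse(a2 == ".", ".", "0"))
      code <- paste0(c1, sep, c2)
      if (key %in% names(idx)) {
        g <- idxGene[[key]]
        gts[[g]][key, ] <- code
      } else {
        g <- chrom2gene[[fix$CHROM[r]]]
        if (!is.null(g) && !is.na(g)) {
          nonref <- c1 == "1" | c2 == "1"
          ignored[, g] <- ignored[, g] + as.integer(nonref)
        }
      }
    }
  }
  list(genotypes = gts, samples = samples, ignored = ignored, empty = FALSE)
}

#' Call diplotypes for a whole cohort
#'
#' Reads a genotype VCF (plus an optional CYP2D6 copy-number sidecar TSV
#' with columns \code{sample_id}, \code{gene}, \code{copy_number}) and
#' produces one diplotype call per sample per gene in the allele table.
#' Identical genotype profiles are called once and reused, so cohort size
#' adds negligible cost beyond VCF parsing. Variants inside a gene region
#' that are absent from the allele index are ignored but counted; samples
#' exceeding \code{ignoredVariantThreshold} non-reference unindexed
#' genotypes in a gene trigger a possible-novel-allele warning. The run is
#' fully deterministic.
#'
#' @param vcf Path to a VCF (v4.2+) with GT fields; phased GT is respected.
#' @param table An [AlleleTable-class].
#' @param cnSidecar Optional path to the copy-number sidecar TSV.
#' @param duplicationPolicy Passed to [applyCopyNumber()].
#' @param ignoredVariantThreshold Per-gene, per-sample unindexed-variant
#'   warning threshold (default 5).
#' @return data.frame with columns \code{sample_id}, \code{gene},
#'   \code{diplotype}, \code{allele_a}, \code{mult_a}, \code{allele_b},
#'   \code{mult_b}, \code{flags}, \code{alternatives}; a summary list of
#'   no-call/ambiguity/ignored counts is attached as attribute
#'   \code{"log"}.
#' @export
callCohort <- function(vcf, table, cnSidecar = NULL,
                       duplicationPolicy = c("higher", "lower", "ambiguous"),
                       ignoredVariantThreshold = 5L) {
  duplicationPolicy <- match.arg(duplicationPolicy)
  parsed <- vcfGenotypes(vcf, table)
  samples <- parsed$samples
  if (parsed$empty)
    warning("VCF contains no variant records; all samples called *1/*1")
  cn <- if (!is.null(cnSidecar)) readCnSidecar(cnSidecar, samples) else NULL
  cnOf <- function(s) {
    if (is.null(cn)) return(2L)
    i <- which(cn$sample_id == s & cn$gene == "CYP2D6")
    if (length(i)) cn$copy_number[i[1]] else 2L
  }
  over <- which(parsed$ignored > ignoredVariantThreshold, arr.ind = TRUE)
  if (nrow(over))
    warning("possible novel allele: ", nrow(over),
            " sample/gene pair(s) exceed ", ignoredVariantThreshold,
            " unindexed non-reference variants")

  rows <- vector("list", length(samples) * length(genes(table)))
  k <- 0L
  nNoCall <- 0L; nAmbig <- 0L; nCnAmbig <- 0L
  for (g in genes(table)) {
    gtm <- parsed$genotypes[[g]]
    sigs <- paste0("k", apply(gtm, 2, paste, collapse = ";"))
    names(sigs) <- samples
    cache <- list()
    for (s in samples) {
      sig <- sigs[[s]]
      if (is.null(cache[[sig]])) {
        gvec <- stats::setNames(gtm[, s], rownames(gtm))
        cand <- enumerateDiplotypes(gvec, g, table)
        cache[[sig]] <- selectDiplotype(cand, g, table)
      }
      call <- cache[[sig]]
      if (g == "CYP2D6")
        call <- applyCopyNumber(call, cnOf(s), table,
                                policy = duplicationPolicy)
      nNoCall <- nNoCall + ("no_call" %in% call$flags)
      nAmbig <- nAmbig + ("unphased_ambiguity" %in% call$flags)
      nCnAmbig <- nCnAmbig + ("cn_ambiguity" %in% call$flags)
      k <- k + 1L
      rows[[k]] <- data.frame(
        sample_id = s, gene = g, diplotype = call$diplotype,
        allele_a = call$allele_a, mult_a = call$mult_a,
        allele_b = call$allele_b, mult_b = call$mult_b,
        flags = paste(call$flags, collapse = ","),
        alternatives = paste(call$alternatives, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])
  rownames(out) <- NULL
  attr(out, "log") <- list(
    n_samples = length(samples), no_call = nNoCall,
    unphased_ambiguity = nAmbig, cn_ambiguity = nCnAmbig,
    ignored_variants = sum(parsed$ignored))
  out
}

#' Write a diplotype call table
#'
#' @param calls data.frame from [callCohort()].
#' @param path Output TSV path.
#' @return Invisibly, \code{path}.
#' @export
writeDiplotypes <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
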