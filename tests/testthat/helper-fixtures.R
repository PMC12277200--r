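# In-code fixtures and independent oracles used across the suite.

# Compact AlleleTable builder: spec is a list of
# list(allele, variants (character vector), function_class, activity).
makeTable <- function(spec, gene = "CYP2D6", build = "synthetic") {
  al <- data.frame(
    gene = gene,
    allele = vapply(spec, function(s) s[[1]], ""),
    function_class = vapply(spec, function(s) s[[3]], ""),
    activity = vapply(spec, function(s) as.numeric(s[[4]]), 0),
    stringsAsFactors = FALSE)
  al$variants <- lapply(spec, function(s) sort(as.character(s[[2]])))
  newAlleleTable(al, build = build)
}

# 4-allele CYP2D6 table where *99's variants are the union of *4's and
# *10's (deliberate overlap, for ambiguity tests).
tinyD6 <- function() makeTable(list(
  list("*1", character(), "normal", 1),
  list("*4", "CYP2D6:100:A:G", "no_function", 0),
  list("*10", "CYP2D6:200:C:T", "decreased", 0.25),
  list("*99", c("CYP2D6:100:A:G", "CYP2D6:200:C:T"), "normal", 1)))

packagedTable <- function() {
  readAlleleTable(system.file("extdata", "allele_definitions.tsv",
                              package = "pgxCohort"))
}

# Exhaustive O(A^2) candidate oracle: every allele pair whose combined
# defining variants reproduce the observed dosage (phase ignored, so use
# unphased genotypes when comparing with enumerateDiplotypes).
oracleEnumerate <- function(genotypes, gene, table) {
  al <- table@alleles[table@alleles$gene == gene &
                      table@alleles$allele != "*5", ]
  keys <- unique(unlist(al$variants))
  dos <- vapply(keys, function(k) {
    if (!k %in% names(genotypes)) return(0L)
    g <- genotypes[[k]]
    if (is.na(g)) 0L else sum(strsplit(g, "[/|]")[[1]] == "1")
  }, 0L)
  res <- character()
  for (i in seq_len(nrow(al))) {
    for (j in i:nrow(al)) {
      got <- vapply(keys, function(k)
        (k %in% al$variants[[i]]) + (k %in% al$variants[[j]]), 0L)
      if (length(keys) == 0L || all(got == dos))
        res <- c(res, paste(sort(c(al$allele[i], al$allele[j])),
                            collapse = "/"))
    }
  }
  sort(unique(res))
}

pairSetOf <- function(candidates)
  sort(unique(vapply(candidates, function(p)
    paste(sort(p), collapse = "/"), "")))

# Genotypes (unphased) implied by a truth diplotype on a given table.
genotypesFor <- function(table, gene, alleleA, alleleB) {
  va <- alleleDefinition(table, gene, alleleA)$variants
  vb <- alleleDefinition(table, gene, alleleB)$variants
  keys <- union(va, vb)
  gt <- vapply(keys, function(k) {
    d <- (k %in% va) + (k %in% vb)
    c("0/0", "0/1", "1/1")[d + 1L]
  }, "")
  stats::setNames(gt, keys)
}

# A CN-event-free copy of a packaged profile (for exact-recovery tests).
noCnProfile <- function(name = "qgp_like") {
  p <- defaultProfile(name)
  newFrequencyProfile(paste0(p@label, "-noCN"), p@frequencies, 0, 0)
}

# Hardy-Weinberg goodness-of-fit p-value for one gene's simulated truth
# diplotypes against the profile's expected unordered-pair frequencies
# (cells with expected count < 5 are pooled).
hweGofP <- function(truth, gene, profile) {
  f <- profile@frequencies[[gene]]
  alleles <- names(f)
  exp_p <- c()
  for (i in seq_along(alleles)) {
    for (j in i:length(alleles)) {
      lab <- paste(sort(c(alleles[i], alleles[j])), collapse = "/")
      exp_p[lab] <- if (i == j) f[i]^2 else 2 * f[i] * f[j]
    }
  }
  dip <- truth$diplotype[truth$gene == gene]
  key <- vapply(strsplit(dip, "/", fixed = TRUE), function(p)
    paste(sort(p), collapse = "/"), "")
  n <- length(key)
  obs <- vapply(names(exp_p), function(l) sum(key == l), 0L)
  pool <- exp_p * n < 5
  if (any(pool)) {
    obs <- c(obs[!pool], other = sum(obs[pool]))
    exp_p <- c(exp_p[!pool], other = sum(exp_p[pool]))
  }
  suppressWarnings(stats::chisq.test(obs, p = exp_p)$p.value)
}

phenoRank <- function(ph)
  match(ph, c("PM", "IM", "NM", "UM"))
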