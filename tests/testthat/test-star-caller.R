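# Diplotype enumeration, selection, copy-number rewriting, cohort calling.

test_that("enumeration handles the reference, homozygous and empty cases", {
  tiny <- tinyD6()
  expect_equal(pairSetOf(enumerateDiplotypes(character(), "CYP2D6", tiny)),
               "*1/*1")
  hom4 <- stats::setNames("1/1", alleleDefinition(tiny, "CYP2D6",
                                                  "*4")$variants)
  expect_equal(pairSetOf(enumerateDiplotypes(hom4, "CYP2D6", tiny)),
               "*4/*4")
  # three heterozygous singleton variants cannot be split over two
  # haplotypes of single-variant alleles
  t3 <- makeTable(list(
    list("*1", character(), "normal", 1),
    list("*4", "CYP2D6:100:A:G", "no_function", 0),
    list("*10", "CYP2D6:200:C:T", "decreased", 0.25),
    list("*17", "CYP2D6:300:G:A", "decreased", 0.5)))
  g3 <- c("CYP2D6:100:A:G" = "0/1", "CYP2D6:200:C:T" = "0/1",
          "CYP2D6:300:G:A" = "0/1")
  expect_length(enumerateDiplotypes(g3, "CYP2D6", t3), 0)
  call <- selectDiplotype(enumerateDiplotypes(g3, "CYP2D6", t3),
                          "CYP2D6", t3)
  expect_true("no_call" %in% call$flags)
  expect_true(is.na(call$diplotype))
})

test_that("candidate sets equal the exhaustive pair oracle", {
  tables <- list(tinyD6(), makeTable(list(
    list("*1", character(), "normal", 1),
    list("*2", c("CYP2D6:10:A:G", "CYP2D6:20:C:T"), "normal", 1),
    list("*4", c("CYP2D6:20:C:T", "CYP2D6:30:G:A"), "no_function", 0),
    list("*10", "CYP2D6:10:A:G", "decreased", 0.25),
    list("*17", "CYP2D6:40:T:C", "decreased", 0.5),
    list("*35", c("CYP2D6:10:A:G", "CYP2D6:40:T:C"), "normal", 1))))
  set.seed(7)
  for (tab in tables) {
    keys <- unique(unlist(tab@alleles$variants))
    alleles <- setdiff(alleleNames(tab, "CYP2D6"), "*5")
    # genotype patterns implied by every possible truth pair, plus random
    cases <- list()
    for (i in seq_along(alleles))
      for (j in i:length(alleles))
        cases[[length(cases) + 1L]] <-
          genotypesFor(tab, "CYP2D6", alleles[i], alleles[j])
    for (r in 1:15) {
      d <- sample(0:2, length(keys), replace = TRUE)
      cases[[length(cases) + 1L]] <-
        stats::setNames(c("0/0", "0/1", "1/1")[d + 1L], keys)
    }
    for (gt in cases) {
      expect_equal(pairSetOf(enumerateDiplotypes(gt, "CYP2D6", tab)),
                   oracleEnumerate(gt, "CYP2D6", tab))
    }
  }
})

test_that("selection ranks by explained variants, parsimony, then name", {
  tiny <- tinyD6()
  # het at *4's and *10's variants: (*4,*10) and (*1,*99) both explain
  # both variants; (*1,*99) has fewer distinct non-reference alleles
  gt <- c("CYP2D6:100:A:G" = "0/1", "CYP2D6:200:C:T" = "0/1")
  cand <- enumerateDiplotypes(gt, "CYP2D6", tiny)
  expect_setequal(pairSetOf(cand), c("*1/*99", "*10/*4"))
  call <- selectDiplotype(cand, "CYP2D6", tiny)
  expect_equal(call$diplotype, "*1/*99")
  expect_true("unphased_ambiguity" %in% call$flags)
  expect_equal(call$alternatives, "*4/*10")
  # single candidate: no flags
  one <- selectDiplotype(list(c("*1", "*4")), "CYP2D6", tiny)
  expect_equal(one$diplotype, "*1/*4")
  expect_length(one$flags, 0)
})

test_that("phased genotypes disambiguate het-het calls", {
  tiny <- tinyD6()
  # *4 and *10 in trans: both variants on opposite haplotypes
  trans <- c("CYP2D6:100:A:G" = "1|0", "CYP2D6:200:C:T" = "0|1")
  expect_equal(pairSetOf(enumerateDiplotypes(trans, "CYP2D6", tiny)),
               "*10/*4")
  # in cis: both on haplotype 1 -> the combined allele *99 with *1
  cis <- c("CYP2D6:100:A:G" = "1|0", "CYP2D6:200:C:T" = "1|0")
  expect_equal(pairSetOf(enumerateDiplotypes(cis, "CYP2D6", tiny)),
               "*1/*99")
})

test_that("selected diplotypes conserve alternate-allele dosage", {
  tab <- packagedTable()
  set.seed(23)
  alleles <- setdiff(alleleNames(tab, "CYP2D6"), "*5")
  for (r in 1:25) {
    pair <- sample(alleles, 2, replace = TRUE)
    gt <- genotypesFor(tab, "CYP2D6", pair[1], pair[2])
    call <- selectDiplotype(enumerateDiplotypes(gt, "CYP2D6", tab),
                            "CYP2D6", tab)
    va <- alleleDefinition(tab, "CYP2D6", call$allele_a)$variants
    vb <- alleleDefinition(tab, "CYP2D6", call$allele_b)$variants
    for (k in names(gt)) {
      dos <- sum(strsplit(gt[[k]], "/", fixed = TRUE)[[1]] == "1")
      expect_equal((k %in% va) + (k %in% vb), dos)
    }
  }
})

test_that("copy-number rewriting follows the stated semantics", {
  tab <- packagedTable()
  het <- selectDiplotype(list(c("*1", "*4")), "CYP2D6", tab)
  hom1 <- selectDiplotype(list(c("*1", "*1")), "CYP2D6", tab)

  expect_equal(applyCopyNumber(het, 2L, tab)$diplotype, "*1/*4")
  expect_equal(applyCopyNumber(hom1, 3L, tab)$diplotype, "*1x2/*1")
  expect_length(applyCopyNumber(hom1, 3L, tab)$flags, 0)

  d3 <- applyCopyNumber(het, 3L, tab)  # default: duplicate higher activity
  expect_equal(d3$diplotype, "*1x2/*4")
  expect_true("cn_ambiguity" %in% d3$flags)
  expect_equal(applyCopyNumber(het, 3L, tab, policy = "lower")$diplotype,
               "*1/*4x2")
  amb <- applyCopyNumber(het, 3L, tab, policy = "ambiguous")
  expect_equal(amb$diplotype, "*1x2/*4")
  expect_equal(amb$alternatives, "*1/*4x2")

  hom4 <- selectDiplotype(list(c("*4", "*4")), "CYP2D6", tab)
  expect_equal(applyCopyNumber(hom4, 1L, tab)$diplotype, "*4/*5")
  expect_equal(applyCopyNumber(het, 0L, tab)$diplotype, "*5/*5")
  expect_error(applyCopyNumber(het, -1L, tab), "integer >= 0")
})

test_that("cohort calling recovers truth exactly on separable cohorts", {
  tab <- packagedTable()
  dir <- tempfile()
  sim <- simulateCohort(noCnProfile(), 80, seed = 101, tab, dir)
  calls <- callCohort(sim$vcf, tab, cnSidecar = sim$cn)
  m <- merge(calls[, c("sample_id", "gene", "diplotype")],
             sim$truth_calls[, c("sample_id", "gene", "diplotype")],
             by = c("sample_id", "gene"), suffixes = c(".called", ".truth"))
  expect_equal(nrow(m), 80 * 4)
  expect_true(all(m$diplotype.called == m$diplotype.truth))
  lg <- attr(calls, "log")
  expect_equal(lg$no_call, 0)
})

test_that("cohort calling is deterministic and handles empty VCFs", {
  tab <- packagedTable()
  dir <- tempfile()
  sim <- simulateCohort(defaultProfile("qgp_like"), 30, seed = 5, tab, dir)
  c1 <- callCohort(sim$vcf, tab, cnSidecar = sim$cn)
  c2 <- callCohort(sim$vcf, tab, cnSidecar = sim$cn)
  expect_identical(c1, c2)

  empty <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=CYP2D6>",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "SAMP1", sep = "\t")), empty)
  expect_warning(calls <- callCohort(empty, tab), "no variant records")
  expect_equal(unique(calls$diplotype), "*1/*1")
})

test_that("CN sidecar sample mismatches are validation errors", {
  tab <- packagedTable()
  dir <- tempfile()
  sim <- simulateCohort(noCnProfile(), 5, seed = 3, tab, dir)
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tgene\tcopy_number", "GHOST\tCYP2D6\t2"), bad)
  expect_error(callCohort(sim$vcf, tab, cnSidecar = bad),
               "absent from VCF")
})
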