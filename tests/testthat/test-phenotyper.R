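# Activity-score arithmetic, bin lookup, categorical translation,
# landscape enumeration.

test_that("activity scores are multiplicity-weighted allele sums", {
  tab <- packagedTable()
  mk <- function(a, b) selectDiplotype(list(c(a, b)), "CYP2D6", tab)
  expect_equal(cyp2d6ActivityScore(mk("*4", "*4"), tab), 0)
  expect_equal(cyp2d6ActivityScore(mk("*1", "*10"), tab), 1.25)
  # *1x2/*1 via a CN=3 rewrite
  tri <- applyCopyNumber(mk("*1", "*1"), 3L, tab)
  expect_equal(cyp2d6ActivityScore(tri, tab), 3.0)
  # deletion contributes zero
  hemi <- applyCopyNumber(mk("*41", "*41"), 1L, tab)
  expect_equal(cyp2d6ActivityScore(hemi, tab), 0.5)
  # uncertain allele -> NA (Indeterminate downstream)
  expect_true(is.na(cyp2d6ActivityScore(mk("*1", "*22"), tab)))
})

test_that("score bins are total, deterministic, and boundary-correct", {
  cfg <- defaultPhenotypeConfig()
  expect_equal(scoreToPhenotype(0, cfg), "PM")
  expect_equal(scoreToPhenotype(1, cfg), "IM")     # boundary inclusive
  expect_equal(scoreToPhenotype(1.25, cfg), "NM")
  expect_equal(scoreToPhenotype(2.25, cfg), "NM")
  expect_equal(scoreToPhenotype(3, cfg), "UM")
  expect_equal(scoreToPhenotype(NA_real_, cfg), "Indeterminate")
  # totality: every non-negative score hits exactly one bin
  set.seed(4)
  for (s in c(runif(200, 0, 6), 0, 1, 2.25, 100)) {
    hits <- sum(s <= cfg@bins$max)
    expect_gte(hits, 1)
    expect_equal(scoreToPhenotype(s, cfg),
                 cfg@bins$phenotype[nrow(cfg@bins) - hits + 1])
  }
})

test_that("categorical translation matches the configured pair rules", {
  tab <- packagedTable()
  cfg <- defaultPhenotypeConfig()
  mk <- function(g, a, b) selectDiplotype(list(c(a, b)), g, tab)
  expect_equal(categoricalPhenotype("CYP2C19", mk("CYP2C19", "*17", "*17"),
                                    tab, cfg), "UM")
  expect_equal(categoricalPhenotype("CYP2C19", mk("CYP2C19", "*1", "*17"),
                                    tab, cfg), "RM")
  expect_equal(categoricalPhenotype("CYP2C19", mk("CYP2C19", "*2", "*2"),
                                    tab, cfg), "PM")
  # two decreased/no-function CYP3A4 alleles -> PM
  expect_equal(categoricalPhenotype("CYP3A4", mk("CYP3A4", "*22", "*20"),
                                    tab, cfg), "PM")
  expect_equal(categoricalPhenotype("CYP2B6", mk("CYP2B6", "*6", "*6"),
                                    tab, cfg), "PM")
  # uncertain member -> Indeterminate
  expect_equal(categoricalPhenotype("CYP2C19", mk("CYP2C19", "*1", "*12"),
                                    tab, cfg), "Indeterminate")
  # a missing pair rule is an error, never silent
  broken <- new("PhenotypeConfig", bins = cfg@bins,
                pairRules = list(CYP2C19 = list("normal+normal" = "NM")))
  expect_error(categoricalPhenotype("CYP2C19", mk("CYP2C19", "*1", "*17"),
                                    tab, broken), "total")
})

test_that("phenotypes are exchange-symmetric in the two alleles", {
  tab <- packagedTable()
  cfg <- defaultPhenotypeConfig()
  set.seed(9)
  for (g in pgxGenes()) {
    alleles <- setdiff(alleleNames(tab, g), "*5")
    for (r in 1:10) {
      p <- sample(alleles, 2)
      ab <- selectDiplotype(list(p), g, tab)
      ba <- selectDiplotype(list(rev(p)), g, tab)
      if (g == "CYP2D6") {
        expect_equal(cyp2d6ActivityScore(ab, tab),
                     cyp2d6ActivityScore(ba, tab))
      } else {
        expect_equal(categoricalPhenotype(g, ab, tab, cfg),
                     categoricalPhenotype(g, ba, tab, cfg))
      }
    }
  }
})

test_that("raising one allele's activity never lowers the phenotype", {
  tab <- packagedTable()
  cfg <- defaultPhenotypeConfig()
  sub <- tab@alleles[tab@alleles$gene == "CYP2D6" &
                     tab@alleles$function_class != "uncertain", ]
  set.seed(31)
  for (r in 1:40) {
    pick <- sub[sample(nrow(sub), 3, replace = TRUE), ]
    base <- scoreToPhenotype(pick$activity[1] + pick$activity[2], cfg)
    hi <- max(pick$activity[2], pick$activity[3])
    up <- scoreToPhenotype(pick$activity[1] + hi, cfg)
    expect_gte(phenoRank(up), phenoRank(base))
  }
})

test_that("landscape enumeration matches the unordered-pair closed form", {
  cfg <- defaultPhenotypeConfig()
  two <- makeTable(list(
    list("*1", character(), "normal", 1),
    list("*4", "CYP2D6:100:A:G", "no_function", 0)))
  l2 <- phenotypeLandscape(two, "CYP2D6", cfg, maxCn = 2L)
  expect_equal(nrow(l2), 3L)  # n(n+1)/2, n = 2
  expect_equal(stats::setNames(l2$phenotype, l2$diplotype),
               c("*1/*1" = "NM", "*1/*4" = "IM", "*4/*4" = "PM"))

  one <- makeTable(list(list("*1", character(), "normal", 1)))
  expect_equal(nrow(phenotypeLandscape(one, "CYP2D6", cfg)), 1L)

  tiny <- tinyD6()
  l4 <- phenotypeLandscape(tiny, "CYP2D6", cfg)
  expect_equal(nrow(l4), 4 * 5 / 2)
  # per-cell oracle: score equals independent activity arithmetic
  act <- stats::setNames(tiny@alleles$activity, tiny@alleles$allele)
  for (i in seq_len(nrow(l4))) {
    parts <- strsplit(l4$diplotype[i], "/", fixed = TRUE)[[1]]
    expect_equal(l4$activity_score[i], sum(act[parts]))
  }
  # a 10-allele table gives 55 combinations at CN=2
  tab <- packagedTable()
  ten <- newAlleleTable(
    tab@alleles[tab@alleles$gene == "CYP2D6", ][1:10, ],
    build = genomeBuild(tab))
  expect_equal(nrow(phenotypeLandscape(ten, "CYP2D6", cfg)), 55L)
})

test_that("phenotypeCohort covers all genes and respects no-calls", {
  tab <- packagedTable()
  calls <- data.frame(
    sample_id = "S1", gene = pgxGenes(),
    diplotype = c("*1/*17", "*1/*4", "*6/*6", "*1/*1"),
    allele_a = c("*1", "*1", "*6", "*1"), mult_a = 1L,
    allele_b = c("*17", "*4", "*6", "*1"), mult_b = 1L,
    flags = "", alternatives = "", stringsAsFactors = FALSE)
  ph <- phenotypeCohort(calls, tab)
  expect_equal(stats::setNames(ph$phenotype, ph$gene),
               c(CYP2C19 = "RM", CYP2D6 = "IM", CYP2B6 = "PM",
                 CYP3A4 = "NM"))
  expect_equal(ph$activity_score[ph$gene == "CYP2D6"], 1.0)
  nc <- calls[2, ]; nc$flags <- "no_call"
  expect_equal(phenotypeCohort(nc, tab)$phenotype, "Indeterminate")
})
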