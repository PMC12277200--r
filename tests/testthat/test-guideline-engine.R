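# Drug rule loading/validation, actionability, combined two-gene
# recommendation matrices.

test_that("the shipped rule config loads, validates and round-trips", {
  rules <- defaultDrugRules()
  expect_s4_class(rules, "DrugRuleSet")
  expect_length(drugs(rules), 14)
  # aliases resolve to the shared TCA rule
  expect_identical(drugRule(rules, "imipramine"),
                   drugRule(rules, "amitriptyline"))
  path <- tempfile(fileext = ".yaml")
  writeDrugRules(rules, path)
  back <- readDrugRules(path)
  for (d in drugs(rules)) {
    a <- rules@rules[[d]]; b <- back@rules[[d]]
    for (f in c("source", "genes", "actionable", "aliases",
                "standard_categories"))
      expect_identical(a[[f]], b[[f]])
    expect_identical(a$matrix, b$matrix)
  }
})

test_that("a non-total two-gene matrix fails validation naming the pair", {
  y <- yaml::read_yaml(system.file("extdata", "drug_rules.yaml",
                                   package = "pgxCohort"))
  y$drugs$sertraline$matrix[["PM+PM"]] <- NULL
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(y, path)
  expect_error(readDrugRules(path), "PM\\+PM")
  y2 <- yaml::read_yaml(system.file("extdata", "drug_rules.yaml",
                                    package = "pgxCohort"))
  y2$drugs$fluvoxamine$actionable <- list("PM", "NOPE")
  yaml::write_yaml(y2, path)
  expect_error(readDrugRules(path), "unknown phenotype")
})

test_that("single-gene actionability matches the guideline statuses", {
  rules <- defaultDrugRules()
  expect_true(isActionable(drugRule(rules, "citalopram_escitalopram"),
                           c(CYP2C19 = "RM")))
  expect_false(isActionable(drugRule(rules, "fluvoxamine"),
                            c(CYP2D6 = "IM")))
  expect_true(isActionable(drugRule(rules, "zuclopenthixol"),
                           c(CYP2D6 = "UM")))
  expect_false(isActionable(drugRule(rules, "quetiapine"),
                            c(CYP3A4 = "IM")))
  expect_false(isActionable(drugRule(rules, "haloperidol"),
                            c(CYP2D6 = "Indeterminate")))
  expect_error(isActionable(drugRule(rules, "quetiapine"),
                            c(CYP2D6 = "PM")), "CYP3A4")
})

test_that("actionable-set nesting holds: zuclopenthixol contains
           haloperidol and pimozide", {
  rules <- defaultDrugRules()
  halo <- drugRule(rules, "haloperidol")$actionable
  pimo <- drugRule(rules, "pimozide")$actionable
  zuclo <- drugRule(rules, "zuclopenthixol")$actionable
  expect_true(all(halo %in% zuclo))
  expect_true(all(pimo %in% zuclo))
  expect_setequal(union(halo, pimo), zuclo)
})

test_that("sertraline matrix anchors and grid totality hold", {
  expect_equal(sertralineRecommendation("PM", "PM")$label, "G")
  expect_equal(sertralineRecommendation("PM", "NM")$label, "D")
  expect_equal(sertralineRecommendation("NM", "PM")$label, "E")
  nmnm <- sertralineRecommendation("NM", "NM")
  rules <- defaultDrugRules()
  rule <- drugRule(rules, "sertraline")
  expect_true(nmnm$label %in% rule$standard_categories)
  flagged <- sertralineRecommendation("Indeterminate", "NM")
  expect_true(flagged$flagged)
  expect_true(is.na(flagged$label))
  # every cell of the 5x4 grid maps to exactly one described category
  for (c19 in phenotypeLevels("CYP2C19")) {
    for (b6 in phenotypeLevels("CYP2B6")) {
      rec <- sertralineRecommendation(c19, b6)
      expect_true(rec$label %in% names(rule$categories))
      expect_type(rec$text, "character")
      # actionability consistent with standard-care categories
      expect_equal(
        isActionable(rule, stats::setNames(c(c19, b6),
                                           c("CYP2C19", "CYP2B6"))),
        !(rec$label %in% rule$standard_categories))
    }
  }
})

test_that("TCA matrix anchors fix the figure-legend cells", {
  expect_equal(tcaRecommendation("RM", "NM")$label, "B")
  expect_equal(tcaRecommendation("UM", "NM")$label, "B")
  expect_equal(tcaRecommendation("NM", "UM")$label, "C")
  expect_equal(tcaRecommendation("NM", "PM")$label, "D")
  expect_equal(tcaRecommendation("NM", "IM")$label, "E")
  # cross-extreme combinations: avoid
  expect_equal(tcaRecommendation("PM", "UM")$label, "A")
  expect_equal(tcaRecommendation("UM", "PM")$label, "A")
  rule <- drugRule(defaultDrugRules(), "amitriptyline")
  expect_true(tcaRecommendation("NM", "NM")$label %in%
                rule$standard_categories)
  for (c19 in phenotypeLevels("CYP2C19"))
    for (d6 in phenotypeLevels("CYP2D6"))
      expect_true(tcaRecommendation(c19, d6)$label %in%
                    names(rule$categories))
})

test_that("cohort classification matches per-sample rule application", {
  rules <- defaultDrugRules()
  mkpheno <- function(id, c19, d6, b6, a4)
    data.frame(sample_id = id, gene = pgxGenes(),
               phenotype = c(c19, d6, b6, a4), stringsAsFactors = FALSE)
  # all-normal sample: nothing actionable
  allNM <- classifyCohort(mkpheno("S1", "NM", "NM", "NM", "NM"), rules)
  expect_false(any(allNM$actionable))
  # CYP2D6 PM sample: every CYP2D6 rule containing PM fires
  pmD6 <- classifyCohort(mkpheno("S2", "NM", "PM", "NM", "NM"), rules)
  hit <- pmD6$drug[pmD6$actionable]
  expect_true(all(c("paroxetine", "fluvoxamine", "venlafaxine",
                    "vortioxetine", "aripiprazole", "brexpiprazole",
                    "haloperidol", "risperidone", "pimozide",
                    "zuclopenthixol") %in% hit))
  # the combined TCA rule fires too: (NM, PM) -> D is non-standard
  expect_true("amitriptyline" %in% hit)
  expect_false("citalopram_escitalopram" %in% hit)
  expect_false("sertraline" %in% hit)
  # missing gene column errors naming the drug's unmet requirement
  noA4 <- mkpheno("S3", "NM", "NM", "NM", "NM")[1:3, ]
  expect_error(classifyCohort(noA4, rules), "quetiapine.*CYP3A4")
})

test_that("classification frequencies follow the phenotype mixture", {
  rules <- defaultDrugRules()
  set.seed(77)
  n <- 4000
  mix <- c(NM = 0.6, IM = 0.25, PM = 0.1, UM = 0.05)
  d6 <- sample(names(mix), n, replace = TRUE, prob = mix)
  ph <- data.frame(
    sample_id = rep(sprintf("S%04d", 1:n), each = 4),
    gene = rep(pgxGenes(), n),
    phenotype = as.vector(rbind("NM", d6, "NM", "NM")),
    stringsAsFactors = FALSE)
  cls <- classifyCohort(ph, rules)
  # pimozide actionable = P(IM) + P(PM) = 0.35, within 3 binomial SE
  p <- mean(cls$actionable[cls$drug == "pimozide"])
  se <- sqrt(0.35 * 0.65 / n)
  expect_lt(abs(p - 0.35), 3 * se)
  # two-gene histogram: category counts + flagged account for every sample
  summ <- summarizeCohort(cls, "mix")
  h <- summ@histograms[["amitriptyline"]]
  fl <- cohortStats(summ)
  expect_equal(sum(h) + fl$flagged[fl$drug == "amitriptyline"], n)
})

test_that("modal TCA categories separate the shipped profiles", {
  tab <- packagedTable()
  rules <- defaultDrugRules()
  modalCat <- function(profile, seed) {
    set.seed(seed)
    sim <- simulateDiplotypes(profile, 4000)
    ph <- phenotypeCohort(sim$truth, tab)
    cls <- classifyCohort(ph, rules)
    rule <- drugRule(rules, "amitriptyline")
    cats <- cls$category[cls$drug == "amitriptyline" & !cls$flagged]
    cats <- cats[!cats %in% rule$standard_categories]
    names(sort(table(cats), decreasing = TRUE))[1]
  }
  expect_equal(modalCat(defaultProfile("qgp_like"), 13), "B")
  expect_equal(modalCat(defaultProfile("1kg_like"), 13), "E")
})
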