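test_that("consequence classes follow the documented precedence", {
  expect_equal(classifyConsequence("c.2912del", "p.(Pro971Glnfs*95)"),
               "frameshift")
  expect_equal(classifyConsequence("c.2332dup", "p.(Met778Asnfs*4)"),
               "frameshift")
  expect_equal(classifyConsequence("c.1374C>A", "p.(Tyr458*)"),
               "nonsense")
  expect_equal(classifyConsequence("c.954-2A>T", "p.?"), "splice")
  expect_equal(classifyConsequence("c.3277+1G>A", "p.?"), "splice")
  expect_equal(classifyConsequence("c.100G>A", "p.(Glu34Lys)"),
               "missense")
  expect_equal(classifyConsequence("Deletion of Exons 15-17", "",
                                   structural = TRUE), "large_deletion")
  # structural flag outranks everything else
  expect_equal(classifyConsequence("c.1C>T", "p.(Gln1*)",
                                   structural = TRUE), "large_deletion")
  expect_equal(classifyConsequence("gibberish", "???"), "other")
  # unicode asterisk normalised
  expect_equal(classifyConsequence("c.209C>G", "p.(Ser70∗)"),
               "nonsense")
})

test_that("CADD and frequency exclusions are strict and context-aware", {
  # monoallelic frequency rule dismisses the high-frequency truncation
  expect_false(frequencyCaddFilter(40, 0.0024, "monoallelic")$keep)
  expect_equal(frequencyCaddFilter(40, 0.0024, "monoallelic")$rule,
               "af_above_monoallelic")
  # the same frequency passes in a biallelic context
  expect_true(frequencyCaddFilter(25, 0.0011, "biallelic")$keep)
  # CADD exactly at the threshold is retained (strict <)
  expect_true(frequencyCaddFilter(15, NA, "monoallelic")$keep)
  expect_false(frequencyCaddFilter(14.99, NA, "monoallelic")$keep)
  expect_equal(frequencyCaddFilter(14.99, NA, "monoallelic")$rule,
               "cadd_below_min")
  # absent CADD passes; absent frequency counts as zero
  expect_true(frequencyCaddFilter(NA, NA, "hemizygous")$keep)
  # hemizygous uses the monoallelic ceiling
  expect_false(frequencyCaddFilter(30, 0.002, "hemizygous")$keep)
  # the CADD rule is recorded as the single first-failing rule
  both <- frequencyCaddFilter(10, 0.5, "monoallelic")
  expect_equal(both$rule, "cadd_below_min")
})

test_that("the FAM83H last-exon rule excludes upstream truncations only", {
  rules <- loadGeneRules()
  # upstream-exon truncating example record: outside the interval
  ex <- fam83hExampleRecord()
  cls <- classifyConsequence(ex$cdna, ex$protein)
  expect_equal(cls, "nonsense")
  g1 <- applyGeneRules(ex$gene, ex$genomic, cls, rules)
  expect_false(g1$keep)
  expect_equal(g1$rule, "gene_rule_failed")
  # last-exon truncating variant is kept
  g2 <- applyGeneRules("FAM83H", "chr8:g.144810257G>T", "nonsense", rules)
  expect_true(g2$keep)
  # non-FAM83H truncations and FAM83H missense pass unchanged
  expect_true(applyGeneRules("ENAM", "chr4:g.71508226G>A", "nonsense",
                             rules)$keep)
  expect_true(applyGeneRules("FAM83H", "chr8:g.144812000G>A", "missense",
                             rules)$keep)
})

test_that("the example record is excluded by the cascade while the cohort survives", {
  ex <- fam83hExampleRecord()
  t1 <- triageVariants(ex)
  expect_false(t1$keep)
  expect_equal(t1$rule, "af_above_monoallelic")
  # with a permissive frequency ceiling the gene rule still excludes it
  t2 <- triageVariants(ex, triageParams(mafMonoallelicMax = 0.01))
  expect_false(t2$keep)
  expect_equal(t2$rule, "gene_rule_failed")

  cohort <- loadReportedCohort()
  t3 <- triageVariants(cohort)
  expect_true(all(t3$keep))
})

test_that("the cascade is idempotent and monotone in the frequency ceiling", {
  ex <- fam83hExampleRecord()
  extra <- data.frame(
    family = ex$family, gene = ex$gene, genomic = ex$genomic,
    cdna = ex$cdna, protein = ex$protein, zygosity = ex$zygosity,
    cadd = ex$cadd, gnomad_af = ex$gnomad_af,
    classification = ex$classification, source_table = "ex",
    sex = NA_character_, structural = FALSE, primary = TRUE,
    stringsAsFactors = FALSE)
  cohort <- rbind(loadReportedCohort(), extra)
  t1 <- triageVariants(cohort)
  kept <- t1[t1$keep, names(cohort)]
  t2 <- triageVariants(kept)
  expect_true(all(t2$keep))  # idempotent on the kept set
  expect_equal(nrow(t2), nrow(kept))

  # tightening the monoallelic ceiling never enlarges the kept set
  ceilings <- c(0.001, 5e-4, 1e-4, 5e-5)
  keptSets <- lapply(ceilings, function(m) {
    t <- triageVariants(cohort, triageParams(mafMonoallelicMax = m))
    which(t$keep)
  })
  for (i in seq_along(keptSets)[-1]) {
    expect_true(all(keptSets[[i]] %in% keptSets[[i - 1]]))
  }

  # excluded variants carry exactly one first-failing rule and replaying
  # provenance reproduces the kept set
  expect_true(all(t1$rule[!t1$keep] != "pass"))
  expect_true(all(t1$rule[t1$keep] == "pass"))
})

test_that("inheritance assembly covers XL, compound het, carrier and unknown genes", {
  modes <- panelModes(loadPanelFixture("ai19"))
  mk <- function(family, gene, genomic, zygosity, sex = NA,
                 primary = TRUE) {
    data.frame(family = family, gene = gene, genomic = genomic,
               zygosity = zygosity, sex = sex, primary = primary,
               consequence = "missense", stringsAsFactors = FALSE)
  }
  # heterozygous female AMELX: XL candidate
  d <- assembleDiagnoses(mk("8", "AMELX", "chrX:g.11314944G>A", "het",
                            "XX"), modes)
  expect_equal(d$mode, "XL")
  expect_equal(d$genotype, "heterozygous")
  expect_equal(d$status, "candidate")
  # two heterozygous ACP4 variants: unphased compound het AR candidate
  d <- assembleDiagnoses(rbind(
    mk("50", "ACP4", "chr19:g.51294940C>T", "het"),
    mk("50", "ACP4", "chr19:g.51295044del", "het")), modes)
  expect_equal(d$mode, "AR")
  expect_equal(d$genotype, "compound_het")
  expect_true(d$unphased)
  # single het in an AR-only gene: carrier, not a candidate
  d <- assembleDiagnoses(mk("70", "WDR72", "chr15:g.53907717G>A", "het"),
                         modes)
  expect_equal(d$status, "carrier")
  # hom in a dual-mode gene is recessive
  d <- assembleDiagnoses(mk("64", "ENAM", "chr4:g.71508226G>A", "hom"),
                         modes)
  expect_equal(d$mode, "AR")
  expect_error(assembleDiagnoses(mk("1", "NOPE", "x", "het"), modes),
               "unknown gene")
})

test_that("digenic reporting lists multi-gene families with their primary gene", {
  res <- replayCohort()
  expect_equal(sort(res$digenic$family), c("18", "25", "4", "62"))
  expect_equal(
    res$digenic$primaryGene[res$digenic$family %in% c("4", "18")],
    c("COL17A1", "COL17A1"))
  expect_equal(
    res$digenic$primaryGene[res$digenic$family %in% c("25", "62")],
    c("MMP20", "MMP20"))
  # single-gene cohorts give an empty report
  single <- res$candidates[res$candidates$family == "1", ]
  expect_equal(nrow(digenicReport(single)), 0L)
})

test_that("cohort summarisation counts families, modes and distinct variants", {
  res <- replayCohort()
  s <- res$summary
  expect_equal(s$solved, length(unique(
    res$candidates$family[res$candidates$status == "candidate"])))
  expect_equal(sum(s$perMode), s$solved)
  expect_equal(sum(s$perClass), s$distinctVariants)
  expect_true(all(diff(as.integer(s$perGene)) <= 0))  # descending
  # empty candidate set: zero everywhere
  s0 <- summarizeCohort(res$candidates[0, ], 181)
  expect_equal(s0$solved, 0L)
  expect_equal(s0$distinctVariants, 0L)
  expect_equal(s0$percentSolved, 0L)
  expect_error(summarizeCohort(res$candidates, 0), "cohort size")
  # summary serialises to JSON
  p <- withr::local_tempfile(fileext = ".json")
  writeCohortSummary(s, p)
  j <- jsonlite::read_json(p)
  expect_equal(j$solved, s$solved)
})

test_that("annotation joins by variant key and flags unmatched calls", {
  calls <- data.frame(contig = "chr1", pos = c(100L, 200L), ref = "A",
                      alt = "T", stringsAsFactors = FALSE)
  ann <- data.frame(contig = "chr1", pos = 100L, ref = "A", alt = "T",
                    gene = "G1", cadd = 22, gnomad_af = 1e-4,
                    stringsAsFactors = FALSE)
  out <- annotateCalls(calls, ann)
  expect_equal(out$gene, c("G1", NA))
  expect_equal(out$annotated, c(TRUE, FALSE))
  # stripping annotation reproduces the call set
  expect_equal(out[names(calls)], calls)
  expect_error(annotateCalls(calls, rbind(ann, ann)), "duplicate keys")
})

test_that("the cohort fixture is self-consistent", {
  cohort <- loadReportedCohort()
  # one family set across the three per-mode tables
  prim <- cohort[cohort$primary, ]
  expect_equal(length(unique(prim$family)),
               length(unique(cohort$family)))
  # zygosity-derived sex is present exactly for X-linked records
  expect_true(all(!is.na(cohort$sex[cohort$gene == "AMELX"])))
  expect_true(all(cohort$zygosity[cohort$sex %in% "XY" &
                                    cohort$gene == "AMELX" &
                                    cohort$zygosity != "het"] == "hemi"))
  # genomic keys parse for every non-structural record
  nonStruct <- cohort[!cohort$structural, ]
  expect_true(all(grepl("^chr[0-9X]+:g\\.", nonStruct$genomic)))
})
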