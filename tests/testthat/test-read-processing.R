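test_that("UMI extraction takes the read-2 prefix and skips short reads", {
  r <- extractUmi(c("ACGTACGTTTTTTTTT", "ACGTAC"), umiLength = 8L)
  expect_equal(r$umi[1], "ACGTACGT")
  expect_equal(r$trimmed[1], "TTTTTTTT")
  expect_true(r$skipped[2])
  expect_true(is.na(r$umi[2]))
})

test_that("extracted UMIs match truth for all error-free reads", {
  ref <- makeTestRef()
  panel <- makeTestPanel(ref)
  s <- simulateSample(panel, ref, NULL,
                      simParams(seed = 21L, meanMolecules = 50,
                                errorRate = 0))
  um <- extractUmi(s$reads2, 8L)
  expect_identical(unname(um$umi), s$truth$umi)
})

test_that("probe assignment tolerates the mismatch budget and refuses ties", {
  ref <- makeTestRef()
  panel <- makeTestPanel(ref)
  probes <- panelProbes(panel)
  mc <- S4Vectors::mcols(probes)
  r1 <- paste0(mc$ext_seq[1], mc$gap_seq[1])
  r2t <- paste0(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(mc$lig_seq[1]))), substr(mc$gap_seq[1], 1, 50))
  expect_equal(assignProbe(r1, r2t, probes), mc$probe_id[1])

  flip <- function(s, k) {
    for (p in seq_len(k)) {
      b <- substr(s, p, p)
      substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), b)[1]
    }
    s
  }
  expect_equal(assignProbe(flip(r1, 2), r2t, probes), mc$probe_id[1])
  expect_true(is.na(assignProbe(flip(r1, 2), flip(r2t, 1), probes)))

  # two probes with identical arms tie and the read stays unassigned
  twin <- probes[c(1, 1)]
  S4Vectors::mcols(twin)$probe_id <- c("a", "b")
  expect_true(is.na(assignProbe(r1, r2t, twin)))
})

test_that("arm trimming retains only gap-fill bases", {
  params <- designParams()
  read <- strrep("A", 150)
  expect_equal(nchar(trimArms(read, params)), 110L)  # min(129, 110)
  # generic arithmetic: with a longer nominal gap the whole remainder stays
  wide <- designParams(gapFillLength = 129L)
  expect_equal(nchar(trimArms(read, wide)), 129L)
  expect_true(is.na(trimArms(strrep("A", 21), params)))
})

test_that("a variant under an arm never reaches the pileup", {
  ref <- makeTestRef()
  panel <- makeTestPanel(ref)
  probes <- panelProbes(panel)
  # plant inside probe 1's extension-arm flank (just left of the gap)
  strand1 <- as.character(GenomicRanges::strand(probes)[1])
  armPos <- if (strand1 == "+") GenomicRanges::start(probes)[1] - 3L else
    GenomicRanges::end(probes)[1] + 3L
  cseq <- as.character(ref[["chr1"]])
  refb <- substr(cseq, armPos, armPos)
  pv <- plantedVariants("chr1", armPos - 1L, refb,
                        setdiff(c("A", "C", "G", "T"), refb)[1],
                        "hom", "snv")
  s <- simulateSample(panel, ref, pv,
                      simParams(seed = 31L, meanMolecules = 60,
                                errorRate = 0))
  pr <- processReads(s$reads1, s$reads2, probes)
  pu <- pileupFragments(pr$fragments, ref)
  expect_false(armPos %in% pu$alleles$pos)
})

test_that("dedup groups by (probe, UMI), takes the majority and is idempotent", {
  ref <- makeTestRef()
  panel <- makeTestPanel(ref)
  probes <- panelProbes(panel)
  mc <- S4Vectors::mcols(probes)
  gap <- mc$gap_seq[1]
  alt <- gap
  substr(alt, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                 substr(gap, 10, 10))[1]
  records <- data.frame(
    probe_id = mc$probe_id[1],
    umi = c("AAAAAAAA", "AAAAAAAA", "AAAAAAAA", "CCCCCCCC", "CCCCCCCC"),
    target = c(alt, alt, gap, gap, gap), stringsAsFactors = FALSE)
  fr <- dedupConsensus(records, probes)
  expect_equal(nrow(fr), 2L)
  expect_equal(fr$n_reads, c(3L, 2L))
  # majority {alt, alt, gap} -> alt at position 10
  consSeq <- fr$consensus[fr$umi == "AAAAAAAA"]
  if (as.character(GenomicRanges::strand(probes)[1]) == "-") {
    consSeq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(consSeq)))
  }
  expect_equal(consSeq, alt)

  # idempotence: rerunning on the collapsed fragments changes nothing
  again <- dedupConsensus(
    data.frame(probe_id = fr$probe_id, umi = fr$umi,
               target = vapply(seq_len(nrow(fr)), function(i) {
                 if (as.character(GenomicRanges::strand(probes)[
                   match(fr$probe_id[i], mc$probe_id)]) == "-")
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(fr$consensus[i])))
                 else fr$consensus[i]
               }, character(1)), stringsAsFactors = FALSE), probes)
  expect_equal(again$consensus, fr$consensus)
  expect_equal(nrow(again), nrow(fr))
})

test_that("dedup equals the brute-force grouping oracle on simulated reads", {
  ref <- makeTestRef()
  panel <- makeTestPanel(ref)
  probes <- panelProbes(panel)
  pv <- randomPlantedVariant(ref, probes, 2L, 40L, "snv", "het")
  s <- simulateSample(panel, ref, pv,
                      simParams(seed = 41L, meanMolecules = 120,
                                errorRate = 0.005))
  pr <- processReads(s$reads1, s$reads2, probes)
  um <- extractUmi(s$reads2, 8L)
  ids <- assignProbe(s$reads1, um$trimmed, probes)
  keep <- !is.na(ids)
  records <- data.frame(probe_id = ids[keep], umi = um$umi[keep],
                        target = trimArms(s$reads1[keep]),
                        stringsAsFactors = FALSE)
  expect_equal(pr$fragments, oracleDedup(records, probes))
})

test_that("read conservation holds: assigned + unassigned + skipped = input", {
  ref <- makeTestRef()
  panel <- makeTestPanel(ref)
  s <- simulateSample(panel, ref, NULL,
                      simParams(seed = 51L, meanMolecules = 60,
                                errorRate = 0.01))
  # corrupt some reads: junk and short records
  s$reads1[1:5] <- strrep("G", 150)
  s$reads2[6:8] <- "ACGT"
  pr <- processReads(s$reads1, s$reads2, panelProbes(panel))
  expect_equal(pr$assigned + pr$unassigned + pr$skipped,
               length(s$reads1))
  expect_equal(pr$skipped, 3L)
  expect_gte(pr$unassigned, 5L)
})

test_that("consensus suppresses sequencing error below the single-read rate", {
  ref <- makeTestRef()
  panel <- makeTestPanel(ref)
  probes <- panelProbes(panel)
  errRate <- 0.01
  s <- simulateSample(panel, ref, NULL,
                      simParams(seed = 61L, meanMolecules = 100,
                                dupGeomP = 0.25, errorRate = errRate))
  pr <- processReads(s$reads1, s$reads2, probes)
  fr <- pr$fragments[pr$fragments$n_reads >= 3L, ]
  mc <- S4Vectors::mcols(probes)
  mism <- 0L; tot <- 0L
  for (i in seq_len(nrow(fr))) {
    j <- match(fr$probe_id[i], mc$probe_id)
    gapGenomic <- if (as.character(GenomicRanges::strand(probes)[j]) ==
                      "-") {
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(mc$gap_seq[j])))
    } else mc$gap_seq[j]
    a <- utf8ToInt(fr$consensus[i]); b <- utf8ToInt(gapGenomic)
    mism <- mism + sum(a != b)
    tot <- tot + length(a)
  }
  expect_gt(tot, 1000L)
  expect_lt(mism / tot, errRate / 2)
})

test_that("coverage breadth counts bases strictly above the threshold", {
  expect_equal(coverageBreadth(c(25, 25, 10, 30), 20), 0.75)
  expect_equal(coverageBreadth(numeric(0)), 0)

  ref <- makeTestRef()
  panel <- makeTestPanel(ref)
  s <- simulateSample(panel, ref, NULL,
                      simParams(seed = 71L, meanMolecules = 80,
                                efficiencySigma = 0.2, errorRate = 0))
  pr <- processReads(s$reads1, s$reads2, panelProbes(panel))
  rep <- coverageReport(pr$fragments, panelRegions(panel), threshold = 20)
  expect_true(rep$panel >= 0 && rep$panel <= 1)
  expect_gt(rep$panel, 0.99)  # uniform-ish depth ~80 per probe
  expect_error(coverageReport(pr$fragments, GenomicRanges::GRanges()),
               "empty region set")
})
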