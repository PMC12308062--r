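# mipscreen

Targeted genetic screening with single molecule molecular inversion
probes (smMIPs), end to end: panel design, capture simulation, UMI-aware
read processing, simplified variant and copy-number calling, and a
variant-triage cascade with Mendelian inheritance-mode assembly.

## Who this is for

smMIP panels are a low-cost alternative to exome sequencing for
screening disease cohorts against a fixed gene list. An smMIP is an
oligonucleotide whose two target-complementary arms (extension and
ligation, 45 nt combined) flank a 110 nt gap-fill region; the gap is
copied, circularised and amplified, and an 8 nt stretch of degenerate
bases in the probe backbone (the UMI, 4^8 combinations) tags each
captured molecule so PCR duplicates can be collapsed. This package
implements the computational side of such a screen for a 19-gene
amelogenesis imperfecta (AI) panel — the inherited enamel-formation
disorder whose isolated forms segregate as autosomal dominant (AD),
autosomal recessive (AR) or X-linked (XL) traits — and ships the
panel's gene table and a transcribed screening-cohort fixture so the
whole workflow can be exercised without access to patient data.

## The core model

* **Design.** Target regions are tiled into gap-fill windows of length
  `G = 110` with adjacent overlap of at least 10 bp; for a region of
  length `L > G` the window count is `ceiling((L - G)/(G - 10)) + 1`,
  with starts spread evenly. Candidates on both strands are scored with
  a transparent logistic stand-in,
  `score = logistic(2.5 - 6|GC_arm - 0.5| - 4|GC_target - 0.5| - 0.3 * maxHomopolymer)`,
  and one probe per window is selected (score floor 0.5, below-floor
  candidates kept but flagged). Pool rebalancing sets each probe's
  volume factor to `clip(target / depth, 0.25, 4)`.
* **Processing.** Reads are assigned to probes by arm-anchored Hamming
  matching (<= 2 mismatches), arms are trimmed so probe-derived bases
  never reach a pileup, and reads sharing a (probe, UMI) pair are
  collapsed to a majority-vote consensus fragment.
* **Calling.** A deterministic threshold genotyper over consensus
  fragments (no-call below depth 8; hom/hemi at alt fraction >= 0.85;
  het in [0.25, 0.75]) and a median-ratio copy-number rule (ratio of
  library-normalised probe depth to a reference cohort's median; runs of
  >= 3 probes below 0.65 are heterozygous deletions, below 0.1
  homozygous, above 1.4 duplications).
* **Triage.** Variants are excluded when CADD < 15 (strict), or when
  the gnomAD allele frequency exceeds 0.01 in a biallelic genotype
  context or 0.001 in a monoallelic/hemizygous one; truncating FAM83H
  variants qualify only in the gene's large last exon. Surviving
  variants are assembled into per-family diagnosis candidates (hom or
  compound het in AR-capable genes; single het in AD-capable genes; any
  qualifying AMELX genotype as XL) and summarised cohort-wide, with
  families carrying candidates in two genes reported as digenic.

## Worked example

```r
library(mipscreen)

res <- replayCohort(cohortSize = 181L)
res$summary$solved          # 63
res$summary$percentSolved   # 35
res$summary$perMode         # XL 7, AD 29, AR 27
res$summary$distinctVariants  # 56
nrow(res$digenic)           # 4  (families 4, 18, 25, 62)
```

Running the replay prints a molecular diagnosis for 63 of 181 probands
(35%): 7 X-linked, 29 dominant and 27 recessive families, built from 56
distinct variants, with four families carrying qualifying genotypes in
two genes at once (a possible digenic signal; the primary gene is
designated per family).

The simulation side works from synthetic references:

```r
ref     <- randomReference(c(chr1 = 3000L), seed = 42)
regions <- GenomicRanges::GRanges("chr1", IRanges::IRanges(501, width = 300),
                                  gene = "G1", label = "ex1")
probes  <- designProbes(regions, ref)   # 3 probes, 110 nt gap fills
panel   <- MipPanel(data.frame(symbol = "G1", transcript = "NM_000001.1",
                               contig = "chr1", start = 1, end = 3000,
                               cytoband = "1p1", modes = "AR"),
                    regions = regions, probes = probes)
sim   <- simulateSample(panel, ref, params = simParams(seed = 7))
frags <- processReads(sim$reads1, sim$reads2, probes)$fragments
calls <- callSmallVariants(pileupFragments(frags, ref))
```

A thin command-line wrapper is available at
`inst/scripts/mipscreen.R` (`panel-validate`, `design`, `rebalance`,
`cohort-summarize`).

## Scope

The package does not reproduce the physical reagent: the optimised
probe pool's composition, its empirical score distribution and its
coverage performance on control DNA depend on a human reference genome,
an external design tool and the wet-lab protocol, and are out of scope.
The probe score here is a documented stand-in, not comparable to
external design scores, and ACMG pathogenicity classification is
carried as read-only labels, never computed.
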