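---
title: "Methods: smMIP panel design, simulation and variant triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: smMIP panel design, simulation and variant triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mipscreen)
```

# The screening problem

Single molecule molecular inversion probes (smMIPs) capture a fixed set
of genomic intervals from many samples at low cost. Each probe is a
single-stranded oligo: two target-complementary arms — extension and
ligation, 45 nt combined — flank a common backbone carrying universal
PCR primer sites and an 8 nt stretch of degenerate bases. The arms
hybridise either side of a 110 nt gap-fill region; polymerase fills the
gap, ligase circularises the product, and PCR amplifies it. The
degenerate stretch acts as a unique molecular identifier (UMI): reads
sharing a probe and UMI derive from one captured molecule, so PCR
duplicates can be collapsed and polymerase errors suppressed by
consensus.

This package implements the full computational path of such a screen —
design, capture simulation, read processing, calling, and triage — for
panels like the packaged 19-gene amelogenesis imperfecta (AI) panel,
where each gene is annotated with the inheritance modes (AD, AR, XL) it
can act through.

# Probe design

## Tiling

A target region of length $L$ is tiled into windows of the gap-fill
length $G = 110$ so that every base is covered and adjacent windows
overlap by at least 10 bp. For $L > G$ the window count is the closed
form $\lceil (L-G)/(G-o) \rceil + 1$ with $o = 10$; starts are spread
evenly, which maximises the minimum pairwise overlap. Regions shorter
than $G$ receive a single window centred on the region, its flanks drawn
from the reference: the region is silent on how sub-window targets
should be handled, and a centred window keeps the target maximally far
from the trimming boundaries.

## Arms and geometry

Arms are taken from the reference immediately flanking the window, with
no overlap into it. The 45 nt total is split 21 (extension) / 24
(ligation) by default; only the total is a hard design constraint, so
the split is configurable. Arm and gap sequences are stored in
*sequenced orientation*: for a minus-strand probe the flanks are
reverse-complemented and their roles swapped, so that in either
orientation a captured molecule reads extension arm, gap fill, ligation
arm. The assembled oligo is ligation arm + linker + N×8 + linker +
extension arm; the shipped linker pair is a fixed default (so oligos
are reproducible) standing in for universal primer sites, and the
backbone (arms + linkers + UMI) totals 83 nt with the default geometry.

## Scoring

External probe-design tools score candidates with a trained logistic
regression whose coefficients are not public. We do not attempt to
reproduce it. The packaged stand-in is a transparent logistic in three
interpretable covariates:

$$\mathrm{score} = \mathrm{logistic}\!\left(2.5 - 6\,|GC_{arm}-0.5|
  - 4\,|GC_{target}-0.5| - 0.3\,H\right)$$

where $H$ is the longest homopolymer run across arms and gap fill.
Balanced GC and short runs score above the 0.5 selection floor;
AT- or GC-extreme arms score low. The coefficients are fixed constants
chosen so that the floor separates "comfortable" from "difficult"
sequence, mirroring the practice of accepting sub-floor probes only in
difficult regions (such probes are kept but flagged `below_floor`).
Scores are *not* comparable to any external tool's values; they exist
so selection, the floor, and the relaxation path are real, testable
code paths.

Selection ties break deterministically: higher score, then plus strand,
then leftmost start.

## Rebalancing

Pool rebalancing emulates the iterative equalisation of per-probe
depth: given observed mean depths $d_i$ and a target $t$, the volume
factor is $\mathrm{clip}(t/\max(d_i, 1), 0.25, 4)$. The clip bounds and
the failure rule (depth below 5% of the median marks the probe failed,
factor 0, flagged for redesign) are package defaults — the procedure's
shape, not its exact constants, is what is documented upstream. The
simulator models capture efficiency as an *intrinsic, reproducible
property of each probe* (a log-normal quantile drawn from a
probe-indexed stream independent of the run seed): without persistence
across runs, depth-based rebalancing could not reduce depth variance
between runs, contradicting the procedure it emulates.

# Capture simulation

The simulator is first-class, tested code; it is the package's
substitute for raw sequencing data, which screening studies typically
cannot deposit.

For each probe, the number of unique molecules is
$\mathrm{Poisson}(\mu \cdot e_i \cdot c_i \cdot k)$ with $\mu$ the mean
molecules per probe (`meanMolecules`, default 100), $e_i$ the intrinsic
log-normal efficiency (`efficiencySigma`, default 0.5), $c_i$ the
relative concentration (rebalancing hook), and $k$ a local copy factor
(1; 0.5 inside a heterozygous deletion span; 0 inside a homozygous
one). Each molecule draws a UMI uniformly over $4^8$ sequences, a
haplotype, and $1+\mathrm{Geom}(p)$ read pairs (`dupGeomP`, default
0.5). Read 1 starts at the extension-arm end of the molecule and, at
150 bp, spans the whole 110 nt gap fill; read 2 carries the UMI, then
the ligation arm and target in reverse complement. Substitution errors
are i.i.d. per base (`errorRate`, default 0.001); qualities are
constant Q30 and the error process is substitution-only so that the
planted truth stays exact — indels enter only via haplotypes.
Identical seeds give byte-identical output.

What the simulator does *not* emulate: polymerase slippage, strand
bias, index hopping, per-cycle quality decay, demultiplexing (one file
pair per sample), and any empirical per-probe efficiency distribution —
the log-normal sigma is a free parameter, not an estimate. Passing
tests therefore demonstrate the pipeline's correctness under a clean
generative model, not its robustness to every artefact of real
instruments.

# Read processing

Genome alignment is deliberately replaced by **arm-anchored probe
assignment**: the panel is small and probes carry coordinates, so a
read pair is assigned to the unique probe whose expected arm sequences
match the read termini with at most 2 mismatches in total (Hamming
distance at fixed offsets; ties and non-matches are unassigned, which
is a value, not an error). This is the package's largest deliberate
divergence from alignment-based pipelines; off-target reads are simply
unassigned, and indel-containing arms are a documented blind spot of
the fixed-offset matching.

Arms are trimmed positionally — probe-derived bases must never reach a
pileup — and reads sharing (probe, UMI) are collapsed to a
majority-vote consensus per position, ties breaking to the reference
base (with constant qualities the documented quality tie-break reduces
to the reference rule). Collapsing to a consensus, rather than merely
marking duplicates, is equivalent for counting and better for error
suppression. The target consensus is drawn from read 1 only, which
covers the whole gap fill at the default geometry; read 2 contributes
the UMI and the ligation-arm anchor. Using both mates would require
arbitrating mate offsets for indel haplotypes, for no depth gain.

Coverage breadth is the fraction of targeted bases with consensus depth
*strictly greater than* the threshold (default 20), the natural reading
of "more than 20 reads"; the threshold is configurable.

# Variant calling

Fragments identical to their reference gap are pure depth. Differing
fragments are compared directly when a handful of substitutions
explains them; otherwise (length change, or a dense mismatch run that
signals a shifted indel haplotype whose positional trim drew in foreign
flank bases) the fragment is globally aligned to the reference gap
(match 2, mismatch −3, gap open 5, extend 2) and alleles are read off
the alignment. All alleles are left-aligned to the VCF convention by
trimming shared trailing bases, extending empty alleles with left
reference context, and trimming shared leading bases beyond the anchor.

Two numerical guards matter at window boundaries. Alleles starting
within `edgeMask` (3) bases of a fragment end are trimming-boundary
artefacts and are ignored; consistently, each fragment contributes
*depth* only over its callable (edge-shrunk) span. Without the second
rule, positions in the overlap of adjacent windows accumulate depth
from fragments that can never report an allele there, diluting alt
fractions and miscalling homozygotes as heterozygotes.

The genotyper is a deterministic threshold rule: no-call below depth 8;
hom (hemi on chrX in XY samples) at alt fraction ≥ 0.85; het in
[0.25, 0.75]; intermediate fractions flagged ambiguous; alleles with
fewer than 2 supporting fragments or fraction < 0.1 are residual
consensus error and are dropped. The thresholds are package choices —
no caller parameters are documented upstream — and local assembly is
deliberately not reproduced: arms are trimmed, fragments are short and
probe-anchored, so a pileup suffices.

Copy number uses a median-ratio rule instead of a beta-binomial model:
each probe's library-normalised depth is divided by the median of the
same quantity over ≥ 3 reference samples; runs (within a gene, probe
order) of ≥ 3 probes with ratio < 0.65 / < 0.1 / > 1.4 are heterozygous
deletions, homozygous deletions, duplications. Probes whose reference
median is zero are masked and recorded. The intrinsic-efficiency model
makes per-probe efficiency cancel in the ratio, which is exactly the
situation a real reference cohort approximates. A caveat follows from
library-size normalisation: when a deleted span is a large fraction of
the panel the normaliser itself shrinks and ratios are biased upward —
real multi-gene panels keep any one gene a small fraction of probes,
and the tests mirror that.

VCF output is 4.2, single sample, GT/DP/AF (`0/1`, `1/1`, hemizygous
`1`); tests round-trip it through an independent parser.

# Variant triage

The cascade excludes a variant when (first) its CADD score is present
and strictly below 15, or (second) its population allele frequency
exceeds the ceiling for its genotype context: 0.01 when biallelic,
0.001 when monoallelic or hemizygous. Absent frequency counts as 0;
absent CADD passes the score test — several retained truncating
variants in the packaged cohort print no score. "Biallelic" is
operationalised as the variant's context in the candidate genotype
(homozygous or member of a multi-variant family/gene group; a lone
heterozygous variant is monoallelic; hemizygous X uses the monoallelic
ceiling). The context is fixed by the *input* genotypes and carried
through, which makes the cascade idempotent and its rules
order-independent; each excluded variant records exactly one
first-failing rule, so replaying provenance reproduces the kept set.

One gene-specific rule ships: truncating (nonsense or frameshift)
FAM83H variants qualify only inside the gene's large last coding exon.
The packaged interval is an approximation of that exon, chosen to
separate last-exon truncations from upstream-exon ones on this panel,
and is marked as such in the fixture; the packaged counter-example
record (a recurrent upstream-exon truncation with frequency 0.0024)
is excluded twice over — by the monoallelic frequency ceiling and,
were the ceiling relaxed, by the gene rule.

Consequence classes are parsed from HGVS nomenclature with a
deterministic precedence — structural > frameshift > nonsense > splice
> missense > other — where splice requires an intronic offset in the
cDNA together with an unknown protein effect. Unparseable nomenclature
falls to `other` rather than failing.

Inheritance assembly per family and gene: homozygous or ≥ 2
heterozygous variants in an AR-capable gene form a recessive candidate
(compound heterozygotes are assumed in trans and flagged `unphased`;
segregation confirmation is out of scope); a single heterozygous
variant in an AD-capable gene forms a dominant candidate; any
qualifying genotype in the X-linked gene forms an XL candidate
(heterozygous females included — the packaged cohort reports such
families as X-linked); a lone heterozygous variant in an AR-only gene
is a carrier note. Families with candidates in two genes appear in the
digenic report with their designated primary gene.

The cohort summary counts solved families, per-mode and per-gene
tallies (one primary candidate per family), distinct variants across
primary candidates (deduplicated by genomic key), and the solved
percentage rounded half away from zero. Per-consequence-class tallies
are *reported but not asserted* anywhere: the transcription's recurrent
variants and secondary-gene records make independent class tallies
genuinely ambiguous, so only the family and distinct-variant counts are
treated as checkable.

# Fixtures and their limits

The `ai19` panel fixture carries the 19 genes, transcripts, hg19
intervals (converted once to 0-based half-open form), cytobands and the
per-gene mode map; it ships **no probes** — the optimised physical
reagent's composition, score tally and coverage performance on control
DNA are properties of the reagent and a human reference genome, and are
out of scope here. Exon-level regions for simulations are synthetic and
built in code. The cohort fixture transcribes the published per-family
variant tables, with secondary-gene records of the digenic families
flagged `primary = FALSE`; sample sex is inferred from X-linked
zygosity (heterozygous → XX, hemizygous → XY) and left missing for
autosomal families, where the assembler does not use it.

# Problem sizes and reproducibility

The shipped tests run on synthetic panels of 6–23 probes with 60–1800
molecules per probe: large enough that binomial and chi-square checks
have power (UMI uniformity on > 10^4 tags; duplicate-size means within
3 standard errors over > 5000 groups; ~10^4 reads for the
deduplication oracle; 20 seeded samples for genotype recovery; 10 null
and 1 planted run for copy number; 5 seeds for rebalancing), and small
enough to keep the full suite in minutes on one core. All randomness
flows from explicit seeds; identical seeds give byte-identical
simulator output.

# Known limitations

* Arm matching is Hamming-at-fixed-offset; reads with indels inside an
  arm go unassigned.
* The pileup genotyper has no local assembly and no base-quality
  model; densely clustered variants within one fragment rely on the
  global alignment heuristics.
* The copy-number rule reports probe-resolution segments, not
  breakpoints, and needs ≥ 3 consecutive affected probes.
* UMI collisions (two molecules, one tag) are not corrected; at 4^8
  tags and panel-scale molecule counts the collision rate is
  negligible, and no directional-network error correction of UMIs is
  attempted.
* ACMG classification is carried as read-only labels from the fixture;
  the package computes none.
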