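# shared synthetic fixtures and independent oracles

`%+%` <- function(a, b) paste0(a, b)

# one-contig reference and a small two-region panel used across suites
makeTestRef <- function(seed = 42L, len = 3000L) {
  randomReference(c(chr1 = len), seed = seed)
}

makeTestPanel <- function(ref, regionStarts = c(501L, 1501L),
                          regionWidths = c(300L, 250L)) {
  regions <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(regionStarts, width = regionWidths),
    gene = "G1", label = paste0("ex", seq_along(regionStarts)))
  probes <- designProbes(regions, ref)
  panel <- MipPanel(
    data.frame(symbol = "G1", transcript = "NM_000001.1",
               contig = "chr1", start = 1L,
               end = Biostrings::width(ref)[1], cytoband = "1p1",
               modes = "AR"),
    regions = regions, probes = probes)
  panel
}

# oracle: slow, obvious (probe, UMI) grouping with per-column majority;
# written independently of dedupConsensus (nested loops, no vectorised
# tie handling beyond the same documented rules)
oracleDedup <- function(records, probes) {
  mc <- S4Vectors::mcols(probes)
  keys <- unique(paste(records$probe_id, records$umi, sep = "|"))
  out <- NULL
  for (k in keys) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    rows <- which(records$probe_id == parts[1] & records$umi == parts[2])
    seqs <- records$target[rows]
    i <- which(mc$probe_id == parts[1])
    refGap <- mc$gap_seq[i]
    L <- max(nchar(seqs))
    cons <- character(L)
    for (j in seq_len(L)) {
      votes <- character(0)
      for (s in seqs) {
        if (nchar(s) >= j) votes <- c(votes, substr(s, j, j))
      }
      tab <- sort(table(votes), decreasing = TRUE)
      winners <- names(tab)[tab == tab[1]]
      if (length(winners) == 1) {
        cons[j] <- winners
      } else if (j <= nchar(refGap) &&
                 substr(refGap, j, j) %in% winners) {
        cons[j] <- substr(refGap, j, j)
      } else {
        cons[j] <- sort(winners)[1]
      }
    }
    consSeq <- paste(cons, collapse = "")
    strand <- as.character(GenomicRanges::strand(probes)[i])
    if (strand == "-") {
      consSeq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(consSeq)))
    }
    out <- rbind(out, data.frame(
      probe_id = parts[1], umi = parts[2], n_reads = length(rows),
      consensus = consSeq,
      contig = as.character(GenomicRanges::seqnames(probes)[i]),
      start = GenomicRanges::start(probes)[i],
      end = GenomicRanges::end(probes)[i], stringsAsFactors = FALSE))
  }
  out <- out[order(out$probe_id, out$umi), ]
  rownames(out) <- NULL
  out
}

# oracle: brute-force leftmost equivalent representation of a variant.
# Enumerates candidate (pos, ref, alt) with ref/alt lengths preserving
# the edit size, and keeps representations whose application to the
# sequence yields the same haplotype; returns the leftmost, shortest.
oracleLeftAlign <- function(contigSeq, pos, ref, alt) {
  apply1 <- function(p, r, a) {
    paste0(substr(contigSeq, 1, p - 1), a,
           substr(contigSeq, p + nchar(r), nchar(contigSeq)))
  }
  target <- apply1(pos, ref, alt)
  best <- NULL
  sizes <- expand.grid(rl = 1:6, al = 1:6)
  for (p in seq_len(min(pos + 5, nchar(contigSeq)))) {
    for (s in seq_len(nrow(sizes))) {
      rl <- sizes$rl[s]; al <- sizes$al[s]
      if (p + rl - 1 > nchar(contigSeq)) next
      r <- substr(contigSeq, p, p + rl - 1)
      for (aCand in unique(c(substr(target, p, p + al - 1)))) {
        if (nchar(aCand) != al) next
        if (r == aCand) next
        if (apply1(p, r, aCand) == target) {
          cand <- list(pos = p, ref = r, alt = aCand)
          sz <- function(x) nchar(x$ref) + nchar(x$alt)
          # minimal representation first, then leftmost position
          if (is.null(best) || sz(cand) < sz(best) ||
              (sz(cand) == sz(best) && cand$pos < best$pos)) {
            best <- cand
          }
        }
      }
    }
  }
  best
}

# planted variant expressed in the caller's left-aligned convention
normalizePlanted <- function(ref, pv) {
  cseq <- as.character(ref[[pv$contig]])
  normalizeVariantLeft(cseq, pv$pos + 1L, pv$ref, pv$alt)
}

# random anchored small variant inside a probe's central gap fill
randomPlantedVariant <- function(ref, probes, i, offset, kind, zygosity) {
  cseq <- as.character(ref[[as.character(
    GenomicRanges::seqnames(probes)[i])]])
  pos1 <- GenomicRanges::start(probes)[i] + offset
  refb <- substr(cseq, pos1, pos1)
  if (kind == "snv") {
    alt <- setdiff(c("A", "C", "G", "T"), refb)[1]
    plantedVariants("chr1", pos1 - 1L, refb, alt, zygosity, "snv")
  } else if (kind == "del") {
    refal <- substr(cseq, pos1, pos1 + 2)
    plantedVariants("chr1", pos1 - 1L, refal, refb, zygosity, "del")
  } else {
    plantedVariants("chr1", pos1 - 1L, refb, paste0(refb, "TG"),
                    zygosity, "ins")
  }
}
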