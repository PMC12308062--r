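#' Left-align an anchored variant
#'
#' Normalises a (position, ref, alt) representation to its leftmost
#' equivalent, the standard VCF convention for indels in repetitive
#' context: trailing shared bases are trimmed, empty alleles are extended
#' leftwards with reference context, and shared leading bases beyond the
#' anchor are trimmed.
#'
#' @param contigSeq Character, the full contig sequence.
#' @param pos 1-based position of the first ref base.
#' @param ref,alt Allele strings (ref may be "" for a pure insertion
#'   before normalisation).
#' @return List with \code{pos}, \code{ref}, \code{alt}.
#' @export
normalizeVariantLeft <- function(contigSeq, pos, ref, alt) {
  repeat {
    changed <- FALSE
    # trim identical trailing base
    while (nchar(ref) > 0L && nchar(alt) > 0L &&
           substr(ref, nchar(ref), nchar(ref)) ==
             substr(alt, nchar(alt), nchar(alt)) &&
           !(nchar(ref) == 1L && nchar(alt) == 1L)) {
      ref <- substr(ref, 1L, nchar(ref) - 1L)
      alt <- substr(alt, 1L, nchar(alt) - 1L)
      changed <- TRUE
    }
    # extend left when an allele is empty
    if ((nchar(ref) == 0L || nchar(alt) == 0L) && pos > 1L) {
      b <- substr(contigSeq, pos - 1L, pos - 1L)
      ref <- paste0(b, ref)
      alt <- paste0(b, alt)
      pos <- pos - 1L
      changed <- TRUE
    }
    if (!changed) break
  }
  # trim identical leading bases beyond the anchor
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

# variants of one fragment consensus against its reference gap sequence;
# returns data.frame(pos, ref, alt) with pos 1-based genomic
.fragmentAlleles <- function(consensus, refGap, gapStart) {
  if (identical(consensus, refGap)) {
    return(data.frame(pos = integer(0), ref = character(0),
                      alt = character(0), stringsAsFactors = FALSE))
  }
  if (nchar(consensus) == nchar(refGap)) {
    a <- utf8ToInt(consensus); b <- utf8ToInt(refGap)
    d <- which(a != b)
    # a dense mismatch run signals a shifted (indel) haplotype whose
    # positional trim drew foreign flank bases in; realign instead
    if (length(d) <= 5L) {
      return(data.frame(pos = gapStart + d - 1L,
                        ref = strsplit(refGap, "")[[1L]][d],
                        alt = strsplit(consensus, "")[[1L]][d],
                        stringsAsFactors = FALSE))
    }
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2,
                                                  mismatch = -3)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(consensus), Biostrings::DNAString(refGap),
    type = "global", substitutionMatrix = mat,
    gapOpening = 5, gapExtension = 2)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  out <- list()
  refPos <- 0L  # offset within refGap of last consumed ref base
  i <- 1L
  n <- length(p)
  while (i <= n) {
    if (s[i] != "-" && p[i] != "-") {
      refPos <- refPos + 1L
      if (s[i] != p[i]) {
        out[[length(out) + 1L]] <- data.frame(
          pos = gapStart + refPos - 1L, ref = s[i], alt = p[i],
          stringsAsFactors = FALSE)
      }
      i <- i + 1L
    } else if (p[i] == "-") {
      # deletion from the sample: collect the run
      j <- i
      while (j <= n && p[j] == "-") j <- j + 1L
      delBases <- paste(s[i:(j - 1L)], collapse = "")
      out[[length(out) + 1L]] <- data.frame(
        pos = gapStart + refPos,  # first deleted ref base
        ref = delBases, alt = "", stringsAsFactors = FALSE)
      refPos <- refPos + (j - i)
      i <- j
    } else {
      # insertion in the sample
      j <- i
      while (j <= n && s[j] == "-") j <- j + 1L
      insBases <- paste(p[i:(j - 1L)], collapse = "")
      out[[length(out) + 1L]] <- data.frame(
        pos = gapStart + refPos, ref = "", alt = insBases,
        stringsAsFactors = FALSE)
      i <- j
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(pos = integer(0), ref = character(0), alt = character(0),
               stringsAsFactors = FALSE)
}

#' Pile up consensus fragments over the target space
#'
#' Builds allele support from deduplicated, arm-trimmed consensus
#' fragments. Fragments identical to the reference contribute reference
#' depth only; differing fragments are compared to the reference gap
#' fill (global alignment when lengths differ), and resulting alleles are
#' left-aligned with \code{\link{normalizeVariantLeft}}. Alleles starting
#' within \code{edgeMask} bases of a fragment end are ignored as
#' trimming-boundary artefacts; consistently, each fragment contributes
#' depth only over its callable (edge-shrunk) span, so allele fractions
#' at window-overlap positions are not diluted by fragments that cannot
#' report the allele.
#'
#' @param fragments Fragment data.frame from \code{\link{dedupConsensus}}.
#' @param ref Named \code{DNAStringSet} reference.
#' @param edgeMask Bases masked at each fragment end (default 3).
#' @return List (class \code{"MipPileup"}): \code{alleles} data.frame
#'   (\code{contig}, 1-based \code{pos}, \code{ref}, \code{alt},
#'   \code{count}, \code{depth}), and \code{depth}, the per-contig
#'   coverage Rle of fragment counts.
#' @export
pileupFragments <- function(fragments, ref, edgeMask = 3L) {
  fragGr <- GenomicRanges::GRanges(
    fragments$contig,
    IRanges::IRanges(fragments$start + edgeMask,
                     pmax(fragments$end - edgeMask,
                          fragments$start + edgeMask)))
  cov <- GenomicRanges::coverage(fragGr)
  out <- list()
  for (k in seq_len(nrow(fragments))) {
    refGap <- .refSlice(ref, fragments$contig[k], fragments$start[k],
                        fragments$end[k])
    cons <- fragments$consensus[k]
    if (identical(cons, refGap)) next
    al <- .fragmentAlleles(cons, refGap, fragments$start[k])
    if (nrow(al) == 0L) next
    contigSeq <- as.character(ref[[fragments$contig[k]]])
    keepLo <- fragments$start[k] + edgeMask
    keepHi <- fragments$end[k] - edgeMask
    for (v in seq_len(nrow(al))) {
      if (al$pos[v] < keepLo || al$pos[v] > keepHi) next
      norm <- normalizeVariantLeft(contigSeq, al$pos[v], al$ref[v],
                                   al$alt[v])
      out[[length(out) + 1L]] <- data.frame(
        contig = fragments$contig[k], pos = norm$pos, ref = norm$ref,
        alt = norm$alt, stringsAsFactors = FALSE)
    }
  }
  alleles <- if (length(out)) {
    df <- do.call(rbind, out)
    agg <- stats::aggregate(list(count = rep(1L, nrow(df))),
                            by = df[c("contig", "pos", "ref", "alt")],
                            FUN = sum)
    agg$depth <- vapply(seq_len(nrow(agg)), function(i) {
      v <- cov[[agg$contig[i]]]
      if (agg$pos[i] > length(v)) 0L else
        as.integer(v[agg$pos[i]])
    }, integer(1))
    agg[order(agg$contig, agg$pos, agg$alt), , drop = FALSE]
  } else {
    data.frame(contig = character(0), pos = integer(0),
               ref = character(0), alt = character(0), count = integer(0),
               depth = integer(0), stringsAsFactors = FALSE)
  }
  rownames(alleles) <- NULL
  structure(list(alleles = alleles, depth = cov), class = "MipPileup")
}

#' Call small variants from a pileup
#'
#' Deterministic threshold genotyper: sites with consensus depth below
#' \code{minDepth} are no-calls (counted, not raised); an alt fraction at
#' or above \code{homMin} is homozygous (hemizygous on chrX in XY
#' samples); a fraction inside \code{hetRange} is heterozygous;
#' intermediate fractions are flagged ambiguous.
#'
#' Alleles below the noise floor (fewer than \code{minAltCount}
#' supporting fragments or an alt fraction below \code{minAltFraction})
#' are residual consensus errors and are dropped, not emitted.
#'
#' @param pileup A \code{MipPileup} from \code{\link{pileupFragments}}.
#' @param sex \code{"XX"} or \code{"XY"}.
#' @param minDepth Minimum consensus depth (default 8).
#' @param homMin Hom/hemi alt-fraction threshold (default 0.85).
#' @param hetRange Het alt-fraction interval (default [0.25, 0.75]).
#' @param minAltCount,minAltFraction Noise floor (defaults 2 fragments,
#'   0.1).
#' @return data.frame of calls: \code{contig}, \code{pos} (1-based),
#'   \code{ref}, \code{alt}, \code{genotype} (het/hom/hemi/ambiguous),
#'   \code{af}, \code{depth}, \code{filter}; attribute \code{noCalls}
#'   counts low-depth sites dropped. Calls are invariant to fragment
#'   input order.
#' @export
callSmallVariants <- function(pileup, sex = "XX", minDepth = 8L,
                              homMin = 0.85, hetRange = c(0.25, 0.75),
                              minAltCount = 2L, minAltFraction = 0.1) {
  al <- pileup$alleles
  noCalls <- 0L
  rows <- list()
  for (i in seq_len(nrow(al))) {
    if (al$depth[i] < minDepth) { noCalls <- noCalls + 1L; next }
    af <- al$count[i] / al$depth[i]
    if (al$count[i] < minAltCount || af < minAltFraction) next
    onX <- identical(al$contig[i], "chrX")
    gt <- if (af >= homMin) {
      if (onX && sex == "XY") "hemi" else "hom"
    } else if (af >= hetRange[1L] && af <= hetRange[2L]) {
      if (onX && sex == "XY") "ambiguous" else "het"
    } else "ambiguous"
    rows[[length(rows) + 1L]] <- data.frame(
      contig = al$contig[i], pos = al$pos[i], ref = al$ref[i],
      alt = al$alt[i], genotype = gt, af = af, depth = al$depth[i],
      filter = if (gt == "ambiguous") "ambiguous" else "PASS",
      stringsAsFactors = FALSE)
  }
  calls <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(0), pos = integer(0),
               ref = character(0), alt = character(0),
               genotype = character(0), af = numeric(0),
               depth = integer(0), filter = character(0),
               stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  attr(calls, "noCalls") <- noCalls
  calls
}

#' Call copy-number segments from probe depths
#'
#' Median-ratio rule with run-length segmentation: each probe's
#' library-size-normalised depth in the test sample is divided by the
#' median of the same quantity across a cohort of reference samples.
#' Consecutive runs (within a gene, in probe order) of at least
#' \code{minProbes} probes with ratio below \code{hetDelMax}
#' (heterozygous deletion), below \code{homDelMax} (homozygous deletion)
#' or above \code{dupMin} (duplication) are reported. Probes whose
#' reference median is zero are masked and recorded.
#'
#' @param testDepths Named numeric vector of per-probe fragment depths in
#'   the test sample.
#' @param refDepths Matrix (probes x reference samples, same probe order)
#'   of fragment depths; at least 3 columns.
#' @param probeGenes Character vector, gene per probe (same order).
#' @param minProbes Minimum run length (default 3).
#' @param hetDelMax,homDelMax,dupMin Ratio thresholds (defaults 0.65,
#'   0.1, 1.4).
#' @return data.frame of segments: \code{gene}, \code{firstProbe},
#'   \code{lastProbe} (indexes into the probe order), \code{nProbes},
#'   \code{ratio} (mean over the run), \code{state}; attribute
#'   \code{maskedProbes} lists masked probe indexes.
#' @export
callCnv <- function(testDepths, refDepths, probeGenes, minProbes = 3L,
                    hetDelMax = 0.65, homDelMax = 0.1, dupMin = 1.4) {
  stopifnot(ncol(refDepths) >= 3L,
            length(testDepths) == nrow(refDepths),
            length(probeGenes) == length(testDepths))
  testNorm <- testDepths / sum(testDepths)
  refNorm <- sweep(refDepths, 2L, colSums(refDepths), "/")
  refMed <- apply(refNorm, 1L, median)
  masked <- which(refMed == 0)
  ratio <- ifelse(refMed > 0, testNorm / refMed, NA_real_)
  state <- rep("normal", length(ratio))
  state[!is.na(ratio) & ratio < hetDelMax] <- "het_del"
  state[!is.na(ratio) & ratio < homDelMax] <- "hom_del"
  state[!is.na(ratio) & ratio > dupMin] <- "dup"
  state[is.na(ratio)] <- "masked"
  segs <- list()
  for (g in unique(probeGenes)) {
    idx <- which(probeGenes == g)
    r <- rle(state[idx])
    endPos <- cumsum(r$lengths)
    startPos <- endPos - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (r$values[k] %in% c("het_del", "hom_del", "dup") &&
          r$lengths[k] >= minProbes) {
        span <- idx[startPos[k]:endPos[k]]
        segs[[length(segs) + 1L]] <- data.frame(
          gene = g, firstProbe = span[1L], lastProbe = span[length(span)],
          nProbes = length(span), ratio = mean(ratio[span]),
          state = r$values[k], stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(segs)) do.call(rbind, segs) else
    data.frame(gene = character(0), firstProbe = integer(0),
               lastProbe = integer(0), nProbes = integer(0),
               ratio = numeric(0), state = character(0),
               stringsAsFactors = FALSE)
  attr(out, "maskedProbes") <- masked
  out
}

#' Write calls as a single-sample VCF 4.2 file
#'
#' Emits GT/DP/AF format fields; heterozygous calls as \code{0/1},
#' homozygous as \code{1/1}, hemizygous as \code{1}. Unsorted input is
#' sorted internally with a warning. An empty call set yields a valid
#' header-only VCF.
#'
#' @param calls Call data.frame from \code{\link{callSmallVariants}}.
#' @param sampleId Sample column name.
#' @param path Output path.
#' @param contigLengths Optional named integer vector for ##contig lines.
#' @return Invisibly, the path.
#' @export
writeVcfFile <- function(calls, sampleId, path, contigLengths = NULL) {
  ord <- order(calls$contig, calls$pos)
  if (!identical(ord, seq_len(nrow(calls)))) {
    if (nrow(calls)) warning("calls unsorted; sorting by contig, position")
    calls <- calls[ord, , drop = FALSE]
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=mipscreen")
  if (!is.null(contigLengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contigLengths),
                          as.integer(contigLengths)))
  }
  hdr <- c(hdr,
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Consensus fragment depth">',
    '##FORMAT=<ID=AF,Number=1,Type=Float,Description="Alt allele fraction">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sampleId, sep = "\t"))
  body <- character(0)
  if (nrow(calls)) {
    gt <- c(het = "0/1", hom = "1/1", hemi = "1",
            ambiguous = "./.")[calls$genotype]
    body <- paste(calls$contig, calls$pos, ".", calls$ref, calls$alt,
                  ".", calls$filter,  ".",
                  "GT:DP:AF",
                  paste(gt, calls$depth, sprintf("%.4g", calls$af),
                        sep = ":"),
                  sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
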