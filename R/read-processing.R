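#' Extract UMIs from read 2
#'
#' The UMI occupies the first \code{umiLength} bases of read 2 (adjacent
#' to the probe backbone). Reads shorter than the UMI are skipped with a
#' recorded reason rather than raised.
#'
#' @param reads2 Character vector of read-2 sequences.
#' @param umiLength UMI length (default 8).
#' @return List with \code{umi}, \code{trimmed} (read 2 minus the UMI)
#'   and \code{skipped} (logical: read too short).
#' @examples
#' extractUmi("ACGTACGTTTTTTT")$umi
#' @export
extractUmi <- function(reads2, umiLength = 8L) {
  skipped <- nchar(reads2) <= umiLength
  umi <- ifelse(skipped, NA_character_, substr(reads2, 1L, umiLength))
  trimmed <- ifelse(skipped, NA_character_,
                    substr(reads2, umiLength + 1L, nchar(reads2)))
  list(umi = umi, trimmed = trimmed, skipped = skipped)
}

# mismatch counts of fixed-length read prefixes against each probe's
# expected arm prefix; returns an (nReads x nProbes) matrix
.armMismatchMatrix <- function(prefixes, armSeqs) {
  n <- length(prefixes)
  m <- matrix(NA_integer_, nrow = n, ncol = length(armSeqs))
  for (j in seq_along(armSeqs)) {
    m[, j] <- .hammingToPattern(prefixes, armSeqs[j])
  }
  m
}

#' Assign reads to probes by arm-anchored matching
#'
#' Replaces genome alignment: panels are small and probes carry
#' coordinates, so a read is assigned to the unique probe whose expected
#' arm sequences match the read termini (extension arm at the start of
#' read 1, ligation arm at the start of the UMI-trimmed read 2, as its
#' reverse complement) with at most \code{maxMismatches} mismatches in
#' total (Hamming distance at fixed offsets; no indel tolerance). Ties
#' between probes and non-matches yield \code{NA} (unassigned), which is
#' a value, not an error.
#'
#' @param reads1 Character vector of read-1 sequences.
#' @param trimmed2 Character vector of UMI-trimmed read-2 sequences.
#' @param probes Probe \code{GRanges} (from \code{\link{designProbes}}).
#' @param params \code{\link{designParams}}.
#' @param maxMismatches Total arm mismatch budget (default 2).
#' @return Character vector of probe ids, \code{NA} where unassigned.
#' @export
assignProbe <- function(reads1, trimmed2, probes,
                        params = designParams(), maxMismatches = 2L) {
  mc <- S4Vectors::mcols(probes)
  extLen <- params@extensionLength
  ligLen <- params@ligationLength
  p1 <- substr(reads1, 1L, extLen)
  p2 <- substr(trimmed2, 1L, ligLen)
  mm <- .armMismatchMatrix(p1, mc$ext_seq) +
    .armMismatchMatrix(p2, .revcomp(mc$lig_seq))
  best <- max.col(-mm, ties.method = "first")
  bestMM <- mm[cbind(seq_along(best), best)]
  nBest <- rowSums(mm == bestMM)
  ifelse(bestMM <= maxMismatches & nBest == 1L, mc$probe_id[best],
         NA_character_)
}

#' Trim probe arms from an assigned read
#'
#' Arm bases originate from the synthesised probe oligo, not the sample,
#' and must never contribute to pileups. The retained target sequence is
#' the read-1 segment between the extension-arm prefix and the gap-fill
#' length: \code{min(readLength - extensionLength, gapFillLength)} bases.
#'
#' @param reads1 Character vector of read-1 sequences.
#' @param params \code{\link{designParams}}.
#' @return Character vector of target-only sequences (sequenced
#'   orientation); empty results are returned as \code{NA} (record
#'   skipped).
#' @export
trimArms <- function(reads1, params = designParams()) {
  extLen <- params@extensionLength
  out <- substr(reads1, extLen + 1L, extLen + params@gapFillLength)
  out[!nzchar(out)] <- NA_character_
  out
}

#' Collapse PCR duplicates into UMI consensus fragments
#'
#' Reads sharing (probe, UMI) derive from one captured molecule; each
#' group is collapsed to a single consensus fragment. The per-position
#' consensus is the majority base; ties break towards the reference base
#' (qualities are constant in this pipeline, so the quality tie-break
#' reduces to the reference rule). Deduplication is idempotent.
#'
#' @param records data.frame with columns \code{probe_id}, \code{umi},
#'   \code{target} (arm-trimmed, sequenced orientation).
#' @param probes Probe \code{GRanges} (for reference gap sequences and
#'   coordinates).
#' @return data.frame of fragments: \code{probe_id}, \code{umi},
#'   \code{n_reads}, \code{consensus} (plus-strand genomic orientation),
#'   \code{contig}, \code{start} (1-based), \code{end}.
#' @export
dedupConsensus <- function(records, probes) {
  mc <- S4Vectors::mcols(probes)
  pidx <- match(records$probe_id, mc$probe_id)
  stopifnot(!anyNA(pidx))
  key <- paste(records$probe_id, records$umi, sep = "\r")
  groups <- split(seq_len(nrow(records)), key)
  out <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    rows <- groups[[g]]
    i <- pidx[rows[1L]]
    refGap <- mc$gap_seq[i]  # sequenced orientation
    seqs <- records$target[rows]
    if (length(rows) == 1L) {
      cons <- seqs
    } else {
      L <- max(nchar(seqs))
      m <- matrix("", nrow = length(seqs), ncol = L)
      for (r in seq_along(seqs)) {
        ch <- strsplit(seqs[r], "", fixed = TRUE)[[1L]]
        m[r, seq_along(ch)] <- ch
      }
      refCh <- strsplit(refGap, "", fixed = TRUE)[[1L]]
      cons <- vapply(seq_len(L), function(j) {
        col <- m[, j]
        col <- col[nzchar(col)]
        tab <- table(col)
        top <- names(tab)[tab == max(tab)]
        if (length(top) == 1L) return(top)
        # tie: prefer the reference base, else first alphabetically
        if (j <= length(refCh) && refCh[j] %in% top) refCh[j] else top[1L]
      }, character(1))
      cons <- paste(cons, collapse = "")
    }
    strand <- as.character(GenomicRanges::strand(probes)[i])
    consGenomic <- if (strand == "-") .revcomp(cons) else cons
    out[[g]] <- data.frame(
      probe_id = records$probe_id[rows[1L]], umi = records$umi[rows[1L]],
      n_reads = length(rows), consensus = consGenomic,
      contig = as.character(GenomicRanges::seqnames(probes)[i]),
      start = GenomicRanges::start(probes)[i],
      end = GenomicRanges::end(probes)[i], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$probe_id, res$umi), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Full read-processing pass: raw read pairs to consensus fragments
#'
#' Chains UMI extraction, arm-anchored probe assignment, arm trimming and
#' UMI-consensus deduplication, preserving read conservation
#' (assigned + unassigned + skipped = input reads).
#'
#' @param reads1,reads2 Character vectors of raw read sequences.
#' @param probes Probe \code{GRanges}.
#' @param params \code{\link{designParams}}.
#' @param maxMismatches Arm mismatch budget for assignment.
#' @return List with \code{fragments} (see \code{\link{dedupConsensus}}),
#'   \code{assigned}, \code{unassigned}, \code{skipped} counts and the
#'   per-read \code{assignment} table.
#' @export
processReads <- function(reads1, reads2, probes, params = designParams(),
                         maxMismatches = 2L) {
  stopifnot(length(reads1) == length(reads2))
  um <- extractUmi(reads2, params@umiLength)
  ok <- !um$skipped
  probeId <- rep(NA_character_, length(reads1))
  probeId[ok] <- assignProbe(reads1[ok], um$trimmed[ok], probes, params,
                             maxMismatches)
  assigned <- !is.na(probeId)
  target <- rep(NA_character_, length(reads1))
  target[assigned] <- trimArms(reads1[assigned], params)
  usable <- assigned & !is.na(target)
  records <- data.frame(probe_id = probeId[usable],
                        umi = um$umi[usable],
                        target = target[usable],
                        stringsAsFactors = FALSE)
  fragments <- if (nrow(records)) dedupConsensus(records, probes) else
    data.frame(probe_id = character(0), umi = character(0),
               n_reads = integer(0), consensus = character(0),
               contig = character(0), start = integer(0), end = integer(0),
               stringsAsFactors = FALSE)
  list(fragments = fragments,
       assigned = sum(usable),
       unassigned = sum(ok & !assigned) + sum(assigned & !usable),
       skipped = sum(um$skipped),
       assignment = data.frame(read = seq_along(reads1),
                               probe_id = probeId,
                               skipped = um$skipped,
                               stringsAsFactors = FALSE))
}

#' Breadth of coverage from a depth vector
#'
#' @param depths Numeric vector of per-base depths.
#' @param threshold Depth threshold; a base counts when its depth is
#'   strictly greater (default 20).
#' @return Fraction of bases with depth above the threshold.
#' @examples
#' coverageBreadth(c(25, 25, 10, 30))  # 0.75
#' @export
coverageBreadth <- function(depths, threshold = 20L) {
  if (length(depths) == 0L) return(0)
  mean(depths > threshold)
}

#' Coverage breadth and depth over target regions
#'
#' Per-base depth counts the consensus fragments covering each targeted
#' base; breadth is the fraction of targeted bases with depth strictly
#' greater than \code{threshold} (the "more than N deduplicated reads"
#' reading), reported per gene and panel-wide, along with per-probe mean
#' fragment depth.
#'
#' @param fragments Fragment data.frame from \code{\link{dedupConsensus}}.
#' @param regions Target-region \code{GRanges} with a \code{gene} column.
#' @param threshold Depth threshold (default 20; strict inequality).
#' @return List with \code{perBase} (GRanges of depths), \code{perProbe}
#'   (mean depth per probe), \code{perGene} and \code{panel} breadths.
#' @export
coverageReport <- function(fragments, regions, threshold = 20L) {
  if (length(regions) == 0L) {
    stop("input error: empty region set", call. = FALSE)
  }
  fragGr <- GenomicRanges::GRanges(
    fragments$contig, IRanges::IRanges(fragments$start, fragments$end))
  cov <- GenomicRanges::coverage(fragGr)
  perGeneBreadth <- function(gr) {
    tot <- 0L; over <- 0L
    for (i in seq_along(gr)) {
      chrom <- as.character(GenomicRanges::seqnames(gr)[i])
      s <- GenomicRanges::start(gr)[i]; e <- GenomicRanges::end(gr)[i]
      d <- if (chrom %in% names(cov)) {
        v <- cov[[chrom]]
        if (e > length(v)) v <- c(v, S4Vectors::Rle(0L, e - length(v)))
        as.integer(S4Vectors::window(v, s, e))
      } else rep(0L, e - s + 1L)
      tot <- tot + length(d)
      over <- over + sum(d > threshold)
    }
    if (tot == 0L) 0 else over / tot
  }
  genes <- unique(S4Vectors::mcols(regions)$gene)
  perGene <- vapply(genes, function(g)
    perGeneBreadth(regions[S4Vectors::mcols(regions)$gene == g]),
    numeric(1))
  perProbe <- tapply(fragments$probe_id, fragments$probe_id, length)
  list(perProbe = perProbe,
       perGene = setNames(perGene, genes),
       panel = perGeneBreadth(regions),
       depth = cov)
}
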