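#' Tile a target region into gap-fill windows
#'
#' Produces gap-fill windows of exactly the design's gap-fill length that
#' jointly cover every base of the region, with adjacent windows
#' overlapping by at least \code{minOverlap}. The window count is the
#' closed form \code{ceiling((L - G) / (G - minOverlap)) + 1} for a region
#' of length \code{L > G}; window starts are spread evenly so the minimum
#' pairwise overlap is maximised. Regions shorter than the gap-fill length
#' get a single window centred on the region, with flanks drawn from the
#' reference at design time.
#'
#' @param region GRanges of length 1.
#' @param params \code{\link{designParams}}.
#' @param contigLengths optional named integer vector of contig lengths;
#'   when supplied, windows extending beyond the contig raise a bounds
#'   error.
#' @return GRanges of gap-fill windows, ordered left to right, carrying
#'   the region's \code{gene} and \code{label} metadata.
#' @examples
#' r <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, width = 500),
#'                             gene = "G1", label = "ex1")
#' length(tileRegion(r, designParams()))  # 5 windows
#' @export
tileRegion <- function(region, params = designParams(),
                       contigLengths = NULL) {
  stopifnot(length(region) == 1L)
  G <- params@gapFillLength
  L <- GenomicRanges::width(region)
  s <- GenomicRanges::start(region)
  e <- GenomicRanges::end(region)
  if (L <= G) {
    starts <- s - ((G - L) %/% 2L)
  } else {
    n <- as.integer(ceiling((L - G) / (G - params@minOverlap))) + 1L
    starts <- as.integer(round(seq(s, e - G + 1L, length.out = n)))
  }
  chrom <- as.character(GenomicRanges::seqnames(region))
  if (!is.null(contigLengths)) {
    clen <- contigLengths[[chrom]]
    if (any(starts < 1L) || any(starts + G - 1L > clen)) {
      stop("bounds error: window extends beyond contig '", chrom, "'",
           call. = FALSE)
    }
  }
  mc <- S4Vectors::mcols(region)
  GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = starts, width = G),
    gene = if (!is.null(mc$gene)) mc$gene else "",
    label = if (!is.null(mc$label)) mc$label else "")
}

.refSlice <- function(ref, chrom, start, end) {
  if (!chrom %in% names(ref)) {
    stop("contig '", chrom, "' absent from reference", call. = FALSE)
  }
  clen <- Biostrings::width(ref[chrom])
  if (start < 1L || end > clen) {
    stop("bounds error: [", start, ", ", end, "] outside contig '", chrom,
         "' (length ", clen, ")", call. = FALSE)
  }
  as.character(Biostrings::subseq(ref[[chrom]], start, end))
}

#' Design one probe over a gap-fill window
#'
#' Takes the extension and ligation arms from the reference immediately
#' flanking the gap fill (no overlap into it), with per-arm lengths from
#' the design's arm split and a combined length equal to the arm total.
#' Arm and gap sequences are stored in sequenced orientation: for a
#' minus-strand probe the arms are the reverse complements of the flanks
#' with their roles swapped, so that in both orientations the captured
#' molecule reads extension arm, then gap fill, then ligation arm.
#'
#' @param window GRanges of length 1 (the gap fill).
#' @param ref Named \code{DNAStringSet} reference.
#' @param params \code{\link{designParams}}.
#' @param strand \code{"+"} or \code{"-"}.
#' @return GRanges of length 1 over the gap fill with metadata columns
#'   \code{ext_seq}, \code{lig_seq}, \code{gap_seq} (sequenced
#'   orientation), \code{score} (NA until scored) and
#'   \code{relative_concentration}.
#' @export
designProbe <- function(window, ref, params = designParams(),
                        strand = "+") {
  stopifnot(length(window) == 1L, strand %in% c("+", "-"))
  chrom <- as.character(GenomicRanges::seqnames(window))
  s <- GenomicRanges::start(window)
  e <- GenomicRanges::end(window)
  extLen <- params@extensionLength
  ligLen <- params@ligationLength
  up <- .refSlice(ref, chrom, s - extLen, s - 1L)
  dn <- .refSlice(ref, chrom, e + 1L, e + ligLen)
  gap <- .refSlice(ref, chrom, s, e)
  if (strand == "+") {
    extSeq <- up
    ligSeq <- dn
    gapSeq <- gap
  } else {
    # roles swap: extension primes from the downstream flank on the
    # minus strand; keep per-arm lengths from the arm split
    extSeq <- .revcomp(.refSlice(ref, chrom, e + 1L, e + extLen))
    ligSeq <- .revcomp(.refSlice(ref, chrom, s - ligLen, s - 1L))
    gapSeq <- .revcomp(gap)
  }
  if (grepl("[^ACGT]", paste0(extSeq, ligSeq))) {
    stop("degenerate-base error: non-ACGT base in arm region",
         call. = FALSE)
  }
  out <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s, e),
                                strand = strand)
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    probe_id = NA_character_,
    gene = if (!is.null(S4Vectors::mcols(window)$gene))
      S4Vectors::mcols(window)$gene else "",
    label = if (!is.null(S4Vectors::mcols(window)$label))
      S4Vectors::mcols(window)$label else "",
    ext_seq = extSeq, lig_seq = ligSeq, gap_seq = gapSeq,
    score = NA_real_, below_floor = FALSE,
    relative_concentration = 1.0)
  out
}

#' Score a probe with the packaged logistic stand-in
#'
#' A transparent, deterministic logistic model of design difficulty:
#' \deqn{score = logistic(b0 + b1 |GC_{arm} - 0.5| + b2 |GC_{target} - 0.5|
#'   + b3 \cdot maxHomopolymer)}
#' with fixed coefficients \code{b0 = 2.5}, \code{b1 = -6}, \code{b2 = -4},
#' \code{b3 = -0.3}. GC fractions are computed over the concatenated arms
#' and over the gap fill; \code{maxHomopolymer} is the longest
#' single-base run across arms and gap fill. Balanced GC and short
#' homopolymers score above 0.5. This stand-in is not comparable to
#' external probe-design scores; it exists so selection, the score floor
#' and the below-floor relaxation are exercised end to end.
#'
#' @param extSeq,ligSeq,gapSeq Arm and gap-fill sequences; alternatively
#'   pass a probe \code{GRanges} row as \code{extSeq} and leave the others
#'   missing.
#' @return Numeric score(s) in [0, 1].
#' @examples
#' scoreProbe(strrep("AT", 11), strrep("GC", 12), strrep("ACGT", 27))
#' @export
scoreProbe <- function(extSeq, ligSeq, gapSeq) {
  if (missing(ligSeq) && inherits(extSeq, "GRanges")) {
    mc <- S4Vectors::mcols(extSeq)
    ligSeq <- mc$lig_seq
    gapSeq <- mc$gap_seq
    extSeq <- mc$ext_seq
  }
  if (any(!nzchar(extSeq)) || any(!nzchar(ligSeq)) || any(!nzchar(gapSeq))) {
    stop("precondition error: empty probe sequence", call. = FALSE)
  }
  arms <- paste0(extSeq, ligSeq)
  armGC <- .gcFraction(arms)
  gapGC <- .gcFraction(gapSeq)
  homo <- pmax(.maxHomopolymer(arms), .maxHomopolymer(gapSeq))
  eta <- 2.5 - 6 * abs(armGC - 0.5) - 4 * abs(gapGC - 0.5) - 0.3 * homo
  stats::plogis(eta)
}

#' Select one probe per window from strand candidates
#'
#' Candidates with scores at or above the score floor are preferred; when
#' no candidate for a window reaches the floor, the highest-scoring
#' candidate is kept and flagged \code{below_floor} (mirroring design
#' relaxation in difficult genomic regions). Ties break deterministically:
#' higher score, then plus strand, then leftmost start.
#'
#' @param candidates GRanges of scored candidates with a
#'   \code{window_id} metadata column.
#' @param params \code{\link{designParams}}.
#' @return GRanges with one probe per window, \code{below_floor} set.
#' @export
selectProbes <- function(candidates, params = designParams()) {
  if (length(candidates) == 0L) {
    stop("selection error: empty candidate set", call. = FALSE)
  }
  mc <- S4Vectors::mcols(candidates)
  stopifnot(!is.null(mc$window_id), !any(is.na(mc$score)))
  picks <- integer(0)
  for (w in unique(mc$window_id)) {
    idx <- which(mc$window_id == w)
    sc <- mc$score[idx]
    strand <- as.character(GenomicRanges::strand(candidates)[idx])
    ord <- order(-sc, strand != "+", GenomicRanges::start(candidates)[idx])
    best <- idx[ord[1L]]
    if (max(sc) < params@scoreFloor) {
      S4Vectors::mcols(candidates)$below_floor[best] <- TRUE
    }
    picks <- c(picks, best)
  }
  candidates[picks]
}

#' Assemble the orderable oligo sequence of a probe
#'
#' Single-strand layout: ligation arm, backbone linker (universal PCR
#' primer site), the degenerate UMI stretch (\code{N} times
#' \code{umiLength}), second linker, extension arm.
#'
#' @param probe GRanges row with \code{ext_seq}/\code{lig_seq} columns.
#' @param params \code{\link{designParams}}.
#' @return Character oligo sequence containing exactly
#'   \code{umiLength} \code{N} characters.
#' @export
assembleOligo <- function(probe, params = designParams()) {
  if (params@umiLength <= 0L) {
    stop("parameter error: umiLength must be positive", call. = FALSE)
  }
  mc <- S4Vectors::mcols(probe)
  paste0(mc$lig_seq, params@linker5,
         strrep("N", params@umiLength), params@linker3, mc$ext_seq)
}

#' Design probes for a set of target regions
#'
#' Full design pass: tiles each region into gap-fill windows, builds
#' plus- and minus-strand candidates from the reference, scores them with
#' the logistic stand-in, and selects one probe per window. Output is
#' deterministic for identical inputs.
#'
#' @param regions GRanges of target regions (with \code{gene}/\code{label}
#'   columns, e.g. from \code{\link{readBed}}).
#' @param ref Named \code{DNAStringSet} reference.
#' @param params \code{\link{designParams}}.
#' @return GRanges of selected probes with unique \code{probe_id}s.
#' @examples
#' ref <- randomReference(c(chr1 = 2000L), seed = 1)
#' r <- GenomicRanges::GRanges("chr1", IRanges::IRanges(501, width = 300),
#'                             gene = "G1", label = "ex1")
#' probes <- designProbes(r, ref)
#' @export
designProbes <- function(regions, ref, params = designParams()) {
  contigLengths <- setNames(Biostrings::width(ref), names(ref))
  out <- list()
  wid <- 0L
  for (i in seq_along(regions)) {
    windows <- tileRegion(regions[i], params, contigLengths)
    for (j in seq_along(windows)) {
      wid <- wid + 1L
      cand <- suppressWarnings(c(
        designProbe(windows[j], ref, params, "+"),
        designProbe(windows[j], ref, params, "-")))
      S4Vectors::mcols(cand)$window_id <- wid
      S4Vectors::mcols(cand)$score <- scoreProbe(cand)
      out[[length(out) + 1L]] <- selectProbes(cand, params)
    }
  }
  probes <- do.call(c, out)
  S4Vectors::mcols(probes)$probe_id <- sprintf("mip_%04d",
                                               seq_along(probes))
  probes
}

#' Compute a probe-pool rebalancing plan from observed depths
#'
#' For each probe the volume factor is
#' \code{clip(targetDepth / max(depth, eps), minFactor, maxFactor)}.
#' Probes with depth below \code{failFraction} times the median depth are
#' marked \code{failed} with factor 0 and a redesign flag, mirroring
#' replacement of failed probes with alternative designs between runs.
#'
#' @param depths Named non-negative numeric vector of per-probe mean
#'   depths from the previous run.
#' @param targetDepth Positive target mean depth.
#' @param minFactor,maxFactor Clipping bounds for the volume factor.
#' @param failFraction Fraction of the median depth below which a probe is
#'   declared failed.
#' @param eps Depth floor used in the ratio to avoid division by zero.
#' @return data.frame with columns \code{probe_id}, \code{depth},
#'   \code{factor}, \code{status} (\code{ok}, \code{boosted},
#'   \code{reduced} or \code{failed}) and \code{redesign}.
#' @examples
#' rebalanceProbes(c(A = 400, B = 100), targetDepth = 200)
#' @export
rebalanceProbes <- function(depths, targetDepth, minFactor = 0.25,
                            maxFactor = 4, failFraction = 0.05, eps = 1) {
  stopifnot(all(depths >= 0), targetDepth > 0)
  if (all(depths == 0)) {
    stop("degenerate-input error: all probe depths are zero",
         call. = FALSE)
  }
  med <- median(depths)
  factor <- pmin(pmax(targetDepth / pmax(depths, eps), minFactor),
                 maxFactor)
  failed <- depths < failFraction * med
  factor[failed] <- 0
  status <- ifelse(failed, "failed",
                   ifelse(factor > 1, "boosted",
                          ifelse(factor < 1, "reduced", "ok")))
  data.frame(probe_id = if (is.null(names(depths)))
               sprintf("probe_%04d", seq_along(depths)) else names(depths),
             depth = unname(depths), factor = unname(factor),
             status = unname(status), redesign = unname(failed),
             stringsAsFactors = FALSE)
}
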