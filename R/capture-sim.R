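#' Simulation parameters for smMIP capture sequencing
#'
#' @slot seed integer run seed; every random draw of a simulation is a
#'   deterministic function of it (plus the intrinsic efficiency stream).
#' @slot meanMolecules positive mean number of unique captured molecules
#'   per probe before efficiency skew.
#' @slot efficiencySigma log-normal sigma of the intrinsic per-probe
#'   capture efficiency (0 = perfectly uniform pool).
#' @slot dupGeomP geometric parameter p in (0, 1] of the PCR duplicate
#'   count per molecule (reads per molecule = 1 + Geom(p)).
#' @slot errorRate per-base substitution error rate in [0, 1).
#' @slot readLength read length (paired-end), default 150.
#' @slot sex sample sex, \code{"XX"} or \code{"XY"}; governs chrX ploidy.
#' @slot efficiencySeed seed of the intrinsic efficiency stream. Capture
#'   efficiency is a property of the probe, reproducible across runs, so
#'   that depth-based pool rebalancing can work between runs; this seed is
#'   deliberately separate from the run seed.
#' @exportClass SimParams
setClass("SimParams",
  representation(
    seed = "integer",
    meanMolecules = "numeric",
    efficiencySigma = "numeric",
    dupGeomP = "numeric",
    errorRate = "numeric",
    readLength = "integer",
    sex = "character",
    efficiencySeed = "integer"
  )
)

setValidity("SimParams", function(object) {
  msg <- character()
  if (object@meanMolecules <= 0) msg <- c(msg, "meanMolecules must be > 0")
  if (object@efficiencySigma < 0) msg <- c(msg, "efficiencySigma must be >= 0")
  if (object@dupGeomP <= 0 || object@dupGeomP > 1)
    msg <- c(msg, "dupGeomP must lie in (0, 1]")
  if (object@errorRate < 0 || object@errorRate >= 1)
    msg <- c(msg, "errorRate must lie in [0, 1)")
  if (!object@sex %in% c("XX", "XY")) msg <- c(msg, "sex must be XX or XY")
  if (length(msg)) msg else TRUE
})

#' Construct simulation parameters
#'
#' @param seed run seed.
#' @param meanMolecules mean unique molecules per probe; default 100.
#' @param efficiencySigma log-normal sigma of intrinsic probe efficiency;
#'   default 0.5.
#' @param dupGeomP geometric p for PCR duplicates; default 0.5 (mean one
#'   duplicate per molecule).
#' @param errorRate per-base substitution rate; default 0.001.
#' @param readLength paired-end read length; default 150.
#' @param sex \code{"XX"} or \code{"XY"}; default \code{"XX"}.
#' @param efficiencySeed seed of the intrinsic efficiency stream;
#'   default 20201.
#' @return A \code{SimParams} object.
#' @export
simParams <- function(seed = 1L, meanMolecules = 100, efficiencySigma = 0.5,
                      dupGeomP = 0.5, errorRate = 0.001, readLength = 150L,
                      sex = "XX", efficiencySeed = 20201L) {
  new("SimParams", seed = as.integer(seed),
      meanMolecules = as.numeric(meanMolecules),
      efficiencySigma = as.numeric(efficiencySigma),
      dupGeomP = as.numeric(dupGeomP), errorRate = as.numeric(errorRate),
      readLength = as.integer(readLength), sex = as.character(sex),
      efficiencySeed = as.integer(efficiencySeed))
}

#' Build a planted-variant table
#'
#' Truth-set plumbing for the simulator. Small variants are expressed as
#' anchored ref/alt allele strings at a 0-based position; whole-window
#' copy-number deletions as a half-open span.
#'
#' @param contig,pos contig and 0-based position (span start for CNVs).
#' @param ref,alt allele strings (empty for CNV deletions).
#' @param zygosity \code{"het"}, \code{"hom"} or \code{"hemi"} (hemi only
#'   on chrX in XY samples).
#' @param type \code{"snv"}, \code{"ins"}, \code{"del"} or
#'   \code{"cnv_del"}.
#' @param end 0-based half-open span end, CNV deletions only.
#' @return data.frame of planted variants.
#' @export
plantedVariants <- function(contig, pos, ref = "", alt = "",
                            zygosity = "het", type = "snv", end = NA_integer_) {
  df <- data.frame(contig = contig, pos = as.integer(pos), ref = ref,
                   alt = alt, zygosity = zygosity, type = type,
                   end = as.integer(end), stringsAsFactors = FALSE)
  stopifnot(all(df$zygosity %in% c("het", "hom", "hemi")),
            all(df$type %in% c("snv", "ins", "del", "cnv_del")))
  df
}

#' Generate a random reference sequence set
#'
#' @param lengths named integer vector, contig name to length.
#' @param seed integer seed.
#' @return Named \code{DNAStringSet}.
#' @examples
#' ref <- randomReference(c(chr1 = 5000L, chrX = 3000L), seed = 7)
#' @export
randomReference <- function(lengths, seed = 1L) {
  set.seed(seed)
  seqs <- vapply(lengths, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(setNames(seqs, names(lengths)))
}

# intrinsic per-probe capture efficiency, reproducible across runs
.intrinsicEfficiency <- function(n, sigma, effSeed) {
  if (sigma == 0) return(rep(1, n))
  state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(effSeed)
  u <- runif(n)
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
  qlnorm(u, meanlog = 0, sdlog = sigma)
}

# apply planted small variants to a plus-strand span sequence
.applyEdits <- function(spanSeq, spanStart0, edits) {
  if (nrow(edits) == 0L) return(spanSeq)
  edits <- edits[order(-edits$pos), , drop = FALSE]
  for (k in seq_len(nrow(edits))) {
    loc <- edits$pos[k] - spanStart0 + 1L  # 1-based within span
    refLen <- nchar(edits$ref[k])
    if (loc < 1L || loc + refLen - 1L > nchar(spanSeq)) next
    have <- substr(spanSeq, loc, loc + refLen - 1L)
    if (have != edits$ref[k]) {
      stop("planted variant ref mismatch at ", edits$contig[k], ":",
           edits$pos[k], " (expected ", edits$ref[k], ", found ", have,
           ")", call. = FALSE)
    }
    spanSeq <- paste0(substr(spanSeq, 1L, loc - 1L), edits$alt[k],
                      substr(spanSeq, loc + refLen,  nchar(spanSeq)))
  }
  spanSeq
}

# independent substitution errors on a character vector of reads
.addErrors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0L) return(reads)
  bases <- c("A", "C", "G", "T")
  for (i in seq_along(reads)) {
    len <- nchar(reads[i])
    k <- stats::rbinom(1L, len, rate)
    if (k == 0L) next
    posns <- sample.int(len, k)
    chars <- strsplit(reads[i], "", fixed = TRUE)[[1L]]
    for (p in posns) {
      chars[p] <- sample(setdiff(bases, chars[p]), 1L)
    }
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

#' Simulate smMIP capture sequencing of one sample
#'
#' For each probe the number of unique captured molecules is Poisson with
#' mean \code{meanMolecules} times the probe's intrinsic log-normal
#' efficiency times its relative concentration (and times the local copy
#' factor for planted copy-number deletions: 0.5 heterozygous, 0
#' homozygous). Each molecule draws an independent UMI uniform over
#' \code{4^umiLength} sequences and a haplotype, and emits
#' \code{1 + Geom(p)} read pairs. Read 1 starts at the extension-arm end
#' of the captured molecule; read 2 carries the UMI followed by the
#' ligation arm and target in reverse complement. Substitution errors are
#' i.i.d. per base. Identical seeds give byte-identical output.
#'
#' Planted variants lying outside every probe gap fill are recorded as
#' un-capturable warnings in the truth, not raised.
#'
#' @param panel \code{MipPanel} with designed probes.
#' @param ref Named \code{DNAStringSet}.
#' @param variants Planted variants from \code{\link{plantedVariants}},
#'   or NULL.
#' @param params \code{\link{simParams}}.
#' @param sampleId Sample identifier used in read names.
#' @return List with \code{reads1}/\code{reads2} (named character
#'   vectors), \code{truth} (per-read ledger: read id, probe, UMI,
#'   molecule id, haplotype), \code{genotypes} (planted variants with a
#'   \code{captured} flag) and \code{uncaptured} warning records.
#' @export
simulateSample <- function(panel, ref, variants = NULL,
                           params = simParams(), sampleId = "S1") {
  probes <- panelProbes(panel)
  if (length(probes) == 0L) stop("panel has no probes", call. = FALSE)
  dp <- panelParams(panel)
  if (is.null(variants)) {
    variants <- data.frame(contig = character(0), pos = integer(0),
                           ref = character(0), alt = character(0),
                           zygosity = character(0), type = character(0),
                           end = integer(0), stringsAsFactors = FALSE)
  }
  stopifnot(all(variants$zygosity != "hemi" |
                  (variants$contig == "chrX" & params@sex == "XY")))
  set.seed(params@seed)
  mc <- S4Vectors::mcols(probes)
  eff <- .intrinsicEfficiency(length(probes), params@efficiencySigma,
                              params@efficiencySeed)
  extLen <- dp@extensionLength
  ligLen <- dp@ligationLength
  umiLen <- dp@umiLength
  rl <- params@readLength

  small <- variants[variants$type != "cnv_del", , drop = FALSE]
  cnv <- variants[variants$type == "cnv_del", , drop = FALSE]

  # capturability: does a small variant start inside any gap fill?
  capFlag <- rep(TRUE, nrow(variants))
  if (nrow(variants)) {
    vgr <- GenomicRanges::GRanges(
      variants$contig,
      IRanges::IRanges(start = variants$pos + 1L,
                       end = ifelse(variants$type == "cnv_del",
                                    variants$end, variants$pos + 1L)))
    capFlag <- GenomicRanges::countOverlaps(
      vgr, probes, ignore.strand = TRUE) > 0L
  }

  r1List <- list(); r2List <- list()
  ledger <- list()
  molCounter <- 0L
  for (i in seq_along(probes)) {
    chrom <- as.character(GenomicRanges::seqnames(probes)[i])
    s <- GenomicRanges::start(probes)[i]
    e <- GenomicRanges::end(probes)[i]
    strand <- as.character(GenomicRanges::strand(probes)[i])
    spanStart <- s - (if (strand == "+") extLen else ligLen)
    spanEnd <- e + (if (strand == "+") ligLen else extLen)
    spanSeq <- .refSlice(ref, chrom, spanStart, spanEnd)
    spanStart0 <- spanStart - 1L

    onX <- identical(chrom, "chrX")
    nHap <- if (onX && params@sex == "XY") 1L else 2L

    # copy factor from planted CNV deletions overlapping this gap fill
    copyFactor <- 1
    deletedHap <- integer(0)
    if (nrow(cnv)) {
      hit <- cnv$contig == chrom & cnv$pos < e & cnv$end > s - 1L
      if (any(hit)) {
        zyg <- cnv$zygosity[which(hit)[1L]]
        if (zyg == "het" && nHap == 2L) {
          copyFactor <- 0.5; deletedHap <- 1L
        } else {
          copyFactor <- 0
        }
      }
    }

    # haplotype molecule sequences (plus strand, then orient)
    hapSeqs <- character(nHap)
    for (h in seq_len(nHap)) {
      hv <- small[small$contig == chrom &
                    (small$zygosity == "hom" |
                       small$zygosity == "hemi" |
                       (small$zygosity == "het" & h == 1L)), ,
                  drop = FALSE]
      hapSeqs[h] <- .applyEdits(spanSeq, spanStart0, hv)
    }
    if (strand == "-") hapSeqs <- .revcomp(hapSeqs)

    conc <- mc$relative_concentration[i]
    nMol <- rpois(1L, params@meanMolecules * eff[i] * conc * copyFactor)
    if (nMol == 0L) next
    avail <- setdiff(seq_len(nHap), deletedHap)
    hapIdx <- if (length(avail) == 1L) rep(avail, nMol) else
      sample(avail, nMol, replace = TRUE)
    umis <- vapply(seq_len(nMol), function(z)
      paste(sample(c("A", "C", "G", "T"), umiLen, replace = TRUE),
            collapse = ""), character(1))
    nReads <- 1L + rgeom(nMol, params@dupGeomP)

    molSeq <- hapSeqs[hapIdx]
    r1Mol <- substr(molSeq, 1L, rl)
    r2Mol <- paste0(umis, substr(.revcomp(molSeq), 1L, rl - umiLen))
    idx <- rep(seq_len(nMol), nReads)
    r1List[[length(r1List) + 1L]] <- r1Mol[idx]
    r2List[[length(r2List) + 1L]] <- r2Mol[idx]
    ledger[[length(ledger) + 1L]] <- data.frame(
      sample = sampleId, probe_id = mc$probe_id[i], umi = umis[idx],
      mol_id = molCounter + idx, dup_index = sequence(nReads),
      hap = hapIdx[idx], stringsAsFactors = FALSE)
    molCounter <- molCounter + nMol
  }
  truth <- if (length(ledger)) do.call(rbind, ledger) else
    data.frame(sample = character(0), probe_id = character(0),
               umi = character(0), mol_id = integer(0),
               dup_index = integer(0), hap = integer(0),
               stringsAsFactors = FALSE)
  truth <- cbind(read_id = sprintf("%s_r%06d", sampleId,
                                   seq_len(nrow(truth))), truth)
  truth$read_id <- as.character(truth$read_id)
  rownames(truth) <- NULL
  reads1 <- .addErrors(unlist(r1List, use.names = FALSE),
                       params@errorRate)
  reads2 <- .addErrors(unlist(r2List, use.names = FALSE),
                       params@errorRate)
  if (is.null(reads1)) { reads1 <- character(0); reads2 <- character(0) }
  names(reads1) <- truth$read_id
  names(reads2) <- truth$read_id
  genotypes <- cbind(variants, captured = capFlag)
  list(reads1 = reads1, reads2 = reads2, truth = truth,
       genotypes = genotypes,
       uncaptured = variants[!capFlag, , drop = FALSE])
}

#' Simulate a cohort of samples
#'
#' One FASTQ-equivalent read pair set per sample (demultiplexing is
#' instrument-side and out of scope). Per-sample seeds are derived
#' reproducibly from the shared run seed.
#'
#' @param panel \code{MipPanel} with probes.
#' @param ref Named \code{DNAStringSet}.
#' @param variantSets Named list of planted-variant tables (one per
#'   sample; NULL entries allowed). Duplicate sample ids are an error.
#' @param params \code{\link{simParams}} (seed is the cohort seed).
#' @param sexes Optional named character vector of per-sample sexes.
#' @return List with \code{samples} (per-sample simulation results) and
#'   \code{truth} (merged read ledger).
#' @export
simulateCohort <- function(panel, ref, variantSets, params = simParams(),
                           sexes = NULL) {
  ids <- names(variantSets)
  if (is.null(ids) || any(duplicated(ids))) {
    stop("input error: sample ids must be unique and named", call. = FALSE)
  }
  samples <- list()
  for (k in seq_along(ids)) {
    p <- params
    p@seed <- as.integer((params@seed + 104729L * k) %% 2147483629L)
    if (!is.null(sexes) && ids[k] %in% names(sexes)) {
      p@sex <- unname(sexes[[ids[k]]])
    }
    samples[[ids[k]]] <- simulateSample(panel, ref, variantSets[[k]], p,
                                        sampleId = ids[k])
  }
  truth <- do.call(rbind, lapply(samples, `[[`, "truth"))
  rownames(truth) <- NULL
  list(samples = samples, truth = truth)
}

#' Write a simulated read pair as gzip FASTQ
#'
#' Four-line records with constant Q30 qualities; read names embed the
#' ledger read ids so the truth table can be joined back.
#'
#' @param sim Result of \code{\link{simulateSample}}.
#' @param prefix Output prefix; writes \code{<prefix>_R1.fastq.gz} and
#'   \code{<prefix>_R2.fastq.gz}.
#' @return Invisibly, the two paths.
#' @export
writeFastqPair <- function(sim, prefix) {
  p1 <- paste0(prefix, "_R1.fastq.gz")
  p2 <- paste0(prefix, "_R2.fastq.gz")
  for (side in 1:2) {
    reads <- if (side == 1L) sim$reads1 else sim$reads2
    x <- Biostrings::DNAStringSet(reads)
    q <- Biostrings::BStringSet(strrep("?", nchar(reads)))
    Biostrings::writeXStringSet(x, if (side == 1L) p1 else p2,
                                format = "fastq", qualities = q,
                                compress = TRUE)
  }
  invisible(c(p1, p2))
}

#' Read a FASTQ pair back as named character vectors
#'
#' @param path1,path2 FASTQ(.gz) paths.
#' @return List with \code{reads1} and \code{reads2}.
#' @export
readFastqPair <- function(path1, path2) {
  r1 <- Biostrings::readDNAStringSet(path1, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(path2, format = "fastq")
  list(reads1 = setNames(as.character(r1), names(r1)),
       reads2 = setNames(as.character(r2), names(r2)))
}
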