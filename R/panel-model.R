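#' Construct an smMIP panel
#'
#' Builds a validated \code{\linkS4class{MipPanel}} from a gene table,
#' optional target regions and optional probes. Coordinates are 0-based
#' half-open throughout (BED convention).
#'
#' @param genes data.frame or DataFrame with columns \code{symbol},
#'   \code{transcript}, \code{contig}, \code{start}, \code{end},
#'   \code{cytoband} and \code{modes} (comma-separated subset of
#'   \code{AD,AR,XL}).
#' @param regions GRanges of target regions with metadata columns
#'   \code{gene} and \code{label}; may be empty.
#' @param probes GRanges of designed probes; may be empty.
#' @param params A \code{\link{designParams}} object.
#' @return A validated \code{MipPanel}; invalid input raises an error
#'   listing the violated rules.
#' @examples
#' g <- data.frame(symbol = "ENAM", transcript = "NM_031889.3",
#'                 contig = "chr4", start = 71494460, end = 71512541,
#'                 cytoband = "4q13.3", modes = "AD,AR")
#' MipPanel(g)
#' @export
MipPanel <- function(genes, regions = GenomicRanges::GRanges(),
                     probes = GenomicRanges::GRanges(),
                     params = designParams()) {
  genes <- S4Vectors::DataFrame(genes)
  obj <- new("MipPanel", genes = genes, regions = regions,
             probes = probes, params = params)
  obj
}

#' Load a packaged panel fixture
#'
#' The \code{"ai19"} fixture is the 19-gene amelogenesis imperfecta panel:
#' HGNC symbols, transcripts, hg19 gene intervals (converted once to
#' 0-based half-open coordinates), cytobands and the per-gene
#' inheritance-mode map (AD, AR, AD+AR or XL). The fixture ships no exon
#' coordinates: target regions for simulation are built in code.
#'
#' @param name Fixture identifier; currently only \code{"ai19"}.
#' @return A validated \code{\linkS4class{MipPanel}}.
#' @examples
#' panel <- loadPanelFixture("ai19")
#' nrow(panelGenes(panel))
#' @export
loadPanelFixture <- function(name = "ai19") {
  if (!identical(name, "ai19")) {
    stop("unknown panel fixture: '", name, "'", call. = FALSE)
  }
  tab <- read.delim(.extdata("panel_ai19_genes.tsv"),
                    colClasses = "character")
  genes <- S4Vectors::DataFrame(
    symbol = tab$symbol,
    transcript = tab$transcript,
    omim = tab$omim,
    contig = tab$contig,
    start = as.integer(tab$start),
    end = as.integer(tab$end),
    cytoband = tab$cytoband,
    modes = tab$modes)
  MipPanel(genes)
}

#' Read target regions from a BED file
#'
#' Accepts 3- to 6-column BED (0-based half-open). A name column, when
#' present, is parsed as \code{"GENE|label"}; a bare name is taken as the
#' gene symbol with an empty label. Malformed lines (start >= end,
#' negative coordinates, non-integer fields) raise a parse error citing
#' the offending line number.
#'
#' @param path Path to a BED file.
#' @return A \code{GRanges} (0-based starts kept via BED convention:
#'   the returned ranges use 1-based starts internally as usual for
#'   GRanges, i.e. \code{start = bedStart + 1}) with metadata columns
#'   \code{gene} and \code{label}, in file order.
#' @seealso \code{\link{writeBed}}
#' @export
readBed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$gene <- character(0)
    S4Vectors::mcols(gr)$label <- character(0)
    return(gr)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  parseLine <- function(f, i) {
    if (length(f) < 3L) {
      stop("BED parse error at line ", i, ": fewer than 3 columns",
           call. = FALSE)
    }
    s <- suppressWarnings(as.integer(f[2L]))
    e <- suppressWarnings(as.integer(f[3L]))
    if (is.na(s) || is.na(e)) {
      stop("BED parse error at line ", i, ": non-integer coordinate",
           call. = FALSE)
    }
    if (s < 0L || e < 0L) {
      stop("BED parse error at line ", i, ": negative coordinate",
           call. = FALSE)
    }
    if (s >= e) {
      stop("BED parse error at line ", i, ": start >= end", call. = FALSE)
    }
    name <- if (length(f) >= 4L) f[4L] else ""
    c(chrom = f[1L], start = f[2L], end = f[3L], name = name)
  }
  parsed <- mapply(parseLine, fields, seq_along(fields), SIMPLIFY = FALSE)
  chrom <- vapply(parsed, `[[`, "", "chrom")
  s <- as.integer(vapply(parsed, `[[`, "", "start"))
  e <- as.integer(vapply(parsed, `[[`, "", "end"))
  name <- vapply(parsed, `[[`, "", "name")
  gene <- sub("\\|.*$", "", name)
  label <- ifelse(grepl("|", name, fixed = TRUE),
                  sub("^[^|]*\\|", "", name), "")
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = s + 1L, end = e),
                         gene = gene, label = label)
}

#' Write target regions as BED
#'
#' Emits canonical 4-column BED (\code{chrom}, 0-based \code{start},
#' \code{end}, \code{GENE|label}); regions without gene annotation are
#' written as 3 columns. Reading a canonical file with \code{readBed} and
#' writing it back is byte-identical.
#'
#' @param regions GRanges with optional \code{gene}/\code{label} columns.
#' @param path Output path.
#' @return Invisibly, the path written.
#' @export
writeBed <- function(regions, path) {
  chrom <- as.character(GenomicRanges::seqnames(regions))
  s <- GenomicRanges::start(regions) - 1L
  e <- GenomicRanges::end(regions)
  mc <- S4Vectors::mcols(regions)
  if (!is.null(mc$gene) && any(nzchar(mc$gene))) {
    name <- ifelse(nzchar(mc$label), paste0(mc$gene, "|", mc$label),
                   mc$gene)
    out <- paste(chrom, s, e, name, sep = "\t")
  } else {
    out <- paste(chrom, s, e, sep = "\t")
  }
  writeLines(out, path)
  invisible(path)
}

#' Validate a panel against its structural invariants
#'
#' Checks every type invariant of the panel model: gene intervals are
#' non-empty and symbols unique, inheritance-mode sets are non-empty
#' subsets of \{AD, AR, XL\} with X-linked genes on chrX, target regions
#' are non-duplicated and reference known genes, and probes have the
#' required arm geometry (combined arm length equal to the design's arm
#' total), gap-fill lengths within the design length, scores in [0, 1],
#' positive relative concentrations, and gap fills intersecting at least
#' one target region (when regions are present).
#'
#' Violations are returned as data, not raised: the function is pure and
#' repeated calls give identical output.
#'
#' @param panel A \code{MipPanel} (or a not-yet-validated object with the
#'   same slots).
#' @return data.frame with columns \code{entity}, \code{rule},
#'   \code{message}; zero rows when all invariants hold.
#' @export
validatePanel <- function(panel) {
  viol <- list()
  add <- function(entity, rule, message) {
    viol[[length(viol) + 1L]] <<- data.frame(
      entity = entity, rule = rule, message = message,
      stringsAsFactors = FALSE)
  }
  g <- panel@genes
  if (nrow(g)) {
    bad <- g$start >= g$end
    for (i in which(bad)) {
      add(g$symbol[i], "gene_interval", "start must be < end")
    }
    dup <- duplicated(g$symbol)
    for (i in which(dup)) {
      add(g$symbol[i], "gene_symbol_unique", "duplicate gene symbol")
    }
    modes <- strsplit(g$modes, ",", fixed = TRUE)
    for (i in seq_along(modes)) {
      m <- modes[[i]]
      if (length(m) == 0L || !all(m %in% c("AD", "AR", "XL"))) {
        add(g$symbol[i], "gene_modes",
            "modes must be a non-empty subset of {AD, AR, XL}")
      } else if ("XL" %in% m && g$contig[i] != "chrX") {
        add(g$symbol[i], "xl_on_chrx", "XL gene must lie on chrX")
      }
    }
  }
  r <- panel@regions
  if (length(r)) {
    key <- paste(GenomicRanges::seqnames(r), GenomicRanges::start(r),
                 GenomicRanges::end(r))
    for (i in which(duplicated(key))) {
      add(paste0("region:", key[i]), "region_duplicate",
          "exact-duplicate interval")
    }
    rg <- S4Vectors::mcols(r)$gene
    if (!is.null(rg)) {
      for (i in which(!(rg %in% g$symbol))) {
        add(paste0("region:", key[i]), "region_gene_known",
            paste0("gene '", rg[i], "' absent from panel genes"))
      }
    }
  }
  p <- panel@probes
  if (length(p)) {
    mc <- S4Vectors::mcols(p)
    at <- armTotal(panel@params)
    armlen <- nchar(mc$ext_seq) + nchar(mc$lig_seq)
    for (i in which(armlen != at)) {
      add(mc$probe_id[i], "arm_total",
          sprintf("combined arm length %d != %d", armlen[i], at))
    }
    w <- GenomicRanges::width(p)
    for (i in which(w > panel@params@gapFillLength)) {
      add(mc$probe_id[i], "gap_fill_length",
          sprintf("gap-fill length %d exceeds %d", w[i],
                  panel@params@gapFillLength))
    }
    for (i in which(mc$score < 0 | mc$score > 1)) {
      add(mc$probe_id[i], "score_range", "score outside [0, 1]")
    }
    for (i in which(mc$relative_concentration <= 0)) {
      add(mc$probe_id[i], "relative_concentration",
          "relative concentration must be positive")
    }
    if (length(r)) {
      hits <- GenomicRanges::countOverlaps(p, r, ignore.strand = TRUE)
      for (i in which(hits == 0L)) {
        add(mc$probe_id[i], "probe_in_region",
            "gap-fill intersects no target region")
      }
    }
  }
  if (length(viol)) {
    do.call(rbind, viol)
  } else {
    data.frame(entity = character(0), rule = character(0),
               message = character(0), stringsAsFactors = FALSE)
  }
}
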