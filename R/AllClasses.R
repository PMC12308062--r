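#' Design parameters for smMIP probes
#'
#' Holds the geometric and chemical constants of a probe design: the length
#' of the gap-fill (target) region each probe captures, the combined and
#' per-arm lengths of the extension and ligation arms, the minimum overlap
#' required between adjacent gap-fill windows, the number of degenerate
#' (UMI) bases in the backbone, the logistic score floor used during probe
#' selection, the splice flank added around coding exons, and the two
#' backbone linker segments carrying the universal PCR primer sites.
#'
#' Defaults encode the standard design: 110 nt gap fill, 45 nt of combined
#' arm sequence (21 nt extension + 24 nt ligation), a minimum 10 bp overlap
#' between adjacent probes, an 8 nt UMI (4^8 possible molecular indexes)
#' and a 0.5 score floor.
#'
#' @slot gapFillLength integer, gap-fill (target) length per probe.
#' @slot extensionLength integer, extension-arm length.
#' @slot ligationLength integer, ligation-arm length.
#' @slot minOverlap integer, minimum overlap of adjacent gap-fill windows.
#' @slot umiLength integer, number of degenerate backbone bases.
#' @slot scoreFloor numeric in [0,1], selection score floor.
#' @slot spliceFlank integer, bases added either side of a coding exon.
#' @slot linker5,linker3 character, backbone linker segments (universal
#'   PCR primer sites) flanking the UMI in the assembled oligo.
#' @exportClass DesignParams
setClass("DesignParams",
  representation(
    gapFillLength = "integer",
    extensionLength = "integer",
    ligationLength = "integer",
    minOverlap = "integer",
    umiLength = "integer",
    scoreFloor = "numeric",
    spliceFlank = "integer",
    linker5 = "character",
    linker3 = "character"
  )
)

setValidity("DesignParams", function(object) {
  msg <- character()
  if (object@gapFillLength < 1L)
    msg <- c(msg, "gapFillLength must be >= 1")
  if (object@extensionLength < 1L || object@ligationLength < 1L)
    msg <- c(msg, "arm lengths must be >= 1")
  if (object@minOverlap >= object@gapFillLength)
    msg <- c(msg, "minOverlap must be smaller than gapFillLength")
  if (object@scoreFloor < 0 || object@scoreFloor > 1)
    msg <- c(msg, "scoreFloor must lie in [0, 1]")
  if (object@spliceFlank < 0L)
    msg <- c(msg, "spliceFlank must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct design parameters
#'
#' @param gapFillLength gap-fill (target) length per probe; default 110.
#' @param extensionLength extension-arm length; default 21.
#' @param ligationLength ligation-arm length; default 24 (arms total 45).
#' @param minOverlap minimum overlap between adjacent windows; default 10.
#' @param umiLength degenerate (UMI) bases in the backbone; default 8.
#' @param scoreFloor probe-selection score floor; default 0.5.
#' @param spliceFlank splice flank around coding exons; default 10.
#' @param linker5,linker3 backbone linker segments. The shipped defaults
#'   give a backbone (arms + linkers + UMI) of 83 nt with the default arm
#'   and UMI lengths.
#' @return A \code{DesignParams} object.
#' @examples
#' p <- designParams()
#' armTotal(p)
#' @export
designParams <- function(gapFillLength = 110L, extensionLength = 21L,
                         ligationLength = 24L, minOverlap = 10L,
                         umiLength = 8L, scoreFloor = 0.5,
                         spliceFlank = 10L,
                         linker5 = "CTTCAGCTTCCCGAT",
                         linker3 = "ATCCGACGGTAGTGT") {
  new("DesignParams",
      gapFillLength = as.integer(gapFillLength),
      extensionLength = as.integer(extensionLength),
      ligationLength = as.integer(ligationLength),
      minOverlap = as.integer(minOverlap),
      umiLength = as.integer(umiLength),
      scoreFloor = as.numeric(scoreFloor),
      spliceFlank = as.integer(spliceFlank),
      linker5 = as.character(linker5),
      linker3 = as.character(linker3))
}

#' Combined arm length of a design
#' @param params A \code{DesignParams} object.
#' @return Integer, extension + ligation arm length.
#' @export
armTotal <- function(params) {
  params@extensionLength + params@ligationLength
}

#' An smMIP panel: genes, target regions and probes
#'
#' The central container of the package. \code{genes} is a
#' \code{\link[S4Vectors]{DataFrame}} of gene targets (HGNC symbol,
#' transcript, 0-based half-open interval, cytoband and inheritance-mode
#' set); \code{regions} is a \code{\link[GenomicRanges]{GRanges}} of target
#' regions (typically coding exons plus splice flanks) with \code{gene} and
#' \code{label} metadata columns; \code{probes} is a \code{GRanges} over the
#' gap-fill intervals with arm sequences, score and relative concentration
#' in its metadata columns (possibly empty before design).
#'
#' @slot genes DataFrame of gene targets.
#' @slot regions GRanges of target regions.
#' @slot probes GRanges of designed probes.
#' @slot params DesignParams used for design.
#' @seealso \code{\link{MipPanel}}, \code{\link{validatePanel}},
#'   \code{\link{loadPanelFixture}}
#' @exportClass MipPanel
setClass("MipPanel",
  representation(
    genes = "DataFrame",
    regions = "GRanges",
    probes = "GRanges",
    params = "DesignParams"
  )
)

setValidity("MipPanel", function(object) {
  v <- validatePanel(object)
  if (nrow(v) == 0L) TRUE else
    paste0(v$entity, ": ", v$message, collapse = "; ")
})

#' @describeIn MipPanel-class gene table accessor
#' @param panel A \code{MipPanel}.
#' @return \code{panelGenes}: a DataFrame of gene targets.
#' @export
panelGenes <- function(panel) panel@genes

#' @describeIn MipPanel-class target-region accessor
#' @return \code{panelRegions}: a GRanges of target regions.
#' @export
panelRegions <- function(panel) panel@regions

#' @describeIn MipPanel-class probe accessor
#' @return \code{panelProbes}: a GRanges of probes (gap-fill intervals).
#' @export
panelProbes <- function(panel) panel@probes

#' @describeIn MipPanel-class design-parameter accessor
#' @return \code{panelParams}: the panel's DesignParams.
#' @export
panelParams <- function(panel) panel@params

#' Per-gene inheritance-mode map of a panel
#'
#' @param panel A \code{MipPanel}.
#' @return Named list mapping gene symbol to a character vector drawn from
#'   \code{c("AD", "AR", "XL")}.
#' @export
panelModes <- function(panel) {
  g <- panel@genes
  setNames(strsplit(g$modes, ",", fixed = TRUE), g$symbol)
}

setMethod("show", "MipPanel", function(object) {
  cat("MipPanel with", nrow(object@genes), "genes,",
      length(object@regions), "target regions,",
      length(object@probes), "probes\n")
  if (nrow(object@genes)) {
    cat("  genes:", paste(utils::head(object@genes$symbol, 6L),
                          collapse = ", "),
        if (nrow(object@genes) > 6L) "..." else "", "\n")
  }
})

setMethod("show", "DesignParams", function(object) {
  cat(sprintf(
    "DesignParams: gap-fill %d nt, arms %d+%d nt, min overlap %d, UMI %d nt, score floor %.2f\n",
    object@gapFillLength, object@extensionLength, object@ligationLength,
    object@minOverlap, object@umiLength, object@scoreFloor))
})
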