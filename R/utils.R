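#' @import methods
#' @importFrom stats median rpois rgeom runif qlnorm sd
#' @importFrom utils read.delim write.table
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom GenomicRanges GRanges
NULL

setNames <- stats::setNames

# GC fraction of a character vector of DNA sequences
.gcFraction <- function(x) {
  stopifnot(is.character(x))
  freq <- Biostrings::letterFrequency(Biostrings::DNAStringSet(x),
                                      letters = c("G", "C"))
  rowSums(freq) / nchar(x)
}

# longest homopolymer run across one sequence
.maxHomopolymer <- function(x) {
  vapply(x, function(s) {
    if (nchar(s) == 0L) return(0L)
    r <- rle(strsplit(s, "", fixed = TRUE)[[1L]])
    max(r$lengths)
  }, integer(1), USE.NAMES = FALSE)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Hamming distances of equal-length strings against a single pattern.
# Strings shorter than the pattern count the missing tail as mismatches.
.hammingToPattern <- function(strings, pattern) {
  n <- nchar(pattern)
  pat <- utf8ToInt(pattern)
  vapply(strings, function(s) {
    k <- min(nchar(s), n)
    if (k == 0L) return(n)
    sv <- utf8ToInt(substr(s, 1L, k))
    sum(sv != pat[seq_len(k)]) + (n - k)
  }, integer(1), USE.NAMES = FALSE)
}

# blank-to-NA numeric coercion used by fixture readers
.numOrNA <- function(x) {
  x[x == ""] <- NA_character_
  suppressWarnings(as.numeric(x))
}

# round half away from zero (base round() is banker's rounding)
.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

.extdata <- function(name) {
  path <- system.file("extdata", name, package = "mipscreen")
  if (identical(path, "")) {
    stop("packaged fixture file not found: ", name, call. = FALSE)
  }
  path
}
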