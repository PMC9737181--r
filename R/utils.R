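#' Round half away from zero
#'
#' Fixed-direction rounding used for reported metric tables, where ties at 5
#' always round up in magnitude (base [round()] rounds to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @examples
#' roundHalfUp(0.9615, 3)
#' @export
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## autosome naming: "chr1".."chr22" or bare "1".."22"
isAutosome <- function(chrom) {
  grepl("^(chr)?[0-9]+$", as.character(chrom))
}

chromNumber <- function(chrom) {
  suppressWarnings(as.integer(sub("^chr", "", as.character(chrom))))
}

## canonical bin identifiers: 0-based half-open, "chrom:start-end"
binIds <- function(bins) {
  paste0(as.character(GenomicRanges::seqnames(bins)), ":",
         GenomicRanges::start(bins) - 1L, "-", GenomicRanges::end(bins))
}

## target chromosome names as they appear in a grid, given numbers 13/18/21
targetChromNames <- function(bins, targets = c(13L, 18L, 21L)) {
  lev <- GenomeInfoDb::seqlevels(bins)
  lev[chromNumber(lev) %in% targets & isAutosome(lev)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
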