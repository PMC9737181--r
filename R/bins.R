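#' Tile chromosomes into fixed-width bins
#'
#' Partitions each chromosome left-to-right into consecutive bins of
#' `binSize` bp (BED convention: 0-based half-open intervals; the returned
#' `GRanges` uses the usual 1-based representation). The last bin of a
#' chromosome is truncated at the chromosome end, so bin widths sum exactly
#' to the chromosome length.
#'
#' @param chromSizes Named numeric vector of chromosome lengths in bp.
#' @param binSize Bin width in bp (default 50 kb).
#' @return `GRanges` of bins in the input chromosome order, with an `NA`
#'   `gc` metadata column to be filled by [computeGC()] or a simulator.
#' @examples
#' makeBins(c(chr1 = 125000), 50000)   # 3 bins, last one 25 kb
#' @export
makeBins <- function(chromSizes, binSize = 50000) {
  if (length(chromSizes) == 0L) stop("no chromosomes")
  if (is.null(names(chromSizes)) || any(!nzchar(names(chromSizes))))
    stop("chromSizes must be a named vector")
  if (anyDuplicated(names(chromSizes))) stop("duplicate chromosome names")
  if (!is.numeric(binSize) || length(binSize) != 1L || binSize <= 0)
    stop("binSize must be a positive scalar")
  if (any(chromSizes <= 0)) stop("chromosome lengths must be positive")
  pieces <- lapply(names(chromSizes), function(chrom) {
    len <- chromSizes[[chrom]]
    starts <- seq(0, len - 1, by = binSize)
    GRanges(chrom, IRanges(start = starts + 1, end = pmin(starts + binSize, len)))
  })
  bins <- suppressWarnings(do.call(c, pieces))
  GenomeInfoDb::seqlevels(bins) <- names(chromSizes)
  GenomeInfoDb::seqlengths(bins) <- chromSizes
  mcols(bins)$gc <- NA_real_
  names(bins) <- binIds(bins)
  bins
}

#' Fill per-bin GC fraction from a reference FASTA
#'
#' GC is computed as (G+C)/(A+C+G+T) over the bin sequence. Bins whose
#' sequence is more than 50% N (assembly gaps) get `NA` GC and are excluded
#' from scoring downstream.
#'
#' @param fastaFile Path to a FASTA file covering the grid chromosomes (an
#'   `.fai` index is created if absent).
#' @param bins Bin grid from [makeBins()].
#' @return `bins` with the `gc` metadata column filled.
#' @export
computeGC <- function(fastaFile, bins) {
  if (!file.exists(fastaFile)) stop("FASTA file not found: ", fastaFile)
  if (!file.exists(paste0(fastaFile, ".fai"))) Rsamtools::indexFa(fastaFile)
  fa <- Rsamtools::FaFile(fastaFile)
  have <- GenomeInfoDb::seqnames(Rsamtools::seqinfo(fa))
  need <- GenomeInfoDb::seqlevels(bins)
  missing <- setdiff(need, have)
  if (length(missing))
    stop("chromosome missing from FASTA: ", paste(missing, collapse = ", "))
  seqs <- Rsamtools::getSeq(fa, bins)
  af <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)
  acgt <- rowSums(af[, c("A", "C", "G", "T"), drop = FALSE])
  gc <- ifelse(acgt > 0, (af[, "G"] + af[, "C"]) / acgt, NA_real_)
  nFrac <- 1 - acgt / width(bins)
  gc[nFrac > 0.5] <- NA_real_
  mcols(bins)$gc <- as.numeric(gc)
  bins
}

#' Count reads per bin from a coordinate-sorted BAM file
#'
#' Each mapped, primary, non-duplicate, non-supplementary read with mapping
#' quality at least `mapqMin` is assigned to exactly one bin by its leftmost
#' mapped coordinate. Reads on contigs absent from the grid are ignored (a
#' tally is reported via `message()`).
#'
#' @param bamFile Path to an indexed, coordinate-sorted BAM file.
#' @param bins Bin grid from [makeBins()].
#' @param mapqMin Minimum mapping quality (default 30).
#' @return Named integer vector of counts, one per bin.
#' @export
countReads <- function(bamFile, bins, mapqMin = 30) {
  if (!file.exists(bamFile)) stop("BAM file not found: ", bamFile)
  if (mapqMin < 0) stop("mapqMin must be >= 0")
  bai <- c(paste0(bamFile, ".bai"), sub("\\.bam$", ".bai", bamFile))
  if (!any(file.exists(bai)))
    stop("BAM index (.bai) not found for ", bamFile)
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isDuplicate = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag,
                                   what = c("rname", "pos", "mapq"))
  rec <- Rsamtools::scanBam(bamFile, param = param)[[1L]]
  keep <- !is.na(rec$pos) & !is.na(rec$mapq) & rec$mapq >= mapqMin
  rname <- as.character(rec$rname)[keep]
  pos <- rec$pos[keep]
  known <- rname %in% GenomeInfoDb::seqlevels(bins)
  if (any(!known))
    message(sum(!known), " read(s) on contigs absent from the bin grid ignored")
  starts <- GRanges(factor(rname[known],
                           levels = GenomeInfoDb::seqlevels(bins)),
                    IRanges(pos[known], width = 1))
  n <- countOverlaps(bins, starts)
  names(n) <- binIds(bins)
  n
}
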