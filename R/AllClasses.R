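#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#'   countOverlaps mcols "mcols<-"
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors metadata "metadata<-"
#' @importFrom stats sd qchisq plogis rnorm rbeta rnbinom loess median
#'   cor.test fitted pt
#' @importFrom utils head combn
NULL

setClassUnion("GRangesOrNULL", c("GRanges", "NULL"))

#' BinCounts: per-sample read counts over a fixed bin grid
#'
#' Container pairing an ordered genomic bin grid (a [GenomicRanges::GRanges]
#' with a `gc` metadata column) with a samples-by-bins count matrix. The
#' `stage` slot records how far the counts have progressed through the
#' preprocessing pipeline: `"raw"` (integer read counts), `"gc_corrected"`,
#' or `"vr_corrected"` (GC-corrected and variation-reduced).
#'
#' @slot bins `GRanges` of bins, sorted by (chromosome, start), with a
#'   numeric `gc` metadata column (fraction in \[0,1\], `NA` when unknown).
#' @slot counts Numeric matrix, samples in rows, bins in columns. Row names
#'   are sample identifiers; column names are canonical bin ids
#'   `"chrom:start-end"` (0-based half-open).
#' @slot stage Character scalar, one of `"raw"`, `"gc_corrected"`,
#'   `"vr_corrected"`.
#' @export
setClass("BinCounts",
  representation(bins = "GRanges", counts = "matrix", stage = "character"))

setValidity("BinCounts", function(object) {
  msg <- character()
  if (length(object@stage) != 1L ||
      !object@stage %in% c("raw", "gc_corrected", "vr_corrected"))
    msg <- c(msg, "stage must be one of 'raw', 'gc_corrected', 'vr_corrected'")
  if (ncol(object@counts) != length(object@bins))
    msg <- c(msg, "ncol(counts) must equal the number of bins")
  if (anyNA(object@counts) || any(!is.finite(object@counts)))
    msg <- c(msg, "counts must be finite")
  else if (any(object@counts < 0))
    msg <- c(msg, "counts must be non-negative")
  else if (identical(object@stage, "raw") &&
           any(abs(object@counts - round(object@counts)) > 1e-8))
    msg <- c(msg, "raw counts must be integers")
  if (is.null(rownames(object@counts)) ||
      anyDuplicated(rownames(object@counts)))
    msg <- c(msg, "counts must have unique sample_id row names")
  ord <- order(as.integer(GenomicRanges::seqnames(object@bins)),
               GenomicRanges::start(object@bins))
  if (!identical(ord, seq_along(object@bins)))
    msg <- c(msg, "bins must be sorted by (chromosome, start)")
  if (length(msg)) msg else TRUE
})

#' Construct a BinCounts object
#'
#' @param bins `GRanges` bin grid (see [makeBins()]).
#' @param counts Samples-by-bins matrix with sample ids as row names.
#' @param stage Preprocessing stage of the counts.
#' @return A [BinCounts-class] object.
#' @examples
#' gr <- makeBins(c(chr1 = 150000), 50000)
#' BinCounts(gr, matrix(1:3, 1, 3, dimnames = list("S1", NULL)))
#' @export
BinCounts <- function(bins, counts,
                      stage = c("raw", "gc_corrected", "vr_corrected")) {
  stage <- match.arg(stage)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  colnames(counts) <- binIds(bins)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("S%03d", seq_len(nrow(counts)))
  new("BinCounts", bins = bins, counts = counts, stage = stage)
}

#' @describeIn BinCounts-class Bin grid accessor.
#' @param x,object A `BinCounts` object.
#' @export
setGeneric("binGrid", function(x) standardGeneric("binGrid"))

#' @rdname BinCounts-class
#' @export
setMethod("binGrid", "BinCounts", function(x) x@bins)

#' @rdname BinCounts-class
#' @importFrom BiocGenerics counts
#' @export
setMethod("counts", "BinCounts", function(object) object@counts)

#' @describeIn BinCounts-class Preprocessing stage accessor.
#' @export
setGeneric("stage", function(x) standardGeneric("stage"))

#' @rdname BinCounts-class
#' @export
setMethod("stage", "BinCounts", function(x) x@stage)

#' @rdname BinCounts-class
#' @export
setMethod("dim", "BinCounts", function(x) dim(x@counts))

#' @rdname BinCounts-class
#' @export
setMethod("show", "BinCounts", function(object) {
  cat(sprintf("BinCounts: %d sample(s) x %d bins [%s]\n",
              nrow(object@counts), length(object@bins), object@stage))
  cat(sprintf("  chromosomes: %s\n",
              paste(GenomeInfoDb::seqlevels(object@bins), collapse = ", ")))
})

#' ReferenceModel: fitted preprocessing and per-method dosage statistics
#'
#' The single artifact produced by [fitReferenceModel()] from a euploid
#' reference cohort. It bundles the preprocessing state (GC strata, variation
#' reduction weights, excluded bins) with the fitted parameters of the three
#' chromosome-dosage statistics, so test samples can be scored reproducibly
#' from this object alone.
#'
#' @slot version Bundle format tag.
#' @slot bins Bin grid the model was fitted on.
#' @slot scored Logical per bin: participates in scoring (autosomal, GC
#'   known, not excluded).
#' @slot strata Integer GC-stratum group per bin (`NA` for unscored bins).
#' @slot gcParams List: `method` ("strata" or "loess"), `scope` ("sample" or
#'   "cohort"), `stratumWidth`, `minBinsPerStratum`, and for cohort scope the
#'   fixed `groupWeights`.
#' @slot vrWeights Numeric per-bin variation-reduction weight in (0, 1].
#' @slot chiCutoff Normalized chi-squared cutoff q* actually used.
#' @slot normTarget Reference-cohort mean total count (normalization target).
#' @slot targets Character names of the target chromosomes in grid naming.
#' @slot std Per-target list with `mu`, `sigma` of the reference chromosomal
#'   fraction.
#' @slot ncv Per-target list with `denomSet`, `rMu`, `rSigma`, `cv`.
#' @slot wsrb Per-target list with `binIndex`, `neighbors`, `bMu`, `bSigma`;
#'   plus `k` used.
#' @slot nRef Number of reference samples.
#' @export
setClass("ReferenceModel",
  representation(version = "character", bins = "GRanges", scored = "logical",
                 strata = "integer", gcParams = "list", vrWeights = "numeric",
                 chiCutoff = "numeric", normTarget = "numeric",
                 targets = "character", std = "list", ncv = "list",
                 wsrb = "list", nRef = "integer"))

setValidity("ReferenceModel", function(object) {
  msg <- character()
  nb <- length(object@bins)
  if (length(object@scored) != nb || length(object@vrWeights) != nb ||
      length(object@strata) != nb)
    msg <- c(msg, "scored/strata/vrWeights must have one entry per bin")
  w <- object@vrWeights[object@scored]
  if (length(w) && (any(w <= 0) || any(w > 1 + 1e-12)))
    msg <- c(msg, "variation-reduction weights must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname ReferenceModel-class
#' @param object A `ReferenceModel`.
#' @export
setMethod("show", "ReferenceModel", function(object) {
  cat(sprintf("ReferenceModel (%s): %d reference samples, %d/%d scored bins\n",
              object@version, object@nRef, sum(object@scored),
              length(object@bins)))
  for (tc in object@targets) {
    cat(sprintf("  %s: STD mu=%.5g sd=%.3g | NCV denom={%s} cv=%.3g | WSRB %d bins\n",
                tc, object@std[[tc]]$mu, object@std[[tc]]$sigma,
                paste(object@ncv[[tc]]$denomSet, collapse = ","),
                object@ncv[[tc]]$cv, length(object@wsrb[[tc]]$binIndex)))
  }
})

#' @describeIn ReferenceModel-class Per-target STD parameters.
#' @param x A `ReferenceModel`.
#' @export
stdParams <- function(x) x@std

#' @describeIn ReferenceModel-class Per-target NCV parameters.
#' @export
ncvParams <- function(x) x@ncv

#' @describeIn ReferenceModel-class Per-target WSRB parameters.
#' @export
wsrbParams <- function(x) x@wsrb

#' @describeIn ReferenceModel-class Logical vector of scored bins.
#' @export
scoredBins <- function(x) x@scored

#' @describeIn ReferenceModel-class Variation-reduction weights per bin.
#' @export
vrWeights <- function(x) x@vrWeights

#' EnsembleModel: logistic combination of the three Z statistics
#'
#' Coefficients of the binary logistic model fitted by [fitLogistic()],
#' optionally including sample GC percent and fetal fraction as covariates.
#'
#' @slot beta Named coefficient vector, `"(Intercept)"` first.
#' @slot featureNames Feature column names, in coefficient order.
#' @slot converged `TRUE` for a plain maximum-likelihood fit; `FALSE` when
#'   complete/quasi-separation was detected and the returned coefficients are
#'   the ridge-stabilized solution.
#' @slot iterations IRLS iterations used.
#' @slot logLik Unpenalized log-likelihood at the returned coefficients.
#' @export
setClass("EnsembleModel",
  representation(beta = "numeric", featureNames = "character",
                 converged = "logical", iterations = "integer",
                 logLik = "numeric"))

setValidity("EnsembleModel", function(object) {
  if (length(object@beta) != length(object@featureNames) + 1L)
    return("beta must have one coefficient per feature plus an intercept")
  if (any(!is.finite(object@beta)))
    return("coefficients must be finite")
  TRUE
})

#' @rdname EnsembleModel-class
#' @param object An `EnsembleModel`.
#' @export
setMethod("show", "EnsembleModel", function(object) {
  cat(sprintf("EnsembleModel: logit(p) ~ %s\n",
              paste(object@featureNames, collapse = " + ")))
  print(signif(object@beta, 6))
  cat(sprintf("  converged=%s iterations=%d logLik=%.4f\n",
              object@converged, object@iterations, object@logLik))
})

#' ConfusionSummary: confusion counts and derived screening metrics
#'
#' @slot tp,fp,tn,fn Non-negative integer counts of true positives, false
#'   positives, true negatives and false negatives.
#' @seealso [confusionMetrics()]
#' @export
setClass("ConfusionSummary",
  representation(tp = "integer", fp = "integer", tn = "integer",
                 fn = "integer"))

setValidity("ConfusionSummary", function(object) {
  v <- c(object@tp, object@fp, object@tn, object@fn)
  if (length(v) != 4L || anyNA(v) || any(v < 0))
    return("tp, fp, tn, fn must be non-negative integers")
  TRUE
})

#' @rdname ConfusionSummary-class
#' @param object A `ConfusionSummary`.
#' @export
setMethod("show", "ConfusionSummary", function(object) {
  m <- confusionStats(object)
  cat(sprintf("ConfusionSummary: tp=%d fp=%d tn=%d fn=%d\n",
              object@tp, object@fp, object@tn, object@fn))
  print(roundHalfUp(m, 3))
})

#' @rdname ConfusionSummary-class
#' @param x A `ConfusionSummary`.
#' @param row.names,optional,... Passed through (ignored).
#' @export
setMethod("as.data.frame", "ConfusionSummary",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(tp = x@tp, fp = x@fp, tn = x@tn, fn = x@fn,
               t(confusionStats(x)), row.names = row.names)
  })
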