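#' Fit the reference model on a euploid cohort
#'
#' Runs the full preprocessing chain on a reference cohort of raw bin counts
#' — GC correction, per-sample normalization to the cohort mean total, and
#' chi-squared variation reduction — then fits the three chromosome-dosage
#' statistics (STD, NCV, WSRB) for the target chromosomes on the corrected
#' counts. The returned [ReferenceModel-class] is self-contained: test
#' samples are scored against it with [scoreSamples()].
#'
#' @param ref A raw [BinCounts-class] reference cohort (n >= 3 samples).
#' @param targets Target chromosome numbers (default 13, 18, 21).
#' @param gcMethod `"strata"` (default) or `"loess"` GC correction.
#' @param gcScope `"sample"` (per-sample correction curve, default) or
#'   `"cohort"` (one curve from the cohort mean profile, applied to all).
#' @param stratumWidth,minBinsPerStratum GC strata parameters.
#' @param chiCutoffQuantile Variation-reduction cutoff quantile
#'   (default 0.9999).
#' @param maxDenoms Maximum NCV denominator set size (default 9).
#' @param ncvStrategy `"greedy"` (default) or `"exhaustive"`.
#' @param k WSRB neighbor count (default 100).
#' @param sdFloor WSRB minimum reference ratio SD.
#' @return A [ReferenceModel-class] object.
#' @export
fitReferenceModel <- function(ref, targets = c(13L, 18L, 21L),
                              gcMethod = c("strata", "loess"),
                              gcScope = c("sample", "cohort"),
                              stratumWidth = 0.01, minBinsPerStratum = 50,
                              chiCutoffQuantile = 0.9999, maxDenoms = 9,
                              ncvStrategy = c("greedy", "exhaustive"),
                              k = 100, sdFloor = 1e-10) {
  gcMethod <- match.arg(gcMethod)
  gcScope <- match.arg(gcScope)
  ncvStrategy <- match.arg(ncvStrategy)
  bins <- binGrid(ref)
  mat <- counts(ref)
  if (nrow(mat) < 3L) stop("insufficient reference samples")
  gc <- mcols(bins)$gc
  scored <- !is.na(gc) & isAutosome(seqnames(bins))
  if (!any(scored)) stop("no scorable bins (missing GC or no autosomes)")
  groups <- assignGcStrata(gc, scored, stratumWidth, minBinsPerStratum)

  cohortWeights <- NULL
  if (gcMethod == "strata" && gcScope == "cohort")
    cohortWeights <- gcStrataWeights(colMeans(mat), groups, scored)$weights
  gcRes <- gcCorrectMatrix(mat, gc, scored, groups, method = gcMethod,
                           cohortWeights = cohortWeights)
  scored[gcRes$zeroBins] <- FALSE

  normTarget <- mean(rowSums(gcRes$corrected[, scored, drop = FALSE]))
  normMat <- normalizeTotals(gcRes$corrected, scored, normTarget)
  vr <- chiVarianceWeights(normMat, scored, chiCutoffQuantile)
  scored[vr$zeroBins] <- FALSE
  corrected <- sweep(gcRes$corrected, 2L, vr$weights, "*")

  tchr <- targetChromNames(bins, targets)
  if (length(tchr) == 0L) stop("no target chromosomes present in the grid")
  std <- fitStdModel(corrected, bins, scored, tchr)
  cs <- chromosomeSums(corrected, bins, scored)
  ncv <- fitNcvModel(cs, tchr, maxDenoms = maxDenoms, strategy = ncvStrategy)
  wsrb <- buildWsrbReference(corrected, bins, scored, tchr, k = k,
                             sdFloor = sdFloor)
  new("ReferenceModel",
      version = "aneuscreen-reference-1",
      bins = bins, scored = scored, strata = groups,
      gcParams = list(method = gcMethod, scope = gcScope,
                      stratumWidth = stratumWidth,
                      minBinsPerStratum = minBinsPerStratum,
                      groupWeights = cohortWeights),
      vrWeights = vr$weights, chiCutoff = vr$qstar, normTarget = normTarget,
      targets = tchr, std = std, ncv = ncv, wsrb = wsrb,
      nRef = nrow(mat))
}

#' Apply the fitted preprocessing to new samples
#'
#' GC-corrects each sample (per-sample curve over the model's GC strata, or
#' the stored cohort curve) and applies the reference-fitted
#' variation-reduction weights, yielding counts comparable with those the
#' model statistics were fitted on.
#'
#' @param model A [ReferenceModel-class].
#' @param x A raw [BinCounts-class] on the same bin grid.
#' @return Corrected count matrix (samples x bins).
#' @export
preprocessCounts <- function(model, x) {
  bins <- binGrid(x)
  if (!identical(binIds(bins), binIds(model@bins)))
    stop("bin grid of the samples does not match the model grid")
  gc <- mcols(model@bins)$gc
  gcRes <- gcCorrectMatrix(counts(x), gc, model@scored, model@strata,
                           method = model@gcParams$method,
                           cohortWeights = model@gcParams$groupWeights)
  sweep(gcRes$corrected, 2L, model@vrWeights, "*")
}

#' @describeIn fitReferenceModel Score samples against a fitted model.
#' @param object A [ReferenceModel-class].
#' @param x A raw [BinCounts-class] of test (or reference) samples.
#' @return `scoreSamples`: tidy `data.frame` with columns `sample_id`,
#'   `chrom`, `method` (`STD`, `NCV`, `WSRB`) and `z`.
#' @export
setGeneric("scoreSamples", function(object, x) standardGeneric("scoreSamples"))

#' @rdname fitReferenceModel
#' @export
setMethod("scoreSamples", "ReferenceModel", function(object, x) {
  mat <- preprocessCounts(object, x)
  bins <- object@bins
  scored <- object@scored
  rows <- list()
  for (s in seq_len(nrow(mat))) {
    xs <- mat[s, ]
    sid <- rownames(mat)[s]
    for (tc in object@targets) {
      f <- chromosomeFraction(xs, bins, tc, scored)
      zs <- stdZ(f, object@std[[tc]]$mu, object@std[[tc]]$sigma)
      zn <- ncvZ(xs, bins, object@ncv[[tc]], tc, scored)
      zw <- wsrbZ(xs, object@wsrb[[tc]])
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, chrom = tc,
        method = c("STD", "NCV", "WSRB"), z = c(zs, zn, zw))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
})

#' Z-based trisomy calls from a score table
#'
#' @param zTable Tidy Z table from [scoreSamples()].
#' @param cutoff Z cutoff (default 3.0; the boundary calls trisomy).
#' @return `zTable` with an added `call` column.
#' @export
zCalls <- function(zTable, cutoff = 3.0) {
  zTable$call <- callTrisomyByZ(zTable$z, cutoff)
  zTable
}
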