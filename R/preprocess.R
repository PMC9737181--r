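## GC-stratum assignment: bins are grouped by GC fraction in fixed windows;
## strata with fewer than minBinsPerStratum scored bins are merged into the
## stratum whose mean GC is nearest (depends only on the grid, not on counts,
## so the grouping is shared by reference and test samples).
assignGcStrata <- function(gc, scored, stratumWidth = 0.01,
                           minBinsPerStratum = 50) {
  stopifnot(stratumWidth > 0, stratumWidth <= 1)
  lev <- floor(gc / stratumWidth)
  lev[!is.na(gc) & gc >= 1] <- floor(1 / stratumWidth) - 1
  lev[!scored] <- NA_integer_
  groups <- lev
  repeat {
    tab <- table(groups)
    if (length(tab) <= 1L) break
    small <- names(tab)[tab < minBinsPerStratum]
    if (!length(small)) break
    ## merge the smallest stratum into the one with the nearest mean GC
    g <- small[which.min(tab[small])]
    meanGc <- tapply(gc[scored], groups[scored], mean)
    others <- setdiff(names(meanGc), g)
    nearest <- others[which.min(abs(meanGc[others] - meanGc[[g]]))]
    groups[!is.na(groups) & groups == as.numeric(g)] <- as.numeric(nearest)
  }
  as.integer(groups)
}

## per-sample strata weights: w_g = mean(all scored bins) / mean(stratum g)
gcStrataWeights <- function(x, groups, scored) {
  idx <- scored & !is.na(groups)
  gmean <- mean(x[idx])
  smean <- tapply(x[idx], groups[idx], mean)
  w <- stats::setNames(as.numeric(gmean / smean), names(smean))
  zero <- names(smean)[smean == 0]
  list(weights = w, zeroStrata = zero)
}

applyStrataWeights <- function(x, groups, scored, w) {
  out <- x
  idx <- which(scored & !is.na(groups))
  wi <- w[as.character(groups[idx])]
  wi[!is.finite(wi)] <- 0
  out[idx] <- x[idx] * wi
  out
}

gcCorrectRowLoess <- function(x, gc, scored, span = 0.3) {
  idx <- which(scored & !is.na(gc))
  fit <- stats::loess(x[idx] ~ gc[idx], span = span, degree = 2)
  f <- pmax(fitted(fit), 1e-8)
  out <- x
  out[idx] <- x[idx] * stats::median(f) / f
  out
}

## core matrix-level GC correction; returns corrected matrix plus the per-
## sample stratum weight curves and any bins landing in zero-mean strata
gcCorrectMatrix <- function(mat, gc, scored, groups,
                            method = c("strata", "loess"),
                            cohortWeights = NULL, span = 0.3) {
  method <- match.arg(method)
  out <- mat
  curves <- vector("list", nrow(mat))
  names(curves) <- rownames(mat)
  zeroBins <- integer()
  for (s in seq_len(nrow(mat))) {
    x <- mat[s, ]
    if (sum(x[scored]) <= 0) stop("sample ", rownames(mat)[s],
                                  ": total scored count is zero")
    if (method == "loess") {
      out[s, ] <- gcCorrectRowLoess(x, gc, scored, span = span)
    } else {
      w <- if (is.null(cohortWeights))
        gcStrataWeights(x, groups, scored)
      else list(weights = cohortWeights, zeroStrata = character())
      out[s, ] <- applyStrataWeights(x, groups, scored, w$weights)
      curves[[s]] <- w$weights
      if (length(w$zeroStrata))
        zeroBins <- union(zeroBins,
                          which(!is.na(groups) &
                                groups %in% as.numeric(w$zeroStrata)))
    }
  }
  list(corrected = out, curves = curves, zeroBins = sort(zeroBins))
}

#' GC-content correction of bin counts
#'
#' Corrects per-bin read counts for GC bias. With the default `"strata"`
#' method, bins are grouped into GC windows of `stratumWidth` (windows with
#' fewer than `minBinsPerStratum` bins are merged with the nearest-GC
#' window), and each sample's counts in stratum *g* are scaled by
#' `mean(all scored bins) / mean(stratum g)`, which preserves the sample's
#' grand total exactly. With `"loess"`, a per-sample smooth of count versus
#' GC is fitted and counts are scaled by `median(fitted)/fitted`.
#'
#' @param x A [BinCounts-class] object with GC filled on its grid.
#' @param method `"strata"` (exactly reproducible ratio weights, default) or
#'   `"loess"`.
#' @param stratumWidth GC window width for the strata method (default 0.01).
#' @param minBinsPerStratum Minimum scored bins per stratum before merging
#'   (default 50).
#' @param span LOESS span for `method = "loess"`.
#' @return A [BinCounts-class] object at stage `"gc_corrected"`, with the
#'   per-sample stratum weight curves in `attr(, "gcCurves")` and the indices
#'   of bins in zero-mean strata (to be excluded) in `attr(, "excluded")`.
#' @export
gcCorrect <- function(x, method = c("strata", "loess"), stratumWidth = 0.01,
                      minBinsPerStratum = 50, span = 0.3) {
  method <- match.arg(method)
  bins <- binGrid(x)
  gc <- mcols(bins)$gc
  scored <- !is.na(gc) & isAutosome(seqnames(bins))
  if (!any(scored)) stop("no scored bins: GC missing for all autosomal bins")
  groups <- assignGcStrata(gc, scored, stratumWidth, minBinsPerStratum)
  res <- gcCorrectMatrix(counts(x), gc, scored, groups, method = method,
                         span = span)
  out <- BinCounts(bins, res$corrected, stage = "gc_corrected")
  attr(out, "gcCurves") <- res$curves
  attr(out, "excluded") <- res$zeroBins
  out
}

## normalize rows so every sample has the cohort-mean total over scored bins
normalizeTotals <- function(mat, scored, target = NULL) {
  tot <- rowSums(mat[, scored, drop = FALSE])
  if (any(tot <= 0)) stop("sample with zero scored total")
  if (is.null(target)) target <- mean(tot)
  mat * (target / tot)
}

## chi-squared variation reduction on a normalized reference matrix.
## q_i = chi2_i / (n-1); bins with q above the chi-squared-quantile cutoff
## q* are down-weighted multiplicatively by q*/q_i.
chiVarianceWeights <- function(normMat, scored, chiCutoffQuantile = 0.9999) {
  n <- nrow(normMat)
  if (n < 3L) stop("insufficient reference samples")
  e <- colMeans(normMat[, scored, drop = FALSE])
  zero <- which(scored)[e == 0]
  idx <- which(scored)[e > 0]
  e <- e[e > 0]
  dev <- sweep(normMat[, idx, drop = FALSE], 2L, e)
  chi <- colSums(sweep(dev^2, 2L, e, "/"))
  q <- chi / (n - 1)
  qstar <- stats::qchisq(chiCutoffQuantile, df = n - 1) / (n - 1)
  w <- rep(1, ncol(normMat))
  w[idx] <- ifelse(q > qstar, qstar / q, 1)
  w[zero] <- 1
  list(weights = w, qstar = qstar, q = q, qIndex = idx, zeroBins = zero)
}

#' Chi-squared based variation reduction
#'
#' Down-weights bins whose counts vary across the euploid reference cohort
#' more than chance expectation. For bin *i* with cross-sample expectation
#' `e_i` (after per-sample normalization to the cohort mean total), the
#' statistic `chi2_i = sum_s (x_si - e_i)^2 / e_i` is scaled to
#' `q_i = chi2_i / (n - 1)` and compared with the cutoff
#' `q* = qchisq(chiCutoffQuantile, n - 1) / (n - 1)`. Bins with `q_i > q*`
#' receive multiplicative weight `q*/q_i` (otherwise 1); the same weights are
#' later applied to test samples. Bins with zero expectation are excluded.
#'
#' @param x A GC-corrected [BinCounts-class] reference cohort (n >= 3).
#' @param chiCutoffQuantile Chi-squared cutoff quantile (default 0.9999).
#' @return A list with `weights` (per-bin, in (0,1\]), `qstar`, `counts`
#'   (a `BinCounts` at stage `"vr_corrected"` with weights applied), and
#'   `excluded` (indices of zero-expectation bins).
#' @export
chiSquaredVariationReduction <- function(x, chiCutoffQuantile = 0.9999) {
  bins <- binGrid(x)
  gc <- mcols(bins)$gc
  scored <- !is.na(gc) & isAutosome(seqnames(bins))
  normMat <- normalizeTotals(counts(x), scored)
  res <- chiVarianceWeights(normMat, scored, chiCutoffQuantile)
  corrected <- sweep(counts(x), 2L, res$weights, "*")
  out <- BinCounts(bins, corrected, stage = "vr_corrected")
  list(weights = res$weights, qstar = res$qstar, counts = out,
       excluded = res$zeroBins)
}
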