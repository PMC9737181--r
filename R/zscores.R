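#' Chromosomal fraction of a sample
#'
#' Fraction of the sample's autosomal read counts falling on one chromosome,
#' the dosage unit used by the standard Z statistic. Excluded bins are
#' omitted from both the numerator and the denominator.
#'
#' @param x Numeric count vector over the bins of `bins` (raw or corrected).
#' @param bins Bin grid.
#' @param chrom Chromosome name (grid naming).
#' @param scored Logical per bin; defaults to autosomal bins with known GC.
#' @return The fraction `f_c` in (0, 1).
#' @export
chromosomeFraction <- function(x, bins, chrom, scored = NULL) {
  if (is.null(scored))
    scored <- !is.na(mcols(bins)$gc) & isAutosome(seqnames(bins))
  auto <- scored & isAutosome(seqnames(bins))
  total <- sum(x[auto])
  if (total <= 0) stop("zero autosomal total count")
  sum(x[auto & as.logical(seqnames(bins) == chrom)]) / total
}

## samples x autosomes matrix of per-chromosome scored count sums
chromosomeSums <- function(mat, bins, scored) {
  auto <- scored & isAutosome(seqnames(bins))
  chr <- as.character(seqnames(bins))[auto]
  t(rowsum(t(mat[, auto, drop = FALSE]), group = chr, reorder = FALSE))
}

## ---- standard Z (STD) -----------------------------------------------------

fitStdModel <- function(refMat, bins, scored, targets) {
  if (nrow(refMat) < 3L) stop("insufficient reference samples")
  out <- lapply(targets, function(tc) {
    f <- apply(refMat, 1L, chromosomeFraction, bins = bins, chrom = tc,
               scored = scored)
    s <- stats::sd(f)
    if (!is.finite(s) || s == 0) stop("degenerate reference: zero variance of ",
                                      tc, " fraction")
    list(mu = mean(f), sigma = s)
  })
  names(out) <- targets
  out
}

#' Standard Z-score (STD) of a chromosome dosage
#'
#' `z = (f_c - mu_c) / sigma_c`, where `f_c` is the sample's chromosomal
#' fraction and `mu_c`, `sigma_c` are the mean and sample standard deviation
#' (n-1 denominator) of the reference cohort's fractions.
#'
#' @param f Chromosomal fraction of the test sample ([chromosomeFraction()]).
#' @param mu,sigma Reference mean and standard deviation of the fraction.
#' @return The Z value.
#' @export
stdZ <- function(f, mu, sigma) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  (f - mu) / sigma
}

## ---- normalized chromosome value (NCV) ------------------------------------

ncvCv <- function(chromSums, target, set) {
  r <- chromSums[, target] / rowSums(chromSums[, set, drop = FALSE])
  stats::sd(r) / mean(r)
}

#' Select the NCV denominator chromosome set
#'
#' Chooses the set of non-target autosomes (up to `maxDenoms`, default 9)
#' whose summed counts minimize the coefficient of variation of the ratio
#' `R = count(target) / count(set)` across the reference cohort. The greedy
#' strategy adds, at each step, the chromosome that most reduces the CV and
#' stops when no addition strictly reduces it; the exhaustive strategy
#' enumerates every non-empty subset up to `maxDenoms` (intended as an oracle
#' for small candidate lists). Ties favour the smaller set, then the
#' lower-numbered chromosome.
#'
#' @param chromSums Samples-by-chromosomes matrix of reference counts
#'   (autosomes only; see internals of [fitReferenceModel()]).
#' @param target Target chromosome column name.
#' @param maxDenoms Maximum denominator set size (default 9).
#' @param strategy `"greedy"` (default) or `"exhaustive"`.
#' @param exclude Chromosome names never allowed in the denominator
#'   (defaults to chromosomes 13, 18 and 21).
#' @return List with `denomSet` (chromosome names) and `cv` (achieved CV).
#' @export
selectNcvDenominator <- function(chromSums, target, maxDenoms = 9,
                                 strategy = c("greedy", "exhaustive"),
                                 exclude = NULL) {
  strategy <- match.arg(strategy)
  chroms <- colnames(chromSums)
  if (is.null(exclude)) exclude <- chroms[chromNumber(chroms) %in% c(13L, 18L, 21L)]
  cand <- setdiff(chroms[isAutosome(chroms)], c(target, exclude))
  cand <- cand[order(chromNumber(cand))]
  if (!length(cand)) stop("empty candidate chromosome list")
  if (strategy == "exhaustive") {
    best <- NULL; bestCv <- Inf
    for (size in seq_len(min(maxDenoms, length(cand)))) {
      sets <- utils::combn(cand, size, simplify = FALSE)
      for (set in sets) {
        cv <- ncvCv(chromSums, target, set)
        if (cv < bestCv - 1e-15) { bestCv <- cv; best <- set }
      }
    }
    return(list(denomSet = best, cv = bestCv))
  }
  set <- character(); bestCv <- Inf
  while (length(set) < min(maxDenoms, length(cand))) {
    remaining <- setdiff(cand, set)
    cvs <- vapply(remaining, function(ch) ncvCv(chromSums, target, c(set, ch)),
                  numeric(1))
    if (min(cvs) >= bestCv) break
    set <- c(set, remaining[which.min(cvs)])
    bestCv <- min(cvs)
  }
  list(denomSet = set, cv = bestCv)
}

fitNcvModel <- function(chromSums, targets, maxDenoms = 9,
                        strategy = "greedy") {
  out <- lapply(targets, function(tc) {
    sel <- selectNcvDenominator(chromSums, tc, maxDenoms = maxDenoms,
                                strategy = strategy)
    r <- chromSums[, tc] / rowSums(chromSums[, sel$denomSet, drop = FALSE])
    s <- stats::sd(r)
    if (!is.finite(s) || s == 0) stop("degenerate reference: zero variance of ",
                                      tc, " ratio")
    list(denomSet = sel$denomSet, rMu = mean(r), rSigma = s, cv = sel$cv)
  })
  names(out) <- targets
  out
}

#' Normalized chromosome value (NCV) Z-score
#'
#' `z = (R - rMu) / rSigma` with `R = count(target) / count(denomSet)` in the
#' test sample and `rMu`, `rSigma` the reference mean and SD of the ratio.
#' The ratio cancels sequencing depth, so the statistic is invariant to
#' uniform scaling of a sample's counts.
#'
#' @param x Corrected count vector of the test sample.
#' @param bins Bin grid.
#' @param ncvTarget One target's entry of [ncvParams()] (fields `denomSet`,
#'   `rMu`, `rSigma`).
#' @param chrom Target chromosome name.
#' @param scored Logical vector of scored bins.
#' @return The Z value.
#' @export
ncvZ <- function(x, bins, ncvTarget, chrom, scored = NULL) {
  if (is.null(scored))
    scored <- !is.na(mcols(bins)$gc) & isAutosome(seqnames(bins))
  chr <- as.character(seqnames(bins))
  num <- sum(x[scored & chr == chrom])
  den <- sum(x[scored & chr %in% ncvTarget$denomSet])
  if (den <= 0) stop("zero denominator count")
  ((num / den) - ncvTarget$rMu) / ncvTarget$rSigma
}

## ---- within-sample reference bin (WSRB) -----------------------------------

#' Build the within-sample reference-bin (WSRB) model
#'
#' For every scored bin on a target chromosome, finds the `k` bins on
#' non-target autosomes whose depth-normalized behaviour across the reference
#' cohort is most similar (smallest sum of squared differences of the
#' sample-normalized count profiles), then records the reference mean and SD
#' of the within-sample ratio `t_i = count(bin i) / count(neighbor set)`.
#' Bins whose ratio SD falls below `sdFloor` (or whose neighbor sums are not
#' strictly positive in some reference sample) are dropped from scoring.
#'
#' @param refMat Corrected reference count matrix (samples x bins).
#' @param bins Bin grid.
#' @param scored Logical vector of scored bins.
#' @param targets Target chromosome names.
#' @param k Neighbor count (default 100). If fewer candidate bins exist, all
#'   are used with a warning.
#' @param sdFloor Minimum reference SD of `t_i` for a bin to be scored.
#' @return Per-target list with `binIndex` (grid indices of scored target
#'   bins), `neighbors` (list of grid-index vectors), `bMu`, `bSigma`, and
#'   the reference-cohort calibration `sMu`, `sSd` of the Stouffer
#'   chromosome statistic.
#' @export
buildWsrbReference <- function(refMat, bins, scored, targets, k = 100,
                               sdFloor = 1e-10) {
  if (nrow(refMat) < 3L) stop("insufficient reference samples")
  chr <- as.character(seqnames(bins))
  candIdx <- which(scored & isAutosome(chr) & !(chr %in% targets))
  if (!length(candIdx)) stop("no candidate reference bins")
  if (length(candIdx) < k) {
    warning("fewer than k candidate bins; using all ", length(candIdx))
    k <- length(candIdx)
  }
  scoredIdx <- which(scored)
  norm <- refMat[, scoredIdx, drop = FALSE]
  norm <- norm / rowSums(norm)
  colIn <- match(candIdx, scoredIdx)
  B <- norm[, colIn, drop = FALSE]
  b2 <- colSums(B^2)
  out <- lapply(targets, function(tc) {
    tgtIdx <- which(scored & chr == tc)
    if (!length(tgtIdx)) stop("no scorable bins on ", tc)
    A <- norm[, match(tgtIdx, scoredIdx), drop = FALSE]
    ## d(i,j) = |a_i|^2 + |b_j|^2 - 2 a_i . b_j over reference samples
    d <- outer(colSums(A^2), b2, "+") - 2 * crossprod(A, B)
    nbrs <- vector("list", length(tgtIdx))
    bMu <- bSigma <- numeric(length(tgtIdx))
    keep <- logical(length(tgtIdx))
    for (i in seq_along(tgtIdx)) {
      ord <- order(d[i, ], candIdx)          # ties broken by genomic order
      nbr <- candIdx[ord[seq_len(k)]]
      den <- rowSums(refMat[, nbr, drop = FALSE])
      if (any(den <= 0)) next
      t_i <- refMat[, tgtIdx[i]] / den
      s <- stats::sd(t_i)
      if (!is.finite(s) || s < sdFloor) next
      nbrs[[i]] <- nbr
      bMu[i] <- mean(t_i)
      bSigma[i] <- s
      keep[i] <- TRUE
    }
    if (!any(keep)) stop("all bins dropped on ", tc,
                         " (degenerate reference cohort)")
    tgt <- list(binIndex = tgtIdx[keep], neighbors = nbrs[keep],
                bMu = bMu[keep], bSigma = bSigma[keep])
    ## calibrate the Stouffer chromosome statistic on the reference cohort:
    ## neighboring-bin z values are mildly correlated (shared neighbor sets,
    ## shared GC strata), so the raw sum/sqrt(m) is over-dispersed relative
    ## to N(0,1); standardizing against the reference cohort restores the
    ## Z-score semantics the z >= 3 call rule assumes
    sRef <- apply(refMat, 1L, wsrbStoufferRaw, wsrbTarget = tgt)
    tgt$sMu <- mean(sRef)
    tgt$sSd <- stats::sd(sRef)
    if (!is.finite(tgt$sSd) || tgt$sSd < 1e-12)
      stop("degenerate reference cohort: constant chromosome statistic on ",
           tc)
    tgt
  })
  names(out) <- targets
  out
}

## raw (uncalibrated) Stouffer combination sum(z_i)/sqrt(m)
wsrbStoufferRaw <- function(x, wsrbTarget) {
  den <- vapply(wsrbTarget$neighbors, function(j) sum(x[j]), numeric(1))
  ok <- den > 0
  if (!any(ok)) stop("all bins skipped: zero neighbor-set counts")
  t_i <- x[wsrbTarget$binIndex[ok]] / den[ok]
  z_i <- (t_i - wsrbTarget$bMu[ok]) / wsrbTarget$bSigma[ok]
  sum(z_i) / sqrt(sum(ok))
}

#' Within-sample reference-bin (WSRB) chromosome Z-score
#'
#' For each scored bin on the target chromosome the test sample's ratio
#' `t_i = count(i) / count(neighbor set i)` is standardized against the
#' reference bin statistics, `z_i = (t_i - bMu_i) / bSigma_i`, and the bin
#' Z values are combined by Stouffer's method, `sum(z_i) / sqrt(m)`. Because
#' bin-level z values are mildly correlated, the combined statistic is then
#' standardized against the reference cohort's own Stouffer values (mean
#' `sMu`, SD `sSd` stored in the model), which restores unit-normal null
#' behaviour. Bins whose neighbor-set count is zero in the test sample are
#' skipped; if every bin is skipped an error is raised.
#'
#' @param x Corrected count vector of the test sample.
#' @param wsrbTarget One target's entry of [wsrbParams()].
#' @return The calibrated chromosome Z value.
#' @export
wsrbZ <- function(x, wsrbTarget) {
  raw <- wsrbStoufferRaw(x, wsrbTarget)
  (raw - wsrbTarget$sMu) / wsrbTarget$sSd
}

#' Trisomy call from a Z-score
#'
#' A chromosome with Z at or above the cutoff (default 3.0) is called
#' trisomic; the boundary value itself calls trisomy.
#'
#' @param z Numeric Z value(s).
#' @param cutoff Call threshold (default 3.0).
#' @return Character vector, `"trisomy"` or `"normal"`.
#' @examples
#' callTrisomyByZ(c(3, 2.999, -5))
#' @export
callTrisomyByZ <- function(z, cutoff = 3.0) {
  if (any(!is.finite(z))) stop("z must be finite")
  ifelse(z >= cutoff, "trisomy", "normal")
}
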