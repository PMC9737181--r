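## small deterministic fixtures shared across test files; everything is
## generated in code at test time

## bin grid with constant GC (GC correction becomes the identity)
flatGrid <- function(sizes = c(chr1 = 2000, chr2 = 2000, chr13 = 1000,
                               chr18 = 1000, chr21 = 1000),
                     binSize = 100, gc = 0.41) {
  bins <- makeBins(sizes, binSize)
  GenomicRanges::mcols(bins)$gc <- gc
  bins
}

## reference cohort of near-constant counts with multiplicative noise
flatCohort <- function(n = 6, bins = flatGrid(), mu = 100, noise = 0.05,
                       seed = 7) {
  set.seed(seed)
  mat <- matrix(rpois(n * length(bins), mu), nrow = n,
                dimnames = list(sprintf("R%02d", seq_len(n)), NULL))
  BinCounts(bins, mat, stage = "raw")
}

## memoised desk-scale cohorts so expensive fits run once per suite
.fixtureCache <- new.env(parent = emptyenv())

cachedCalibrationRun <- function() {
  if (is.null(.fixtureCache$calib)) {
    sim <- simulateCohort(simConfig(nReference = 100, nTest = 60, seed = 101))
    model <- fitReferenceModel(sim$reference)
    .fixtureCache$calib <- list(sim = sim, model = model,
                                zTable = scoreSamples(model, sim$test))
  }
  .fixtureCache$calib
}

## a seeded logistic toy that is NOT linearly separable
logisticToy <- function() {
  data.frame(x = c(-2, -1, -0.5, 0.5, -0.3, 0.3, 1, 2),
             y = c(0, 0, 1, 0, 1, 0, 1, 1))
}

## brute-force log-likelihood grid maximization (independent of the IRLS path)
gridLogistic <- function(x, y, b0 = c(-4, 4), b1 = c(-2, 6), steps = 81,
                         refinements = 4) {
  ll <- function(beta0, beta1) {
    eta <- beta0 + beta1 * x
    sum(y * eta - log1p(exp(eta)))
  }
  for (r in seq_len(refinements)) {
    g0 <- seq(b0[1], b0[2], length.out = steps)
    g1 <- seq(b1[1], b1[2], length.out = steps)
    vals <- outer(g0, g1, Vectorize(ll))
    i <- which(vals == max(vals), arr.ind = TRUE)[1, ]
    best <- c(g0[i[1]], g1[i[2]])
    s0 <- diff(b0) / (steps - 1); s1 <- diff(b1) / (steps - 1)
    b0 <- best[1] + c(-2, 2) * s0
    b1 <- best[2] + c(-2, 2) * s1
  }
  best
}

## constructed NCV toy: samples-by-chromosomes counts with a shared depth
## factor and exactly orthogonal (uncorrelated in-sample), mean-zero noise
## columns whose SDs form a well-separated geometric ladder
ncvToy <- function(nCand, n = 8, seed = 1, target = "chr21") {
  set.seed(seed)
  k <- nCand + 1
  raw <- matrix(rnorm(n * k), n, k)
  raw <- sweep(raw, 2, colMeans(raw))
  q <- qr.Q(qr(raw))                         # orthonormal, mean-zero columns
  sds <- 0.002 * 2^(seq_len(k) - 1)
  sds <- sample(sds)                         # random assignment to chroms
  eps <- sweep(q, 2, sds * sqrt(n - 1), "*")
  depth <- exp(rnorm(n, log(1e6), 0.2))
  cs <- depth * (1 + eps)
  dimnames(cs) <- list(paste0("S", seq_len(n)),
                       c(paste0("chr", seq_len(nCand)), target))
  cs
}

## feature table with n samples x two chromosomes, mildly noisy classes
loocvFixture <- function(seed = 21, n = 8) {
  set.seed(seed)
  lab <- rep(c(0, 1), length.out = n * 2)
  data.frame(sample_id = rep(sprintf("S%02d", 1:n), each = 2),
             chrom = rep(c("chr18", "chr21"), n),
             f1 = lab * 2 + rnorm(n * 2),
             f2 = rnorm(n * 2),
             label = lab)
}

## write a tiny coordinate-sorted SAM and convert to indexed BAM
makeToyBam <- function(reads, chromSizes = c(chr1 = 125000), index = TRUE) {
  sam <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chromSizes), chromSizes))
  body <- character()
  if (nrow(reads)) {
    reads <- reads[order(match(reads$chrom, names(chromSizes)), reads$pos), ]
    body <- sprintf("r%03d\t%d\t%s\t%d\t%d\t10M\t*\t0\t0\tACGTACGTAC\t**********",
                    seq_len(nrow(reads)), reads$flag %||% 0L, reads$chrom,
                    reads$pos, reads$mapq)
  }
  writeLines(c(hdr, body), sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = index)
  bam
}

`%||%` <- function(a, b) if (is.null(a)) b else a
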