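#' hg19 autosome lengths
#'
#' @return Named numeric vector of hg19 autosome lengths (bp), chr1..chr22.
#' @export
hg19AutosomeLengths <- function() {
  c(chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
    chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
    chr9 = 141213431, chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
    chr13 = 115169878, chr14 = 107349540, chr15 = 102531392, chr16 = 90354753,
    chr17 = 81195210, chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
    chr21 = 48129895, chr22 = 51304566)
}

#' Simulate an autocorrelated per-bin GC profile
#'
#' Per-bin GC is drawn from a Beta distribution with the requested mean, then
#' smoothed along the genome with a circular moving-average filter (GC varies
#' smoothly at the 50 kb scale in real genomes) and clipped to `range`.
#'
#' @param n Number of bins (or a `GRanges` whose length is used).
#' @param meanGC Target mean GC (default 0.41).
#' @param concentration Beta concentration (alpha + beta, default 20).
#' @param window Moving-average window in bins (default 5).
#' @param range Clipping range (default \[0.2, 0.8\]).
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return Numeric GC vector of length `n`.
#' @export
simulateGcProfile <- function(n, meanGC = 0.41, concentration = 20,
                              window = 5, range = c(0.2, 0.8), seed = NULL) {
  if (inherits(n, "GRanges")) n <- length(n)
  if (!is.null(seed)) set.seed(seed)
  raw <- stats::rbeta(n, meanGC * concentration, (1 - meanGC) * concentration)
  sm <- stats::filter(raw, rep(1 / window, window), sides = 2,
                      circular = TRUE)
  pmin(pmax(as.numeric(sm), range[1]), range[2])
}

#' Quadratic GC bias curve
#'
#' Relative amplification efficiency as a function of bin GC: a downward
#' parabola peaking at `gcOptimum`, floored at 0.1. `amplitude` is the
#' efficiency loss at `gcOptimum +/- 0.25` GC units.
#'
#' @param gc GC fractions.
#' @param amplitude Bias amplitude (0 disables the bias).
#' @param gcOptimum GC of maximal efficiency (default 0.41).
#' @return Relative rates (max 1).
#' @export
gcBiasCurve <- function(gc, amplitude = 0.3, gcOptimum = 0.41) {
  pmax(0.1, 1 - amplitude * ((gc - gcOptimum) / 0.25)^2)
}

#' Expected per-bin sampling rates
#'
#' Base rate proportional to bin width times the GC bias curve; bins on a
#' chromosome carrying a simulated trisomy at fetal fraction `ff` are lifted
#' by the cfDNA mixture factor `1 + ff/2` (one extra fetal chromosome copy
#' over the diploid background). Rates are normalized to sum to 1.
#'
#' @param bins Bin grid with `gc` filled.
#' @param gcBiasAmplitude,gcOptimum GC bias parameters ([gcBiasCurve()]).
#' @param trisomyChrom Optional chromosome name carrying a trisomy.
#' @param ff Fetal fraction (0-1 scale) of the trisomy.
#' @return Numeric rate vector summing to 1.
#' @export
expectedBinRates <- function(bins, gcBiasAmplitude = 0.3, gcOptimum = 0.41,
                             trisomyChrom = NULL, ff = 0) {
  gc <- mcols(bins)$gc
  lambda <- width(bins) * gcBiasCurve(gc, gcBiasAmplitude, gcOptimum)
  if (!is.null(trisomyChrom) && ff > 0) {
    on <- as.logical(seqnames(bins) == trisomyChrom)
    lambda[on] <- lambda[on] * (1 + ff / 2)
  }
  lambda / sum(lambda)
}

#' Simulator configuration
#'
#' Bundles and validates the parameters of [simulateCohort()]. The defaults
#' describe a desk-scale cohort: hg19 autosomes scaled to 1/20 length, 50 kb
#' bins, 200,000 reads per sample (per-bin depth comparable to the >2 million
#' reads of a full-genome shallow-WGS run), negative-binomial counts of size
#' 200, 2% noisy bins with 20-fold smaller size, and a euploid fetal-fraction
#' background of Normal(11%, 3.5%) truncated to \[1, 25\]%.
#'
#' @param nReference,nTest Cohort sizes.
#' @param binSize Bin width (bp).
#' @param scaleFactor Genome length divisor (1 = full-length hg19 autosomes,
#'   with 2,000,000 reads per sample the matching full-scale depth).
#' @param readsPerSample Expected total reads per sample.
#' @param gcBiasAmplitude,gcOptimum GC bias ([gcBiasCurve()]).
#' @param dispersion Negative-binomial size (larger = closer to Poisson).
#' @param noisyBinFraction Fraction of bins with inflated variance.
#' @param noisyBinInflation Factor dividing the NB size of noisy bins.
#' @param trisomySpecs `data.frame` with columns `sample` (test sample
#'   index), `chrom` (13/18/21 or "chr21"), `ff` (fetal fraction, 0-1).
#' @param ffMeanPercent,ffSdPercent Euploid fetal-fraction background (%).
#' @param seed Integer seed fixing all randomness end-to-end.
#' @return Validated list of class `SimConfig`.
#' @export
simConfig <- function(nReference = 100, nTest = 30, binSize = 50000,
                      scaleFactor = 20, readsPerSample = 200000,
                      gcBiasAmplitude = 0.3, gcOptimum = 0.41,
                      dispersion = 200, noisyBinFraction = 0.02,
                      noisyBinInflation = 20, trisomySpecs = NULL,
                      ffMeanPercent = 11, ffSdPercent = 3.5, seed = 1) {
  stopifnot(nReference >= 1, nTest >= 0, binSize > 0, readsPerSample > 0,
            scaleFactor >= 1, dispersion > 0, noisyBinInflation >= 1,
            noisyBinFraction >= 0, noisyBinFraction < 1)
  if (!is.null(trisomySpecs)) {
    trisomySpecs <- as.data.frame(trisomySpecs)
    stopifnot(all(c("sample", "chrom", "ff") %in% names(trisomySpecs)))
    if (any(trisomySpecs$sample < 1 | trisomySpecs$sample > nTest))
      stop("trisomy spec references a nonexistent test sample")
    if (any(trisomySpecs$ff <= 0 | trisomySpecs$ff >= 1))
      stop("trisomy ff must be in (0, 1)")
    trisomySpecs$chrom <- ifelse(grepl("^chr", trisomySpecs$chrom),
                                 as.character(trisomySpecs$chrom),
                                 paste0("chr", trisomySpecs$chrom))
    if (!all(trisomySpecs$chrom %in% c("chr13", "chr18", "chr21")))
      stop("trisomy chrom must be 13, 18 or 21")
  }
  structure(list(nReference = nReference, nTest = nTest, binSize = binSize,
                 scaleFactor = scaleFactor, readsPerSample = readsPerSample,
                 gcBiasAmplitude = gcBiasAmplitude, gcOptimum = gcOptimum,
                 dispersion = dispersion, noisyBinFraction = noisyBinFraction,
                 noisyBinInflation = noisyBinInflation,
                 trisomySpecs = trisomySpecs, ffMeanPercent = ffMeanPercent,
                 ffSdPercent = ffSdPercent, seed = as.integer(seed)),
            class = "SimConfig")
}

#' Default trisomy spike-in table for the end-to-end harness
#'
#' Assigns the first `nTrisomic` test samples a trisomy, cycling through
#' chromosomes 21, 18 and 13 so all targets are exercised, at a fixed fetal
#' fraction.
#'
#' @param nTrisomic Number of trisomic test samples.
#' @param ff Fetal fraction (0-1 scale).
#' @return `data.frame` usable as `trisomySpecs`.
#' @export
defaultTrisomySpecs <- function(nTrisomic = 10, ff = 0.15) {
  data.frame(sample = seq_len(nTrisomic),
             chrom = rep(c("chr21", "chr18", "chr13"),
                         length.out = nTrisomic),
             ff = ff)
}

#' Simulate a synthetic cfDNA cohort
#'
#' Generates a euploid reference cohort plus a test cohort of bin counts on a
#' scaled hg19 autosome grid. Counts are negative-binomial around GC-biased
#' expected rates; a fixed random subset of bins gets inflated variance
#' (targets for chi-squared variation reduction); trisomic test samples have
#' the affected chromosome's rates lifted by `1 + ff/2`. All randomness is
#' fixed by `config$seed`.
#'
#' @param config A [simConfig()] object (or arguments passed to it via
#'   `...`).
#' @param ... When `config` is missing, forwarded to [simConfig()].
#' @return List with `reference` and `test` ([BinCounts-class]), `bins`,
#'   `truth` (`data.frame`: sample_id, cohort, fetal_fraction_percent,
#'   gc_percent, label_chr13/18/21), and `config`.
#' @export
simulateCohort <- function(config = NULL, ...) {
  if (is.null(config)) config <- simConfig(...)
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  sizes <- round(hg19AutosomeLengths() / config$scaleFactor)
  bins <- makeBins(sizes, config$binSize)
  mcols(bins)$gc <- simulateGcProfile(length(bins))
  nBins <- length(bins)
  sizeVec <- rep(config$dispersion, nBins)
  nNoisy <- round(config$noisyBinFraction * nBins)
  if (nNoisy > 0) {
    noisy <- sample.int(nBins, nNoisy)
    sizeVec[noisy] <- config$dispersion / config$noisyBinInflation
  }
  baseRates <- expectedBinRates(bins, config$gcBiasAmplitude,
                                config$gcOptimum)
  drawSample <- function(rates) {
    stats::rnbinom(nBins, mu = config$readsPerSample * rates, size = sizeVec)
  }
  nAll <- config$nReference + config$nTest
  ffs <- pmin(pmax(stats::rnorm(nAll, config$ffMeanPercent,
                                config$ffSdPercent), 1), 25)
  refIds <- sprintf("REF%03d", seq_len(config$nReference))
  testIds <- sprintf("TEST%03d", seq_len(config$nTest))
  labels <- matrix(0L, nrow = nAll, ncol = 3,
                   dimnames = list(c(refIds, testIds),
                                   c("chr13", "chr18", "chr21")))
  ts <- config$trisomySpecs
  if (!is.null(ts)) {
    for (i in seq_len(nrow(ts))) {
      row <- config$nReference + ts$sample[i]
      labels[row, ts$chrom[i]] <- 1L
      ffs[row] <- 100 * ts$ff[i]
    }
  }
  refMat <- matrix(0, config$nReference, nBins, dimnames = list(refIds, NULL))
  for (s in seq_len(config$nReference)) refMat[s, ] <- drawSample(baseRates)
  testMat <- matrix(0, config$nTest, nBins, dimnames = list(testIds, NULL))
  for (s in seq_len(config$nTest)) {
    lifted <- labels[config$nReference + s, ]
    rates <- baseRates
    if (any(lifted == 1L)) {
      tc <- names(lifted)[lifted == 1L]
      ff <- ffs[config$nReference + s] / 100
      for (ch in tc) {
        on <- as.logical(seqnames(bins) == ch)
        rates[on] <- rates[on] * (1 + ff / 2)
      }
      rates <- rates / sum(rates)
    }
    testMat[s, ] <- drawSample(rates)
  }
  gcv <- mcols(bins)$gc
  allMat <- rbind(refMat, testMat)
  gcPct <- 100 * as.numeric(allMat %*% gcv) / rowSums(allMat)
  truth <- data.frame(sample_id = c(refIds, testIds),
                      cohort = rep(c("reference", "test"),
                                   c(config$nReference, config$nTest)),
                      fetal_fraction_percent = ffs,
                      gc_percent = gcPct,
                      label_chr13 = labels[, "chr13"],
                      label_chr18 = labels[, "chr18"],
                      label_chr21 = labels[, "chr21"])
  rownames(truth) <- NULL
  list(reference = BinCounts(bins, refMat, stage = "raw"),
       test = if (config$nTest > 0) BinCounts(bins, testMat, stage = "raw"),
       bins = bins, truth = truth, config = config)
}

## long-format truth labels for the three target chromosomes of one cohort
truthLabels <- function(truth, cohort = "test") {
  tr <- truth[truth$cohort == cohort, , drop = FALSE]
  do.call(rbind, lapply(c("chr13", "chr18", "chr21"), function(ch) {
    data.frame(sample_id = tr$sample_id, chrom = ch,
               label = tr[[paste0("label_", ch)]])
  }))
}

#' End-to-end recovery harness on a simulated cohort
#'
#' Simulates a cohort, fits the reference model, scores the test samples,
#' makes Z-based calls per method, runs the LOOCV logistic ensemble, and
#' compares everything against the simulation truth.
#'
#' @param config A [simConfig()]; defaults to a 30-reference / 30-test cohort
#'   with 10 trisomic samples at fetal fraction 15%
#'   ([defaultTrisomySpecs()]).
#' @param zCutoff Z call cutoff (default 3.0).
#' @param probThreshold Ensemble probability threshold (default 0.5).
#' @param featureNames Ensemble features (default the three Z-scores).
#' @param ... Arguments forwarded to [fitReferenceModel()].
#' @return List with `zTable`, per-method `zConfusion`, `features`,
#'   out-of-fold `probs`, `ensembleConfusion`, `auc`, `truth`, and the fitted
#'   `model`.
#' @export
endToEndRecovery <- function(config = NULL, zCutoff = 3.0,
                             probThreshold = 0.5,
                             featureNames = c("z_std", "z_ncv", "z_wsrb"),
                             ...) {
  if (is.null(config))
    config <- simConfig(nReference = 30, nTest = 30,
                        trisomySpecs = defaultTrisomySpecs(10, 0.15))
  sim <- simulateCohort(config)
  model <- fitReferenceModel(sim$reference, ...)
  zTable <- scoreSamples(model, sim$test)
  labels <- truthLabels(sim$truth, "test")
  calls <- zCalls(zTable, zCutoff)
  merged <- merge(calls, labels, by = c("sample_id", "chrom"))
  zConfusion <- lapply(split(merged, merged$method), function(d)
    confusionFromCalls(d$call, d$label))
  info <- sim$truth[sim$truth$cohort == "test",
                    c("sample_id", "gc_percent", "fetal_fraction_percent")]
  features <- makeFeatureTable(zTable, sampleInfo = info, labels = labels)
  probs <- loocv(features, featureNames)
  ensembleConfusion <- confusionFromCalls(classifyProb(probs, probThreshold),
                                          features$label)
  list(zTable = zTable, zConfusion = zConfusion, features = features,
       probs = probs, ensembleConfusion = ensembleConfusion,
       auc = rocAuc(probs, features$label), truth = sim$truth, model = model)
}
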