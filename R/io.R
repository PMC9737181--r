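## gzip-transparent fread (no extra runtime dependency for .gz input)
freadAuto <- function(path, ...) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    data.table::fread(text = readLines(con), ...)
  } else {
    data.table::fread(path, ...)
  }
}

#' Read and write bin grids as BED4
#'
#' Columns: chrom, start (0-based), end (exclusive), gc (fraction; `.` for
#' missing). Rows must be sorted by (chrom, start) and non-overlapping;
#' violations are rejected with the offending line number.
#'
#' @param bins Bin grid.
#' @param path File path (gzip-transparent on read; use a `.gz` suffix to
#'   compress on write).
#' @return `readBinsBed`: a `GRanges`; `writeBinsBed`: `path`, invisibly.
#' @export
writeBinsBed <- function(bins, path) {
  dt <- data.table::data.table(
    chrom = as.character(seqnames(bins)),
    start = start(bins) - 1L, end = end(bins),
    gc = ifelse(is.na(mcols(bins)$gc), ".",
                format(mcols(bins)$gc, digits = 15, trim = TRUE)))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE,
                     compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' @rdname writeBinsBed
#' @export
readBinsBed <- function(path) {
  dt <- freadAuto(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "gc"),
                          colClasses = list(character = c(1, 4)))
  bad <- which(dt$end <= dt$start)
  if (length(bad)) stop("BED line ", bad[1], ": end <= start")
  for (ch in unique(dt$chrom)) {
    idx <- which(dt$chrom == ch)
    if (is.unsorted(dt$start[idx]))
      stop("BED line ", idx[which(diff(dt$start[idx]) <= 0)[1] + 1L],
           ": bins not sorted by start")
    if (any(dt$start[idx][-1] < dt$end[idx][-length(idx)]))
      stop("BED: overlapping bins on ", ch)
  }
  chroms <- unique(dt$chrom)
  lens <- vapply(chroms, function(ch) max(dt$end[dt$chrom == ch]), numeric(1))
  bins <- GRanges(factor(dt$chrom, levels = chroms),
                  IRanges(dt$start + 1L, dt$end))
  GenomeInfoDb::seqlengths(bins) <- lens
  mcols(bins)$gc <- suppressWarnings(as.numeric(ifelse(dt$gc == ".",
                                                       NA, dt$gc)))
  names(bins) <- binIds(bins)
  bins
}

#' Read and write count matrices as TSV
#'
#' First column `sample_id`, remaining columns one per bin with canonical ids
#' `"chrom:start-end"`. Gzip-transparent.
#'
#' @param x A [BinCounts-class] object.
#' @param path File path.
#' @param bins Optional grid to validate/attach; when `NULL`, a grid is
#'   reconstructed from the column ids (without GC).
#' @param stage Stage to record on the object read back (default `"raw"`).
#' @return `readCountsTsv`: a [BinCounts-class]; `writeCountsTsv`: `path`,
#'   invisibly.
#' @export
writeCountsTsv <- function(x, path) {
  dt <- data.table::data.table(sample_id = rownames(counts(x)), counts(x))
  data.table::fwrite(dt, path, sep = "\t",
                     compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' @rdname writeCountsTsv
#' @export
readCountsTsv <- function(path, bins = NULL,
                          stage = c("raw", "gc_corrected", "vr_corrected")) {
  stage <- match.arg(stage)
  dt <- freadAuto(path, sep = "\t", header = TRUE)
  if (names(dt)[1] != "sample_id") stop("first column must be sample_id")
  ids <- dt$sample_id
  if (anyDuplicated(ids)) stop("duplicate sample ids: ",
                               ids[duplicated(ids)][1])
  mat <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(dt[, -1], is.numeric, logical(1)))[1]
    stop("non-numeric counts in column ", names(dt)[-1][bad])
  }
  rownames(mat) <- ids
  if (is.null(bins)) {
    m <- regmatches(colnames(mat),
                    regexec("^(.+):([0-9]+)-([0-9]+)$", colnames(mat)))
    if (any(lengths(m) != 4)) stop("malformed bin id column name")
    chrom <- vapply(m, `[`, "", 2)
    st <- as.integer(vapply(m, `[`, "", 3))
    en <- as.integer(vapply(m, `[`, "", 4))
    bins <- GRanges(factor(chrom, levels = unique(chrom)),
                    IRanges(st + 1L, en))
    mcols(bins)$gc <- NA_real_
    names(bins) <- binIds(bins)
  } else if (!identical(colnames(mat), binIds(bins))) {
    stop("count columns do not match the bin grid")
  }
  BinCounts(bins, mat, stage = stage)
}

#' Read and write sample metadata / truth tables as TSV
#'
#' Expected columns: `sample_id`, plus any of `cohort`,
#' `fetal_fraction_percent`, `gc_percent`, `label_chr13`, `label_chr18`,
#' `label_chr21`.
#'
#' @param df `data.frame` to write.
#' @param path File path.
#' @return `readSampleInfoTsv`: a `data.frame`.
#' @export
writeSampleInfoTsv <- function(df, path) {
  data.table::fwrite(data.table::as.data.table(df), path, sep = "\t")
  invisible(path)
}

#' @rdname writeSampleInfoTsv
#' @export
readSampleInfoTsv <- function(path) {
  df <- as.data.frame(freadAuto(path, sep = "\t", header = TRUE))
  if (!"sample_id" %in% names(df)) stop("metadata must have a sample_id column")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in metadata")
  df
}

#' Read and write tidy Z-score tables as TSV
#'
#' Columns: `sample_id`, `chrom`, `method`, `z`, and optionally `call`.
#'
#' @param zTable Tidy Z table ([scoreSamples()]).
#' @param path File path.
#' @return `readZScoreTable`: a `data.frame`.
#' @export
writeZScoreTable <- function(zTable, path) {
  data.table::fwrite(data.table::as.data.table(zTable), path, sep = "\t")
  invisible(path)
}

#' @rdname writeZScoreTable
#' @export
readZScoreTable <- function(path) {
  df <- as.data.frame(freadAuto(path, sep = "\t", header = TRUE))
  need <- c("sample_id", "chrom", "method", "z")
  if (!all(need %in% names(df)))
    stop("Z table must have columns: ", paste(need, collapse = ", "))
  df
}

#' Write a metrics table (one row per method/model)
#'
#' Metrics are rounded half-up to 3 decimals, matching the reporting
#' convention of screening-performance tables.
#'
#' @param summaries Named list of [ConfusionSummary-class] objects.
#' @param path File path.
#' @export
writeMetricsTsv <- function(summaries, path) {
  rows <- lapply(names(summaries), function(nm) {
    s <- summaries[[nm]]
    cbind(data.frame(method = nm), as.data.frame(s))
  })
  df <- do.call(rbind, rows)
  for (col in c("accuracy", "sensitivity", "specificity", "ppv", "npv"))
    df[[col]] <- roundHalfUp(df[[col]], 3)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

## ---- model bundle (versioned JSON) -----------------------------------------

#' Serialize / restore a fitted reference model
#'
#' One self-describing, versioned JSON bundle holding the bin grid, the
#' preprocessing state and all per-method statistics, sufficient to score new
#' samples reproducibly.
#'
#' @param model A [ReferenceModel-class].
#' @param path File path (`.json`).
#' @return `readModelBundle`: a [ReferenceModel-class].
#' @export
writeModelBundle <- function(model, path) {
  gw <- model@gcParams$groupWeights
  payload <- list(
    format = model@version,
    bins = list(chrom = as.character(seqnames(model@bins)),
                start = start(model@bins) - 1L, end = end(model@bins),
                gc = mcols(model@bins)$gc),
    seqlevels = GenomeInfoDb::seqlevels(model@bins),
    scored = model@scored,
    strata = model@strata,
    gcParams = list(method = model@gcParams$method,
                    scope = model@gcParams$scope,
                    stratumWidth = model@gcParams$stratumWidth,
                    minBinsPerStratum = model@gcParams$minBinsPerStratum,
                    groupWeightNames = names(gw),
                    groupWeights = unname(gw)),
    vrWeights = model@vrWeights, chiCutoff = model@chiCutoff,
    normTarget = model@normTarget, targets = model@targets,
    std = model@std,
    ncv = model@ncv,
    wsrb = lapply(model@wsrb, function(w)
      list(binIndex = w$binIndex, neighbors = w$neighbors,
           bMu = w$bMu, bSigma = w$bSigma, sMu = w$sMu, sSd = w$sSd)),
    nRef = model@nRef)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname writeModelBundle
#' @export
readModelBundle <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "aneuscreen-reference-1"))
    stop("unrecognized model bundle format: ", p$format)
  bins <- GRanges(factor(p$bins$chrom, levels = p$seqlevels),
                  IRanges(p$bins$start + 1L, p$bins$end))
  mcols(bins)$gc <- as.numeric(p$bins$gc)
  names(bins) <- binIds(bins)
  gw <- NULL
  if (length(p$gcParams$groupWeights)) {
    gw <- as.numeric(p$gcParams$groupWeights)
    names(gw) <- p$gcParams$groupWeightNames
  }
  asTargetList <- function(x, fields) {
    out <- lapply(x, function(e) {
      e <- as.list(e)
      e[fields]
    })
    out
  }
  wsrb <- lapply(p$wsrb, function(w) {
    nbr <- w$neighbors
    ## equal-length neighbor vectors come back simplified to a matrix
    nbr <- if (is.matrix(nbr)) lapply(seq_len(nrow(nbr)),
                                      function(i) as.integer(nbr[i, ]))
           else lapply(nbr, as.integer)
    list(binIndex = as.integer(w$binIndex), neighbors = nbr,
         bMu = as.numeric(w$bMu), bSigma = as.numeric(w$bSigma),
         sMu = w$sMu, sSd = w$sSd)
  })
  new("ReferenceModel",
      version = p$format, bins = bins, scored = as.logical(p$scored),
      strata = as.integer(p$strata),
      gcParams = list(method = p$gcParams$method, scope = p$gcParams$scope,
                      stratumWidth = p$gcParams$stratumWidth,
                      minBinsPerStratum = p$gcParams$minBinsPerStratum,
                      groupWeights = gw),
      vrWeights = as.numeric(p$vrWeights), chiCutoff = p$chiCutoff,
      normTarget = p$normTarget, targets = p$targets,
      std = asTargetList(p$std, c("mu", "sigma")),
      ncv = lapply(p$ncv, function(e) list(denomSet = as.character(e$denomSet),
                                           rMu = e$rMu, rSigma = e$rSigma,
                                           cv = e$cv)),
      wsrb = wsrb, nRef = as.integer(p$nRef))
}

## ---- run configuration ------------------------------------------------------

#' Default pipeline run configuration
#'
#' Every stage parameter with a published value defaults to it: 50 kb bins,
#' MAPQ >= 30, chi-squared cutoff quantile 0.9999, at most 9 NCV denominator
#' chromosomes, 100 WSRB neighbors, Z cutoff 3.0 and probability threshold
#' 0.5.
#'
#' @return Named list of parameters.
#' @export
defaultRunConfig <- function() {
  list(bin_size = 50000, mapq_min = 30, gc_method = "strata",
       gc_scope = "sample", stratum_width = 0.01, min_bins_per_stratum = 50,
       chi_cutoff_quantile = 0.9999, max_denoms = 9, ncv_strategy = "greedy",
       k_neighbors = 100, sd_floor = 1e-10, z_cutoff = 3.0,
       prob_threshold = 0.5, feature_set = "3-param", seed = 1)
}

#' Read / write a run configuration (YAML)
#'
#' @param config Named list of parameters (see [defaultRunConfig()]).
#' @param path File path.
#' @return `readRunConfig`: named list merged over the defaults.
#' @export
writeRunConfig <- function(config, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required for config files")
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required for config files")
  user <- yaml::read_yaml(path)
  cfg <- defaultRunConfig()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  cfg
}
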