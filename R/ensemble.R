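## IRLS for binary logistic regression; lambda is an optional ridge penalty
## on the non-intercept coefficients (used when separation is detected).
irlsLogistic <- function(X, y, lambda = 0, maxIter = 100, tol = 1e-8) {
  p <- ncol(X)
  beta <- rep(0, p)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(maxIter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    fit <- tryCatch(
      solve(crossprod(X, w * X) + pen, crossprod(X, w * z)),
      error = function(e) NULL)
    if (is.null(fit)) return(list(beta = beta, iterations = it,
                                  converged = FALSE, singular = TRUE))
    betaNew <- drop(fit)
    delta <- max(abs(betaNew - beta))
    beta <- betaNew
    if (!all(is.finite(beta))) return(list(beta = beta, iterations = it,
                                           converged = FALSE, singular = TRUE))
    if (delta < tol) { converged <- TRUE; break }
  }
  list(beta = beta, iterations = it, converged = converged, singular = FALSE)
}

logisticLogLik <- function(X, y, beta) {
  eta <- drop(X %*% beta)
  sum(y * eta - log1p(exp(eta)))
}

#' Fit the logistic ensemble model
#'
#' Maximum-likelihood binary logistic regression by iteratively reweighted
#' least squares (convergence when the largest coefficient update is below
#' `1e-8`, at most 100 iterations). Complete or quasi-separation — divergence
#' of the coefficient norm or failure to converge — is detected and handled
#' by refitting with a tiny ridge penalty (`ridge`, default `1e-6`) on the
#' non-intercept coefficients; the returned model is then flagged
#' `converged = FALSE`.
#'
#' @param features `data.frame` (or matrix) of feature columns.
#' @param labels 0/1 vector, 1 = trisomy.
#' @param featureNames Columns of `features` to use (default: all columns).
#' @param ridge Ridge penalty used for the separation fallback.
#' @return An [EnsembleModel-class].
#' @export
fitLogistic <- function(features, labels, featureNames = NULL,
                        ridge = 1e-6) {
  features <- as.data.frame(features)
  if (is.null(featureNames)) featureNames <- colnames(features)
  X <- as.matrix(features[, featureNames, drop = FALSE])
  storage.mode(X) <- "double"
  y <- as.numeric(labels)
  if (anyNA(X) || any(!is.finite(X))) stop("features must be finite")
  if (length(unique(y)) < 2L) stop("labels contain a single class")
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1")
  const <- apply(X, 2L, function(v) max(v) - min(v) == 0)
  if (any(const)) stop("constant feature column(s): ",
                       paste(featureNames[const], collapse = ", "))
  Xd <- cbind("(Intercept)" = 1, X)
  fit <- irlsLogistic(Xd, y, lambda = 0)
  separated <- !fit$converged || fit$singular || max(abs(fit$beta)) > 1e3
  if (separated) fit <- irlsLogistic(Xd, y, lambda = ridge)
  beta <- fit$beta
  names(beta) <- colnames(Xd)
  new("EnsembleModel", beta = beta, featureNames = featureNames,
      converged = !separated, iterations = as.integer(fit$iterations),
      logLik = logisticLogLik(Xd, y, beta))
}

#' Predicted trisomy probability from the ensemble model
#'
#' @param model An [EnsembleModel-class].
#' @param features `data.frame`/matrix containing the model's feature
#'   columns (one row per decision).
#' @return Numeric probabilities in (0, 1).
#' @export
predictProb <- function(model, features) {
  features <- as.data.frame(features)
  X <- as.matrix(features[, model@featureNames, drop = FALSE])
  storage.mode(X) <- "double"
  if (anyNA(X) || any(!is.finite(X))) stop("features must be finite")
  drop(stats::plogis(cbind(1, X) %*% model@beta))
}

#' Classification rule on ensemble probabilities
#'
#' A decision is called trisomy when its probability strictly exceeds the
#' threshold (default 0.5); `p = 0.5` exactly calls normal.
#'
#' @param p Probabilities.
#' @param threshold Probability threshold (default 0.5, strict `>`).
#' @return Character vector `"trisomy"`/`"normal"`.
#' @export
classifyProb <- function(p, threshold = 0.5) {
  ifelse(p > threshold, "trisomy", "normal")
}

#' Leave-one-out cross-validated ensemble probabilities
#'
#' Folds are defined by `sample_id`: all target-chromosome rows of the
#' held-out sample are predicted together by a model fitted on the rows of
#' every other sample. Deterministic; output order matches input rows.
#'
#' @param features `data.frame` with a `sample_id` column, a 0/1 `label`
#'   column, and the feature columns.
#' @param featureNames Feature columns to use.
#' @param ridge Ridge penalty for separation handling (see [fitLogistic()]).
#' @return Numeric vector of out-of-fold probabilities, one per row.
#' @export
loocv <- function(features, featureNames, ridge = 1e-6) {
  stopifnot(is.data.frame(features), "sample_id" %in% names(features),
            "label" %in% names(features))
  ids <- unique(features$sample_id)
  if (length(ids) < 3L) stop("need at least 3 samples for LOOCV")
  out <- rep(NA_real_, nrow(features))
  for (sid in ids) {
    held <- features$sample_id == sid
    train <- features[!held, , drop = FALSE]
    if (length(unique(train$label)) < 2L)
      stop("fold '", sid, "': training labels are single-class")
    m <- fitLogistic(train, train$label, featureNames, ridge = ridge)
    out[held] <- predictProb(m, features[held, , drop = FALSE])
  }
  out
}

#' Confusion counts and screening metrics
#'
#' Builds a [ConfusionSummary-class] from true/false positive/negative
#' counts. Metrics follow the usual closed forms; a metric whose denominator
#' is zero is reported as `NA` (undefined), never as 0.
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return A [ConfusionSummary-class].
#' @examples
#' confusionMetrics(36, 11, 278, 2)
#' @export
confusionMetrics <- function(tp, fp, tn, fn) {
  v <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (anyNA(v) || any(v < 0) || any(abs(v - round(v)) > 0))
    stop("tp, fp, tn, fn must be non-negative integers")
  new("ConfusionSummary", tp = as.integer(tp), fp = as.integer(fp),
      tn = as.integer(tn), fn = as.integer(fn))
}

#' @describeIn confusionMetrics Named metric vector (accuracy, sensitivity,
#'   specificity, ppv, npv) at full precision.
#' @param x A [ConfusionSummary-class].
#' @export
confusionStats <- function(x) {
  tp <- x@tp; fp <- x@fp; tn <- x@tn; fn <- x@fn
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  c(accuracy = frac(tp + tn, tp + fp + tn + fn),
    sensitivity = frac(tp, tp + fn),
    specificity = frac(tn, tn + fp),
    ppv = frac(tp, tp + fp),
    npv = frac(tn, tn + fn))
}

#' Confusion counts from calls and truth labels
#'
#' @param call Character vector of calls (`"trisomy"`/`"normal"`) or logical.
#' @param truth 0/1 (or logical) truth labels, 1 = trisomy.
#' @return A [ConfusionSummary-class].
#' @export
confusionFromCalls <- function(call, truth) {
  pos <- if (is.logical(call)) call else call == "trisomy"
  y <- as.logical(as.numeric(truth))
  confusionMetrics(sum(pos & y), sum(pos & !y), sum(!pos & !y), sum(!pos & y))
}

#' Area under the ROC curve
#'
#' Rank-statistic (Mann-Whitney) AUC: the probability that a random positive
#' scores above a random negative, with ties counted 1/2.
#'
#' @param probs Numeric scores or probabilities.
#' @param labels 0/1 labels.
#' @return AUC in \[0, 1\].
#' @export
rocAuc <- function(probs, labels) {
  y <- as.numeric(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(probs)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' @param probs Numeric scores.
#' @param labels 0/1 labels.
#' @return `data.frame` of (threshold, fpr, tpr), thresholds descending.
#' @export
rocPoints <- function(probs, labels) {
  y <- as.numeric(labels)
  th <- c(Inf, sort(unique(probs), decreasing = TRUE))
  pts <- t(vapply(th, function(t) {
    pos <- probs >= t
    c(fpr = sum(pos & y == 0) / sum(y == 0),
      tpr = sum(pos & y == 1) / sum(y == 1))
  }, numeric(2)))
  data.frame(threshold = th, fpr = pts[, "fpr"], tpr = pts[, "tpr"])
}

#' Pearson correlation of Z-scores with a covariate within a truth group
#'
#' Used for the diagnostic plots relating Z-scores to sample GC percent or
#' fetal fraction, computed separately in the euploid and trisomic groups.
#'
#' @param z Z values of the group rows.
#' @param covariate Covariate values (same length).
#' @return List with `r` (Pearson correlation) and `p` (two-sided t-test
#'   p-value).
#' @export
correlateScores <- function(z, covariate) {
  if (length(z) < 3L) stop("need at least 3 observations")
  if (stats::sd(z) == 0 || stats::sd(covariate) == 0)
    stop("zero variance in z or covariate")
  ct <- stats::cor.test(covariate, z)
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Assemble the ensemble feature table
#'
#' Pivots a tidy Z table to one row per (sample, target chromosome) with
#' columns `z_std`, `z_ncv`, `z_wsrb`, joins optional sample-level covariates
#' (GC percent, fetal fraction percent), and attaches 0/1 truth labels.
#'
#' @param zTable Tidy Z table from [scoreSamples()].
#' @param sampleInfo Optional `data.frame` with `sample_id`, `gc_percent`,
#'   `fetal_fraction_percent`.
#' @param labels Optional `data.frame` with `sample_id`, `chrom`, `label`.
#' @return `data.frame` feature table.
#' @export
makeFeatureTable <- function(zTable, sampleInfo = NULL, labels = NULL) {
  dt <- data.table::as.data.table(zTable)
  wide <- data.table::dcast(dt, sample_id + chrom ~ method, value.var = "z")
  data.table::setnames(wide, c("STD", "NCV", "WSRB"),
                       c("z_std", "z_ncv", "z_wsrb"))
  if (!is.null(sampleInfo))
    wide <- merge(wide, data.table::as.data.table(sampleInfo),
                  by = "sample_id", sort = FALSE)
  if (!is.null(labels))
    wide <- merge(wide, data.table::as.data.table(labels),
                  by = c("sample_id", "chrom"), sort = FALSE)
  out <- as.data.frame(wide)
  out <- out[order(out$sample_id, chromNumber(out$chrom)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
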