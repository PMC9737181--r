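test_that("IRLS logistic fit matches a grid-search likelihood maximization", {
  toy <- logisticToy()
  m <- fitLogistic(toy["x"], toy$y)
  expect_true(m@converged)
  best <- gridLogistic(toy$x, toy$y)
  expect_equal(unname(m@beta), best, tolerance = 5e-4)
  ## and agrees with the standard GLM fit
  g <- glm(y ~ x, data = toy, family = binomial())
  expect_equal(unname(m@beta), unname(coef(g)), tolerance = 1e-6)
})

test_that("separation is flagged and the symmetric toy keeps a zero intercept", {
  d <- data.frame(x = rep(c(-1, 1), 4), y = rep(c(0, 1), 4))
  m <- fitLogistic(d["x"], d$y)
  expect_false(m@converged)
  expect_equal(unname(m@beta[1]), 0, tolerance = 1e-6)
  expect_gt(unname(m@beta[2]), 1)
})

test_that("opposite-label duplicates at one point pull its probability to 0.5", {
  toy <- logisticToy()
  m1 <- fitLogistic(toy["x"], toy$y)
  p1 <- predictProb(m1, data.frame(x = 2))
  toy2 <- rbind(toy, data.frame(x = c(2, 2), y = c(0, 1)))
  m2 <- fitLogistic(toy2["x"], toy2$y)
  p2 <- predictProb(m2, data.frame(x = 2))
  expect_lt(abs(p2 - 0.5), abs(p1 - 0.5))
})

test_that("predicted probabilities follow the logistic closed form", {
  m <- new("EnsembleModel", beta = c("(Intercept)" = 0, x1 = 1, x2 = 0,
                                     x3 = 0),
           featureNames = c("x1", "x2", "x3"), converged = TRUE,
           iterations = 1L, logLik = 0)
  p <- predictProb(m, data.frame(x1 = log(3), x2 = 5, x3 = -2))
  expect_equal(p, 0.75)
  p0 <- predictProb(new("EnsembleModel",
                        beta = c("(Intercept)" = 0, x1 = 0, x2 = 0, x3 = 0),
                        featureNames = c("x1", "x2", "x3"), converged = TRUE,
                        iterations = 1L, logLik = 0),
                    data.frame(x1 = 0, x2 = 0, x3 = 0))
  expect_equal(p0, 0.5)
  expect_equal(classifyProb(p0), "normal")          # strict > 0.5
  expect_equal(classifyProb(0.5 + 1e-9), "trisomy")
  expect_error(predictProb(m, data.frame(x1 = Inf, x2 = 0, x3 = 0)),
               "finite")
})

test_that("logistic preconditions are enforced", {
  toy <- logisticToy()
  expect_error(fitLogistic(toy["x"], rep(0, 8)), "single class")
  toy$c <- 1
  expect_error(fitLogistic(toy[c("x", "c")], toy$y), "constant")
})

test_that("LOOCV probabilities equal independent per-fold GLM refits", {
  d <- loocvFixture()
  p <- loocv(d, c("f1", "f2"))
  for (sid in unique(d$sample_id)) {
    train <- d[d$sample_id != sid, ]
    g <- suppressWarnings(glm(label ~ f1 + f2, data = train,
                              family = binomial()))
    expected <- predict(g, d[d$sample_id == sid, ], type = "response")
    expect_equal(unname(p[d$sample_id == sid]), unname(expected),
                 tolerance = 1e-6)
  }
})

test_that("LOOCV is order-equivariant, leak-free, and names single-class folds", {
  d <- loocvFixture()
  p <- loocv(d, c("f1", "f2"))
  perm <- sample(nrow(d))
  expect_equal(loocv(d[perm, ], c("f1", "f2")), p[perm])

  ## flipping only the held-out rows' labels cannot change their own fold
  d2 <- d
  d2$label[d2$sample_id == "S03"] <- 1 - d2$label[d2$sample_id == "S03"]
  p2 <- loocv(d2, c("f1", "f2"))
  expect_equal(p2[d$sample_id == "S03"], p[d$sample_id == "S03"])

  dBad <- d[d$sample_id %in% c("S01", "S02", "S03"), ]
  dBad$label <- c(0, 1, 0, 0, 0, 0)     # dropping S01 leaves one class
  expect_error(loocv(dBad, c("f1", "f2")), "fold 'S01'")
})

test_that("adding covariate features leaves the fold structure unchanged", {
  d <- loocvFixture()
  d$gc_percent <- rnorm(nrow(d), 41, 1)
  d$ff <- rnorm(nrow(d), 11, 3)
  p3 <- loocv(d, c("f1", "f2"))
  p5 <- loocv(d, c("f1", "f2", "gc_percent", "ff"))
  expect_length(p5, length(p3))       # same rows, same per-sample folds
})

test_that("confusion metrics follow their closed forms and handle 0/0", {
  cs <- confusionMetrics(1, 0, 1, 0)
  expect_equal(unname(confusionStats(cs)), rep(1, 5))
  s <- confusionStats(confusionMetrics(36, 11, 278, 2))
  expect_equal(unname(s["accuracy"]), (36 + 278) / 327)
  expect_equal(unname(s["sensitivity"]), 36 / 38)
  ## sensitivity * (tp+fn) = tp exactly; accuracy is the prevalence-weighted
  ## combination of sensitivity and specificity
  set.seed(31)
  for (i in 1:20) {
    v <- sample(0:40, 4, replace = TRUE)
    if (v[1] + v[4] == 0 || v[2] + v[3] == 0) next
    st <- confusionStats(confusionMetrics(v[1], v[2], v[3], v[4]))
    expect_equal(st[["sensitivity"]] * (v[1] + v[4]), v[1])
    prev <- (v[1] + v[4]) / sum(v)
    expect_equal(st[["accuracy"]],
                 prev * st[["sensitivity"]] + (1 - prev) * st[["specificity"]])
  }
  und <- confusionStats(confusionMetrics(0, 0, 5, 2))
  expect_true(is.na(und["ppv"]))       # undefined, not zero
  expect_error(confusionMetrics(-1, 0, 0, 0), "non-negative")
})

test_that("rank AUC matches exhaustive pair counting and pROC", {
  probs <- c(0.1, 0.4, 0.35, 0.8)
  labels <- c(0, 0, 1, 1)
  pairs <- expand.grid(pos = probs[labels == 1], neg = probs[labels == 0])
  expected <- mean(ifelse(pairs$pos > pairs$neg, 1,
                          ifelse(pairs$pos == pairs$neg, 0.5, 0)))
  expect_equal(rocAuc(probs, labels), expected)
  expect_equal(expected, 0.75)
  expect_equal(rocAuc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(rocAuc(rep(0.5, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(rocAuc(probs, c(1, 1, 1, 1)), "both classes")
  skip_if_not_installed("pROC")
  set.seed(41)
  p <- runif(40); y <- rbinom(40, 1, p)
  if (length(unique(y)) == 2) {
    ref <- as.numeric(suppressMessages(pROC::auc(y, p)))
    expect_equal(rocAuc(p, y), ref)
  }
})

test_that("score-covariate correlation matches the textbook formula", {
  z <- c(1.2, 2.5, 0.3, 4.1, 3.3)
  cv <- c(8, 11, 6, 14, 12)
  res <- correlateScores(z, cv)
  num <- sum((z - mean(z)) * (cv - mean(cv)))
  den <- sqrt(sum((z - mean(z))^2) * sum((cv - mean(cv))^2))
  expect_equal(res$r, num / den)
  tstat <- res$r * sqrt(3 / (1 - res$r^2))
  expect_equal(res$p, 2 * pt(-abs(tstat), df = 3))
  expect_equal(correlateScores(z, z)$r, 1)
  expect_error(correlateScores(rep(1, 5), cv), "zero variance")
})

test_that("the feature table pivots z rows and joins covariates and labels", {
  zt <- data.frame(sample_id = rep(c("A", "B"), each = 6),
                   chrom = rep(rep(c("chr13", "chr21"), each = 3), 2),
                   method = rep(c("STD", "NCV", "WSRB"), 4),
                   z = 1:12)
  info <- data.frame(sample_id = c("A", "B"), gc_percent = c(41, 42),
                     fetal_fraction_percent = c(10, 12))
  lab <- data.frame(sample_id = rep(c("A", "B"), each = 2),
                    chrom = rep(c("chr13", "chr21"), 2),
                    label = c(0, 1, 0, 0))
  ft <- makeFeatureTable(zt, info, lab)
  expect_equal(nrow(ft), 4)
  expect_equal(ft$z_std[ft$sample_id == "A" & ft$chrom == "chr13"], 1)
  expect_equal(ft$z_wsrb[ft$sample_id == "B" & ft$chrom == "chr21"], 12)
  expect_equal(ft$label[ft$sample_id == "A" & ft$chrom == "chr21"], 1)
  expect_true(all(c("gc_percent", "fetal_fraction_percent") %in% names(ft)))
})
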