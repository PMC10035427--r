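test_that("splits are disjoint, exhaustive and deterministic", {
  labels <- rep(c(0L, 1L), each = 5L)
  sp <- splitSamples(labels, seed = 3L)
  expect_length(sp$test, 2L)           # round(0.2 * 10)
  expect_length(sp$train, 8L)
  expect_setequal(c(sp$train, sp$test), 1:10)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_identical(sp, splitSamples(labels, seed = 3L))
  expect_false(identical(sp$test, splitSamples(labels, seed = 4L)$test))
})

test_that("degenerate single-class training splits are redrawn", {
  # one positive among five: some seeds put it into the test set
  labels <- c(1L, 0L, 0L, 0L, 0L)
  hit <- FALSE
  for (s in 1:50) {
    set.seed(s)
    if (sample.int(5L, 1L) == 1L) {    # this seed would strip class 1
      expect_message(sp <- splitSamples(labels, seed = s), "redrawing")
      expect_true(1L %in% sp$train)
      hit <- TRUE
      break
    }
  }
  expect_true(hit)
})

test_that("the five confusion-matrix formulas are computed as printed", {
  # TP=3, FP=1, TN=4, FN=2
  labels <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  preds  <- c(1, 1, 1, 0, 0, 1, 0, 0, 0, 0)
  scores <- c(.9, .8, .7, .4, .3, .6, .2, .1, .2, .3)
  r <- computeMetrics(labels, preds, scores)
  expect_equal(r@confusion, c(TP = 3L, FP = 1L, TN = 4L, FN = 2L))
  expect_equal(r@acc, 0.7)
  expect_equal(r@sen, 0.6)
  expect_equal(r@spe, 0.8)
  expect_equal(r@pre, 0.75)
  expect_equal(r@f1, 2 * 3 / (2 * 3 + 1 + 2))
  expect_equal(r@f1, 2 / (1 / r@pre + 1 / r@sen))   # harmonic-mean identity
  expect_equal(r@sen * (3 + 2), 3)                  # Sen*(TP+FN) = TP
})

test_that("perfect and uninformative scores hit the AUC extremes", {
  labels <- c(1, 1, 1, 0, 0, 0)
  perfect <- computeMetrics(labels, labels, c(.9, .8, .7, .3, .2, .1))
  expect_equal(metricMeans(perfect), c(acc = 1, sen = 1, spe = 1,
                                       pre = 1, f1 = 1, auc = 1))
  tied <- computeMetrics(labels, labels, rep(0.4, 6))
  expect_equal(tied@auc, 0.5)
})

test_that("rank-based AUC equals the all-pairs oracle", {
  set.seed(50)
  for (rep in 1:25) {
    nSamp <- sample(4:20, 1)
    labels <- sample(c(0L, 1L), nSamp, replace = TRUE)
    if (length(unique(labels)) < 2L) next
    scores <- round(runif(nSamp), 2)    # rounding forces ties
    r <- computeMetrics(labels, as.integer(scores > 0.5), scores)
    expect_equal(r@auc, oracleAUC(labels, scores))
  }
})

test_that("zero-denominator metrics are reported as 0 and flagged", {
  # no positives predicted and none present: Sen, Pre, AUC degenerate
  r <- computeMetrics(c(0, 0, 0, 0), c(0, 0, 0, 0), c(.1, .2, .3, .4))
  expect_equal(r@sen, 0)
  expect_equal(r@pre, 0)
  expect_equal(r@auc, 0)
  expect_true(all(c("sen", "pre", "f1", "auc") %in% r@flags))
  expect_equal(r@acc, 1)               # all correct
})

test_that("repeated evaluation aggregates means and stds correctly", {
  coh <- tinyCohort()
  samples <- buildGraphSamples(coh, "pc", "CV")
  cfg <- trainConfig(embeddingDim = 4L, epochs = 5L)
  one <- runExperiment(samples, cfg, nRepeats = 1L, seed = 11L)
  expect_equal(unname(one$std), rep(0, 6))
  several <- runExperiment(samples, cfg, nRepeats = 4L, seed = 11L)
  expect_equal(unname(several$mean), unname(colMeans(several$perRepeat)),
               tolerance = 1e-12)
  popSd <- apply(several$perRepeat, 2,
                 function(x) sqrt(mean((x - mean(x))^2)))
  expect_equal(unname(several$std), unname(popSd), tolerance = 1e-12)
  again <- runExperiment(samples, cfg, nRepeats = 4L, seed = 11L)
  expect_identical(several$perRepeat, again$perRepeat)
})

test_that("a strong-effect cohort is classified above chance with CV", {
  spec <- cohortSpec(nRois = 12L, nTimepoints = 100L,
                     nSubjectsPerGroup = 8L,
                     effectBlock = roiBlockPairs(1:4),
                     effectDelta = 0.5, baseCorrelation = -0.25,
                     noiseSd = 0.2, seed = 8L)
  samples <- buildGraphSamples(sampleCohort(spec), "pc", "CV")
  res <- runExperiment(samples, trainConfig(embeddingDim = 8L,
                                            epochs = 300L),
                       nRepeats = 8L, seed = 21L)
  se <- res$std["acc"] / sqrt(res$nRepeats)
  expect_gt(res$mean[["acc"]], 0.5 + 3 * se)
})

test_that("the ablation grid has the twelve canonical rows and best flags", {
  rows <- defaultFeatureGrid()
  expect_identical(names(rows),
                   c("OS", "OH", "NS", "CV", "OS + OH", "OH + NS",
                     "OH + CV", "NS + CV", "OH + OS + NS", "OH + OS + CV",
                     "OS + NS + CV", "OH + OS + NS + CV"))
  coh <- tinyCohort()
  grid <- buildGrid(coh, "pc", rows,
                    cfg = trainConfig(embeddingDim = 4L, epochs = 3L),
                    nRepeats = 2L, seed = 1L)
  tab <- gridTable(grid)
  expect_equal(nrow(tab), 12L)
  expect_identical(tab$features, names(rows))
  expect_length(grid@best, 6L)
  for (m in names(grid@best)) {
    expect_identical(grid@best[[m]],
                     which.max(tab[[paste0(m, "_mean")]]))
  }
  expect_true(all(tab$acc_std >= 0))
})

test_that("grids survive a CSV round trip losslessly", {
  coh <- tinyCohort()
  grid <- buildGrid(coh, "pc", list(c("OH"), c("CV")),
                    cfg = trainConfig(embeddingDim = 4L, epochs = 3L),
                    nRepeats = 2L, seed = 2L)
  path <- tempfile(fileext = ".csv")
  writeGrid(grid, path)
  back <- readGrid(path)
  expect_equal(gridTable(back), gridTable(grid))
  expect_identical(back@nRepeats, grid@nRepeats)
  expect_identical(back@best, grid@best)
  md <- formatGridMarkdown(grid)
  expect_length(md, 2L + 2L)
  expect_true(any(grepl("\\*\\*", md)))
})
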