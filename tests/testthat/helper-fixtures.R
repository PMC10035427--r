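# Small fixtures assembled in code; nothing is read from disk.

tinySpec <- function(..., seed = 7L) {
  cohortSpec(nRois = 8L, nTimepoints = 40L, nSubjectsPerGroup = 4L,
             effectBlock = roiBlockPairs(1:3), effectDelta = 0.4,
             baseCorrelation = -0.2, noiseSd = 0.2, seed = seed, ...)
}

tinyCohort <- function(seed = 7L) sampleCohort(tinySpec(seed = seed))

randomTimeSeries <- function(n = 4L, m = 20L, seed = 1L) {
  set.seed(seed)
  roiTimeSeries(matrix(rnorm(n * m), n, m), subjectId = "random")
}

# a GraphSample built directly from matrices (bypasses the estimators)
manualSample <- function(raw, X, label = 0L, id = "manual",
                         estimator = "PC") {
  n <- nrow(raw)
  net <- new("BrainNetwork", raw = raw,
             normalized = normalizeAdjacency(raw), estimator = estimator,
             params = list(), roiIds = sprintf("ROI%03d", seq_len(n)),
             subjectId = id)
  nf <- new("NodeFeatures", values = X, featureSet = "CV",
            columnNames = sprintf("f%d", seq_len(ncol(X))))
  new("GraphSample", network = net, features = nf,
      label = as.integer(label), subjectId = id)
}

# linearly separable toy graphs: class mean shifts the features
separableSamples <- function(nPerClass = 10L, n = 5L, d = 4L, seed = 3L,
                            shift = 3) {
  set.seed(seed)
  out <- list()
  for (k in seq_len(2L * nPerClass)) {
    label <- as.integer(k > nPerClass)
    raw <- matrix(0, n, n)
    raw[upper.tri(raw)] <- runif(n * (n - 1) / 2, 0.2, 0.8)
    raw <- raw + t(raw)
    X <- matrix(rnorm(n * d, mean = label * shift, sd = 0.3), n, d)
    out[[k]] <- manualSample(raw, X, label, sprintf("toy-%02d", k))
  }
  out
}
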