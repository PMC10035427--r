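#' Original-signal node features (OS)
#'
#' Uses each ROI's raw time series as its feature vector, so d = m. These
#' signals carry the spontaneous-fluctuation information of each region.
#' Optional per-row z-scoring removes amplitude differences between ROIs.
#'
#' @param ts an [RoiTimeSeries-class].
#' @param zscore z-score every row to mean 0, sd 1.
#' @return a [NodeFeatures-class] with `featureSet = "OS"`.
#' @export
featuresOS <- function(ts, zscore = FALSE) {
  stopifnot(is(ts, "RoiTimeSeries"))
  v <- ts@values
  if (zscore) {
    mu <- rowMeans(v)
    sdv <- apply(v, 1L, stats::sd)
    sdv[sdv == 0] <- 1
    v <- (v - mu) / sdv
  }
  new("NodeFeatures", values = unname(v), featureSet = "OS",
      columnNames = sprintf("OS_t%03d", seq_len(ncol(v))))
}

#' One-hot node features (OH)
#'
#' The n x n identity matrix: each node's feature is an indicator that
#' uniquely identifies its position in the parcellation, carrying no
#' signal or connectivity information.
#'
#' @param n number of nodes.
#' @return a [NodeFeatures-class] with `featureSet = "OH"`.
#' @export
featuresOH <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  new("NodeFeatures", values = diag(n), featureSet = "OH",
      columnNames = sprintf("OH_roi%03d", seq_len(n)))
}

#' Node-statistic features (NS)
#'
#' The eight per-node graph statistics of [nodeStatistics()], d = 8.
#' Binary definitions are computed on the proportionally thresholded graph
#' (top `keepFraction` of absolute edge weights); weighted definitions on
#' the absolute edge weights themselves.
#'
#' @param net a [BrainNetwork-class].
#' @param keepFraction edge fraction kept when binarizing (see
#'   [binarizeAdjacency()]).
#' @return a [NodeFeatures-class] with `featureSet = "NS"`.
#' @export
featuresNS <- function(net, keepFraction = 0.3) {
  stopifnot(is(net, "BrainNetwork"))
  B <- binarizeAdjacency(net, keepFraction)
  vals <- nodeStatistics(B, abs(net@raw))
  new("NodeFeatures", values = unname(vals), featureSet = "NS",
      columnNames = colnames(vals))
}

#' Correlation-vector node features (CV)
#'
#' Each node's feature is its full row of the Pearson correlation matrix
#' (diagonal restored to 1), describing how the ROI relates to every other
#' ROI; d = n. Defined only for networks estimated by Pearson correlation.
#'
#' @param net a [BrainNetwork-class] with `estimator == "PC"`.
#' @return a [NodeFeatures-class] with `featureSet = "CV"`.
#' @export
featuresCV <- function(net) {
  stopifnot(is(net, "BrainNetwork"))
  if (net@estimator != "PC")
    stop("CV features are defined on the Pearson correlation matrix; ",
         "got a ", net@estimator, " network")
  v <- net@raw + diag(nrow(net@raw))
  new("NodeFeatures", values = unname(v), featureSet = "CV",
      columnNames = sprintf("CV_roi%03d", seq_len(ncol(v))))
}

#' Concatenate node-feature blocks
#'
#' Horizontally concatenates feature blocks for the same set of nodes,
#' always in the canonical order OS, OH, NS, CV regardless of the order
#' given. Duplicate block types and mismatched node counts are errors.
#'
#' @param blocks a list of [NodeFeatures-class] objects (a single object
#'   is returned unchanged).
#' @return a [NodeFeatures-class] with `d` the sum of the block widths.
#' @examples
#' coh <- sampleCohort(cohortSpec(nRois = 5, nTimepoints = 20,
#'                                nSubjectsPerGroup = 1))
#' net <- estimatePC(coh@subjects[[1]])
#' combineFeatures(list(featuresCV(net), featuresOH(5)))  # OH block first
#' @export
combineFeatures <- function(blocks) {
  if (is(blocks, "NodeFeatures")) return(blocks)
  stopifnot(is.list(blocks), length(blocks) >= 1L)
  if (length(blocks) == 1L) return(blocks[[1L]])
  blockSets <- lapply(blocks, featureSet)
  flat <- unlist(blockSets)
  if (anyDuplicated(flat))
    stop("duplicate feature blocks: ",
         paste(flat[duplicated(flat)], collapse = ", "))
  ns <- vapply(blocks, function(b) nrow(b@values), integer(1))
  if (length(unique(ns)) > 1L)
    stop("feature blocks disagree on the number of nodes: ",
         paste(ns, collapse = ", "))
  canon <- c("OS", "OH", "NS", "CV")
  ord <- order(vapply(blockSets, function(s) min(match(s, canon)),
                      numeric(1)))
  blocks <- blocks[ord]
  new("NodeFeatures",
      values = do.call(cbind, lapply(blocks, function(b) b@values)),
      featureSet = unlist(blockSets[ord]),
      columnNames = unlist(lapply(blocks, function(b) b@columnNames)))
}

#' Standardize feature columns across nodes
#'
#' Centers and scales every feature column over the nodes of the subject;
#' constant columns become zero. Recommended when concatenating blocks
#' that live on very different scales (raw signals vs statistics in
#' `[0, 1]`).
#'
#' @param nf a [NodeFeatures-class].
#' @return the standardized [NodeFeatures-class].
#' @export
standardizeFeatures <- function(nf) {
  stopifnot(is(nf, "NodeFeatures"))
  v <- nf@values
  mu <- colMeans(v)
  sdv <- apply(v, 2L, stats::sd)
  v <- sweep(v, 2L, mu)
  nz <- sdv > 0
  v[, nz] <- sweep(v[, nz, drop = FALSE], 2L, sdv[nz], "/")
  v[, !nz] <- 0
  nf@values <- v
  nf
}

#' Build labelled graph samples from a cohort
#'
#' Runs the full per-subject front end: estimates each subject's network
#' with the requested estimator, assembles the requested node-feature
#' blocks (CV always uses the subject's Pearson matrix, whatever the
#' adjacency estimator), optionally standardizes feature columns, and
#' pairs everything with the subject's label.
#'
#' @param cohort a [Cohort-class].
#' @param estimatorName `"pc"`, `"sr"` or `"lr"`.
#' @param featureSets character vector drawn from
#'   `c("OS", "OH", "NS", "CV")` (case-insensitive).
#' @param lambda penalty for the SR / LR estimators (ignored for PC).
#' @param standardize standardize feature columns per subject.
#' @param zscoreOS z-score OS rows before use.
#' @param nsKeepFraction edge fraction for the NS binarization.
#' @param binarize replace the weighted adjacency by its proportional
#'   thresholding before GCN normalization.
#' @param keepFraction edge fraction kept when `binarize = TRUE`.
#' @return a list of [GraphSample-class] objects, one per subject.
#' @examples
#' coh <- sampleCohort(cohortSpec(nRois = 8, nTimepoints = 40,
#'                                nSubjectsPerGroup = 2))
#' samples <- buildGraphSamples(coh, "pc", c("OH", "CV"))
#' samples[[1]]
#' @export
buildGraphSamples <- function(cohort, estimatorName = "pc",
                              featureSets = "CV", lambda = 0.25,
                              standardize = TRUE, zscoreOS = FALSE,
                              nsKeepFraction = 0.3, binarize = FALSE,
                              keepFraction = 0.3) {
  stopifnot(is(cohort, "Cohort"))
  estimatorName <- match.arg(tolower(estimatorName), c("pc", "sr", "lr"))
  featureSets <- toupper(featureSets)
  stopifnot(all(featureSets %in% c("OS", "OH", "NS", "CV")))
  lapply(seq_along(cohort@subjects), function(k) {
    ts <- cohort@subjects[[k]]
    net <- switch(estimatorName,
                  pc = estimatePC(ts),
                  sr = estimateSR(ts, lambda),
                  lr = estimateLR(ts, lambda))
    pcNet <- if (estimatorName == "pc") net else estimatePC(ts)
    if (binarize) {
      B <- binarizeAdjacency(net, keepFraction)
      net@raw <- B
      net <- normalizeAdjacency(net)
    }
    blocks <- lapply(featureSets, function(fs) {
      switch(fs,
             OS = featuresOS(ts, zscore = zscoreOS),
             OH = featuresOH(nrow(ts@values)),
             NS = featuresNS(net, nsKeepFraction),
             CV = featuresCV(pcNet))
    })
    feats <- combineFeatures(blocks)
    if (standardize) feats <- standardizeFeatures(feats)
    new("GraphSample", network = net, features = feats,
        label = cohort@labels[k], subjectId = ts@subjectId)
  })
}
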