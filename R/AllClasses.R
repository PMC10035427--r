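#' @import methods
NULL

#' ROI time-series matrix for one subject
#'
#' Holds the extracted regional time series of a single subject: one row per
#' region of interest (ROI), one column per time point. This is the raw input
#' of every network estimator in the package.
#'
#' @slot values numeric matrix, n ROIs x m time points.
#' @slot roiIds character vector of n ROI labels.
#' @slot subjectId single subject identifier.
#' @seealso [roiTimeSeries()], [estimatePC()], [estimateSR()], [estimateLR()]
#' @export
setClass("RoiTimeSeries",
  representation(values = "matrix", roiIds = "character",
                 subjectId = "character"),
  validity = function(object) {
    v <- object@values
    if (!is.numeric(v)) return("values must be a numeric matrix")
    if (nrow(v) < 2L) return("need at least 2 ROIs")
    if (ncol(v) < 3L) return("need at least 3 time points")
    if (length(object@roiIds) != nrow(v))
      return("roiIds length must equal the number of ROIs")
    if (length(object@subjectId) != 1L) return("subjectId must be length 1")
    TRUE
  })

#' Specification of a synthetic two-group cohort
#'
#' Describes a simulated rs-fMRI-like cohort: two labelled groups of subjects,
#' each an n x m ROI time-series matrix drawn from a zero-mean multivariate
#' normal whose correlation on a designated block of ROI pairs differs
#' between groups, plus i.i.d. Gaussian observation noise.
#'
#' @slot nRois number of ROIs (rows) per subject.
#' @slot nTimepoints number of time points (columns) per subject.
#' @slot nSubjectsPerGroup subjects simulated for each of the two groups.
#' @slot effectBlock integer matrix with two columns; each row an unordered
#'   ROI pair whose latent correlation differs between groups.
#' @slot effectDelta group-1 minus group-0 latent correlation on the block,
#'   in `[0, 1)`.
#' @slot baseCorrelation latent correlation of block pairs in group 0.
#' @slot noiseSd standard deviation of the additive observation noise.
#' @slot seed integer RNG seed; the whole cohort is reproducible from it.
#' @seealso [cohortSpec()], [sampleCohort()], [makeGroupCovariance()]
#' @export
setClass("CohortSpec",
  representation(nRois = "integer", nTimepoints = "integer",
                 nSubjectsPerGroup = "integer", effectBlock = "matrix",
                 effectDelta = "numeric", baseCorrelation = "numeric",
                 noiseSd = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@nRois < 2L) return("nRois must be >= 2")
    if (object@nTimepoints < 3L) return("nTimepoints must be >= 3")
    if (object@nSubjectsPerGroup < 1L)
      return("nSubjectsPerGroup must be >= 1")
    b <- object@effectBlock
    if (nrow(b) > 0L) {
      if (ncol(b) != 2L) return("effectBlock must have two columns")
      if (any(b < 1L) || any(b > object@nRois))
        return("effectBlock indices out of range")
      if (any(b[, 1L] == b[, 2L]))
        return("effectBlock pairs must be off-diagonal")
    }
    if (object@effectDelta < 0 || object@effectDelta >= 1)
      return("effectDelta must lie in [0, 1)")
    if (abs(object@baseCorrelation) >= 1)
      return("baseCorrelation must lie in (-1, 1)")
    if (abs(object@baseCorrelation) + object@effectDelta >= 1)
      return("|baseCorrelation| + effectDelta must be < 1")
    if (object@noiseSd < 0) return("noiseSd must be nonnegative")
    TRUE
  })

#' A labelled cohort of subjects
#'
#' A list of [RoiTimeSeries-class] objects with binary group labels, either
#' simulated by [sampleCohort()] or read from disk by [readCohort()].
#'
#' @slot subjects list of [RoiTimeSeries-class] objects.
#' @slot labels integer vector of 0/1 group labels, one per subject.
#' @slot spec the generating [CohortSpec-class] for synthetic cohorts, or
#'   `NULL` for cohorts loaded from disk.
#' @export
setClass("Cohort",
  representation(subjects = "list", labels = "integer", spec = "ANY"),
  validity = function(object) {
    if (length(object@subjects) != length(object@labels))
      return("one label per subject required")
    if (!all(object@labels %in% c(0L, 1L)))
      return("labels must be 0 or 1")
    if (!all(vapply(object@subjects, is, logical(1), "RoiTimeSeries")))
      return("subjects must all be RoiTimeSeries objects")
    n <- vapply(object@subjects, function(s) nrow(s@values), integer(1))
    if (length(unique(n)) > 1L)
      return("all subjects must share the same number of ROIs")
    TRUE
  })

#' Estimated brain functional network of one subject
#'
#' An n x n connectivity estimate together with its symmetrically normalized
#' form used by the spectral GCN. `raw` has a zero diagonal; `normalized`
#' is D^(-1/2) (|raw| + I) D^(-1/2) where D holds the row sums of the
#' self-loop-augmented nonnegative working matrix.
#'
#' @slot raw n x n symmetric matrix with zero diagonal.
#' @slot normalized the degree-normalized adjacency driving GCN propagation.
#' @slot estimator one of `"PC"`, `"SR"`, `"LR"`.
#' @slot params estimator hyperparameters and by-products (e.g. `lambda`,
#'   the unshrunk/shrunk matrices where relevant).
#' @slot roiIds ROI labels.
#' @slot subjectId subject identifier.
#' @seealso [estimatePC()], [estimateSR()], [estimateLR()],
#'   [normalizeAdjacency()]
#' @export
setClass("BrainNetwork",
  representation(raw = "matrix", normalized = "matrix",
                 estimator = "character", params = "list",
                 roiIds = "character", subjectId = "character"),
  validity = function(object) {
    A <- object@raw
    if (nrow(A) != ncol(A)) return("raw must be square")
    if (max(abs(A - t(A))) > 1e-8) return("raw must be symmetric")
    if (max(abs(diag(A))) > 1e-12)
      return("raw must have a zero diagonal")
    if (!object@estimator %in% c("PC", "SR", "LR"))
      return("estimator must be PC, SR or LR")
    TRUE
  })

#' Node feature matrix
#'
#' The n x d per-node input X of the GCN. Feature blocks are drawn from the
#' four families: OS (original signals, d = m), OH (one-hot indicators,
#' d = n), NS (eight node statistics, d = 8) and CV (correlation vectors,
#' d = n), concatenated in that canonical order.
#'
#' @slot values numeric matrix, n nodes x d features.
#' @slot featureSet ordered subset of `c("OS", "OH", "NS", "CV")`.
#' @slot columnNames d column labels.
#' @seealso [featuresOS()], [featuresOH()], [featuresNS()], [featuresCV()],
#'   [combineFeatures()]
#' @export
setClass("NodeFeatures",
  representation(values = "matrix", featureSet = "character",
                 columnNames = "character"),
  validity = function(object) {
    if (!all(object@featureSet %in% c("OS", "OH", "NS", "CV")))
      return("featureSet entries must be OS, OH, NS or CV")
    if (anyDuplicated(object@featureSet))
      return("duplicate feature blocks are not allowed")
    canon <- intersect(c("OS", "OH", "NS", "CV"), object@featureSet)
    if (!identical(canon, object@featureSet))
      return("featureSet must follow the canonical order OS, OH, NS, CV")
    if (length(object@columnNames) != ncol(object@values))
      return("columnNames must match the number of feature columns")
    TRUE
  })

#' One subject as a labelled graph
#'
#' Pairs a subject's estimated network (adjacency) with a node feature
#' matrix and the binary diagnosis label: the unit consumed by the GCN
#' classifier.
#'
#' @slot network a [BrainNetwork-class].
#' @slot features a [NodeFeatures-class] with as many rows as the network
#'   has nodes.
#' @slot label integer 0 or 1.
#' @slot subjectId subject identifier.
#' @seealso [buildGraphSamples()], [trainGCN()]
#' @export
setClass("GraphSample",
  representation(network = "BrainNetwork", features = "NodeFeatures",
                 label = "integer", subjectId = "character"),
  validity = function(object) {
    if (nrow(object@network@raw) != nrow(object@features@values))
      return("network and features must agree on the number of nodes")
    if (!object@label %in% c(0L, 1L)) return("label must be 0 or 1")
    TRUE
  })

#' Parameters of the two-layer spectral GCN
#'
#' The two graph-convolution weight matrices plus the linear classification
#' head applied to the mean/max readout. Shapes chain as
#' (n x d) W0 -> (n x h) -> W1 -> (n x h) -> readout (2h) -> head (2 logits),
#' with h the embedding dimension.
#'
#' @slot W0 d x h first-layer weights.
#' @slot W1 h x h second-layer weights.
#' @slot headW 2h x 2 classification-head weights.
#' @slot headB length-2 head bias.
#' @export
setClass("GCNParams",
  representation(W0 = "matrix", W1 = "matrix", headW = "matrix",
                 headB = "numeric"),
  validity = function(object) {
    h <- ncol(object@W0)
    if (nrow(object@W1) != h || ncol(object@W1) != h)
      return("W1 must be h x h with h = ncol(W0)")
    if (nrow(object@headW) != 2L * h || ncol(object@headW) != 2L)
      return("headW must be 2h x 2")
    if (length(object@headB) != 2L) return("headB must have length 2")
    TRUE
  })

#' GCN training configuration
#'
#' Defaults follow the study design this package implements: embedding
#' dimension 32, 100 epochs, learning rate 0.001 and weight decay 1e-3,
#' trained full-batch with Adam.
#'
#' @slot embeddingDim width h of both hidden layers.
#' @slot epochs number of optimization epochs.
#' @slot learningRate Adam step size.
#' @slot weightDecay L2 penalty coefficient on the weight matrices.
#' @slot optimizer optimizer name (`"adam"`).
#' @slot batchSize minibatch size; `NA` means full batch.
#' @slot seed RNG seed for initialization and batching.
#' @seealso [trainConfig()], [trainGCN()]
#' @export
setClass("TrainConfig",
  representation(embeddingDim = "integer", epochs = "integer",
                 learningRate = "numeric", weightDecay = "numeric",
                 optimizer = "character", batchSize = "integer",
                 seed = "integer"),
  validity = function(object) {
    if (object@embeddingDim < 1L) return("embeddingDim must be positive")
    if (object@epochs < 1L) return("epochs must be positive")
    if (object@learningRate <= 0) return("learningRate must be positive")
    if (object@weightDecay < 0) return("weightDecay must be nonnegative")
    if (!object@optimizer %in% "adam")
      return("only the adam optimizer is implemented")
    TRUE
  })

#' A fitted GCN classifier
#'
#' @slot params the learned [GCNParams-class].
#' @slot config the [TrainConfig-class] used.
#' @slot trace per-epoch mean training cross-entropy.
#' @seealso [trainGCN()], [predictGCN()]
#' @export
setClass("GCNModel",
  representation(params = "GCNParams", config = "TrainConfig",
                 trace = "numeric"))

#' Metrics of one train/test repeat
#'
#' The six classification metrics of a single random split, together with
#' the confusion counts they derive from. Metrics with an empty denominator
#' are reported as 0 and recorded in `flags`.
#'
#' @slot acc,sen,spe,pre,f1,auc the six metrics, each in `[0, 1]`.
#' @slot confusion named integer vector (TP, FP, TN, FN).
#' @slot splitSeed the seed that produced the split.
#' @slot flags names of metrics whose denominator was zero.
#' @seealso [computeMetrics()]
#' @export
setClass("RunResult",
  representation(acc = "numeric", sen = "numeric", spe = "numeric",
                 pre = "numeric", f1 = "numeric", auc = "numeric",
                 confusion = "integer", splitSeed = "integer",
                 flags = "character"),
  validity = function(object) {
    m <- c(object@acc, object@sen, object@spe, object@pre, object@f1,
           object@auc)
    if (any(m < 0 | m > 1)) return("metrics must lie in [0, 1]")
    if (length(object@confusion) != 4L)
      return("confusion must be (TP, FP, TN, FN)")
    TRUE
  })

#' Grid of evaluation results over estimators and feature sets
#'
#' One row per (estimator, feature set) combination; each metric reported
#' as mean and standard deviation over the repeated random splits, with the
#' best row per metric flagged.
#'
#' @slot table data.frame with columns `estimator`, `features` and
#'   `<metric>_mean` / `<metric>_std` for the six metrics.
#' @slot nRepeats number of random splits behind every row.
#' @slot best named integer vector: for each metric, the row index of the
#'   best mean (ties broken by first row).
#' @slot perRepeat list of per-repeat metric data.frames, one per row
#'   (empty for grids restored from CSV).
#' @seealso [buildGrid()], [writeGrid()]
#' @export
setClass("ExperimentGrid",
  representation(table = "data.frame", nRepeats = "integer",
                 best = "integer", perRepeat = "list"),
  validity = function(object) {
    need <- c("estimator", "features",
              paste0(rep(c("acc", "sen", "spe", "pre", "f1", "auc"),
                         each = 2L), c("_mean", "_std")))
    if (!all(need %in% names(object@table)))
      return("table is missing required metric columns")
    TRUE
  })
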