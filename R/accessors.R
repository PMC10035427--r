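#' Accessors for package classes
#'
#' Small generic accessors so user code never touches slots directly:
#' `tsValues()` returns a subject's ROI x time matrix, `adjacency()` and
#' `normalizedAdjacency()` the raw and degree-normalized connectivity,
#' `estimator()` the estimator tag, `featureValues()` / `featureSet()` the
#' node-feature block, `roiIds()` / `subjectId()` the identifiers,
#' `subjectLabels()` the 0/1 group labels of a cohort, `nSubjects()` its
#' size, `metricMeans()` the per-metric means of a grid and `gridTable()`
#' its underlying data.frame.
#'
#' @param x an object of the documented class.
#' @return the corresponding slot value (a matrix, character vector,
#'   integer vector or data.frame; see the individual generics).
#' @name accessors
#' @aliases tsValues adjacency normalizedAdjacency estimator featureValues
#'   featureSet roiIds subjectId subjectLabels nSubjects metricMeans
#'   gridTable
#' @examples
#' spec <- cohortSpec(nRois = 6, nTimepoints = 40, nSubjectsPerGroup = 2)
#' coh <- sampleCohort(spec)
#' nSubjects(coh)
#' dim(tsValues(coh@subjects[[1]]))
NULL

#' @rdname accessors
#' @export
setGeneric("tsValues", function(x) standardGeneric("tsValues"))
#' @rdname accessors
#' @export
setMethod("tsValues", "RoiTimeSeries", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))
#' @rdname accessors
#' @export
setMethod("adjacency", "BrainNetwork", function(x) x@raw)

#' @rdname accessors
#' @export
setGeneric("normalizedAdjacency",
           function(x) standardGeneric("normalizedAdjacency"))
#' @rdname accessors
#' @export
setMethod("normalizedAdjacency", "BrainNetwork", function(x) x@normalized)

#' @rdname accessors
#' @export
setGeneric("estimator", function(x) standardGeneric("estimator"))
#' @rdname accessors
#' @export
setMethod("estimator", "BrainNetwork", function(x) x@estimator)

#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setMethod("featureValues", "NodeFeatures", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("featureValues", "GraphSample", function(x) x@features@values)

#' @rdname accessors
#' @export
setGeneric("featureSet", function(x) standardGeneric("featureSet"))
#' @rdname accessors
#' @export
setMethod("featureSet", "NodeFeatures", function(x) x@featureSet)

#' @rdname accessors
#' @export
setGeneric("roiIds", function(x) standardGeneric("roiIds"))
#' @rdname accessors
#' @export
setMethod("roiIds", "RoiTimeSeries", function(x) x@roiIds)
#' @rdname accessors
#' @export
setMethod("roiIds", "BrainNetwork", function(x) x@roiIds)

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setMethod("subjectId", "RoiTimeSeries", function(x) x@subjectId)
#' @rdname accessors
#' @export
setMethod("subjectId", "GraphSample", function(x) x@subjectId)

#' @rdname accessors
#' @export
setGeneric("subjectLabels", function(x) standardGeneric("subjectLabels"))
#' @rdname accessors
#' @export
setMethod("subjectLabels", "Cohort", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))
#' @rdname accessors
#' @export
setMethod("nSubjects", "Cohort", function(x) length(x@subjects))

#' @rdname accessors
#' @export
setGeneric("metricMeans", function(x) standardGeneric("metricMeans"))
#' @rdname accessors
#' @export
setMethod("metricMeans", "RunResult", function(x) {
  c(acc = x@acc, sen = x@sen, spe = x@spe, pre = x@pre, f1 = x@f1,
    auc = x@auc)
})

#' @rdname accessors
#' @export
setGeneric("gridTable", function(x) standardGeneric("gridTable"))
#' @rdname accessors
#' @export
setMethod("gridTable", "ExperimentGrid", function(x) x@table)

setMethod("show", "RoiTimeSeries", function(object) {
  cat(sprintf("RoiTimeSeries '%s': %d ROIs x %d time points\n",
              object@subjectId, nrow(object@values), ncol(object@values)))
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(paste0("CohortSpec: %d ROIs x %d time points, 2 x %d ",
                     "subjects\n  effect: delta=%.3g on %d ROI pair(s), ",
                     "base r=%.3g, noise sd=%.3g, seed=%d\n"),
              object@nRois, object@nTimepoints, object@nSubjectsPerGroup,
              object@effectDelta, nrow(object@effectBlock),
              object@baseCorrelation, object@noiseSd, object@seed))
})

setMethod("show", "Cohort", function(object) {
  n <- nrow(object@subjects[[1]]@values)
  cat(sprintf("Cohort: %d subjects (%d / %d per class), %d ROIs%s\n",
              length(object@subjects), sum(object@labels == 0L),
              sum(object@labels == 1L), n,
              if (is.null(object@spec)) "" else " [synthetic]"))
})

setMethod("show", "BrainNetwork", function(object) {
  cat(sprintf("BrainNetwork (%s) '%s': %d x %d, %d nonzero edges\n",
              object@estimator, object@subjectId, nrow(object@raw),
              ncol(object@raw),
              sum(object@raw[upper.tri(object@raw)] != 0)))
})

setMethod("show", "NodeFeatures", function(object) {
  cat(sprintf("NodeFeatures [%s]: %d nodes x %d features\n",
              paste(object@featureSet, collapse = " + "),
              nrow(object@values), ncol(object@values)))
})

setMethod("show", "GraphSample", function(object) {
  cat(sprintf("GraphSample '%s' (label %d): %s adjacency, features [%s]\n",
              object@subjectId, object@label, object@network@estimator,
              paste(object@features@featureSet, collapse = " + ")))
})

setMethod("show", "GCNModel", function(object) {
  cat(sprintf(paste0("GCNModel: d=%d -> h=%d, %d epochs, final training ",
                     "loss %.4f\n"),
              nrow(object@params@W0), ncol(object@params@W0),
              length(object@trace), utils::tail(object@trace, 1L)))
})

setMethod("show", "RunResult", function(object) {
  m <- metricMeans(object)
  cat("RunResult:", paste(sprintf("%s=%.3f", names(m), m),
                          collapse = " "), "\n")
  cat("  confusion (TP FP TN FN):", object@confusion, "\n")
})

setMethod("show", "ExperimentGrid", function(object) {
  cat(sprintf("ExperimentGrid: %d rows, %d repeats per row\n",
              nrow(object@table), object@nRepeats))
  print(object@table, digits = 3)
})
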