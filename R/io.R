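#' Write a cohort to a directory of per-subject CSV files
#'
#' One headerless CSV per subject (rows = ROIs, columns = time points)
#' named `<subjectId>.csv`, plus `labels.csv` with columns
#' `subject_id,label`.
#'
#' @param cohort a [Cohort-class].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "Cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- vapply(cohort@subjects, subjectId, character(1))
  for (k in seq_along(cohort@subjects)) {
    utils::write.table(cohort@subjects[[k]]@values,
                       file.path(dir, paste0(ids[k], ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  utils::write.csv(data.frame(subject_id = ids, label = cohort@labels),
                   file.path(dir, "labels.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}

#' Read a cohort from a directory of per-subject CSV files
#'
#' Expects the layout written by [writeCohort()]: a `labels.csv` with
#' columns `subject_id,label` and one headerless time-series CSV per
#' listed subject (rows = ROIs by default). Field counts are checked line
#' by line, so a ragged file is reported with its file name and row
#' number; labels outside `{0, 1}` and subjects with differing ROI counts
#' are errors, and constant ROI rows are flagged with a warning.
#'
#' @param dir the cohort directory.
#' @param transposed set `TRUE` if files store time points in rows.
#' @param sep field separator (`","` or `"\t"`).
#' @return a [Cohort-class] with `spec = NULL`.
#' @export
readCohort <- function(dir, transposed = FALSE, sep = ",") {
  labPath <- file.path(dir, "labels.csv")
  if (!file.exists(labPath))
    stop("labels.csv not found in ", dir)
  lab <- utils::read.csv(labPath, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "label") %in% names(lab)))
    stop("labels.csv must have columns subject_id,label")
  bad <- !lab$label %in% c(0L, 1L)
  if (any(bad))
    stop("label not in {0,1} for subject ",
         paste(lab$subject_id[bad], collapse = ", "))
  subjects <- lapply(seq_len(nrow(lab)), function(k) {
    f <- file.path(dir, paste0(lab$subject_id[k], ".csv"))
    if (!file.exists(f))
      stop("missing time-series file for subject ", lab$subject_id[k],
           ": ", f)
    v <- readStrictMatrix(f, sep = sep)
    if (transposed) v <- t(v)
    roiTimeSeries(v, subjectId = lab$subject_id[k])
  })
  for (s in subjects) {
    sds <- apply(s@values, 1L, stats::sd)
    if (any(sds == 0))
      warning(sprintf("subject %s has constant ROI row(s): %s",
                      s@subjectId,
                      paste(which(sds == 0), collapse = ", ")),
              call. = FALSE)
  }
  new("Cohort", subjects = subjects, labels = as.integer(lab$label),
      spec = NULL)
}

# numeric matrix reader that reports ragged rows by file and row number
readStrictMatrix <- function(path, sep = ",") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(parts)
  if (length(unique(widths)) > 1L) {
    off <- which(widths != widths[1L])[1L]
    stop(sprintf("ragged row in %s: row %d has %d fields, expected %d",
                 path, off, widths[off], widths[1L]))
  }
  v <- suppressWarnings(
    matrix(as.numeric(unlist(parts)), nrow = length(parts), byrow = TRUE))
  if (anyNA(v))
    stop("non-numeric entries in ", path)
  v
}

#' Write an adjacency matrix with a JSON sidecar
#'
#' The matrix goes to `path` as a CSV with the ROI labels as header; the
#' estimator name and its hyperparameters go to `<path>.json`.
#'
#' @param net a [BrainNetwork-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeAdjacency <- function(net, path) {
  stopifnot(is(net, "BrainNetwork"))
  m <- net@raw
  colnames(m) <- net@roiIds
  utils::write.csv(m, path, row.names = FALSE)
  side <- list(subject_id = net@subjectId, estimator = net@estimator,
               params = net@params[setdiff(names(net@params), "W")])
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write a node-feature matrix as CSV
#'
#' @param nf a [NodeFeatures-class].
#' @param path output CSV path; column names are the feature labels.
#' @return `path`, invisibly.
#' @export
writeFeatures <- function(nf, path) {
  stopifnot(is(nf, "NodeFeatures"))
  m <- nf@values
  colnames(m) <- nf@columnNames
  utils::write.csv(m, path, row.names = FALSE)
  invisible(path)
}

configSchema <- function() {
  list(
    data = c("dir", "transposed", "sep"),
    synthetic = c("n_rois", "n_timepoints", "n_subjects_per_group",
                  "effect_rois", "effect_delta", "base_correlation",
                  "noise_sd", "seed"),
    bfn = c("estimator", "lambda", "binarize", "threshold_keep_fraction"),
    features = c("sets", "standardize", "zscore_os", "ns_keep_fraction"),
    train = c("embedding_dim", "epochs", "learning_rate", "weight_decay",
              "optimizer", "batch_size", "seed"),
    evaluation = c("n_repeats", "seed", "train_fraction"),
    output = c("dir"))
}

#' Read and validate an experiment configuration
#'
#' Loads a YAML experiment description and validates it against the
#' package schema before any computation: unknown top-level blocks or
#' keys inside a block are rejected, and exactly one of `data` (a cohort
#' directory) or `synthetic` (a generator description) must be present.
#'
#' @param path YAML file path.
#' @return the validated configuration as a nested list.
#' @export
readExperimentConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  schema <- configSchema()
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown))
    stop("unknown config block(s): ", paste(unknown, collapse = ", "))
  for (block in names(cfg)) {
    if (!is.list(cfg[[block]]))
      stop("config block '", block, "' must be a mapping")
    bad <- setdiff(names(cfg[[block]]), schema[[block]])
    if (length(bad))
      stop("unknown key(s) in block '", block, "': ",
           paste(bad, collapse = ", "))
  }
  if (is.null(cfg$data) == is.null(cfg$synthetic))
    stop("exactly one of the 'data' or 'synthetic' blocks is required")
  cfg
}

cfgGet <- function(cfg, block, key, default) {
  v <- cfg[[block]][[key]]
  if (is.null(v)) default else v
}

#' Run a full experiment from a configuration
#'
#' Executes the end-to-end study described by a YAML configuration (see
#' [readExperimentConfig()]): obtain the cohort (simulate or load), build
#' graph samples per estimator and feature set, run the repeated-split
#' evaluation, and write the results grid plus reproducibility artifacts
#' (resolved configuration snapshot, seed list, per-repeat JSONL log) to
#' the output directory.
#'
#' @param config path to a YAML file, or an already-validated config list.
#' @param outDir output directory; overrides the config's `output.dir`.
#' @param seed master evaluation seed; overrides `evaluation.seed`.
#' @param nRepeats overrides `evaluation.n_repeats`.
#' @return the [ExperimentGrid-class], invisibly.
#' @export
runConfig <- function(config, outDir = NULL, seed = NULL,
                      nRepeats = NULL) {
  cfg <- if (is.character(config)) readExperimentConfig(config) else config
  outDir <- outDir %||% cfgGet(cfg, "output", "dir", "bfngcn-output")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  cohort <- if (!is.null(cfg$synthetic)) {
    s <- cfg$synthetic
    spec <- cohortSpec(
      nRois = s$n_rois %||% 116L,
      nTimepoints = s$n_timepoints %||% 135L,
      nSubjectsPerGroup = s$n_subjects_per_group %||% 20L,
      effectBlock = roiBlockPairs(s$effect_rois %||% 1:5),
      effectDelta = s$effect_delta %||% 0.4,
      baseCorrelation = s$base_correlation %||% -0.2,
      noiseSd = s$noise_sd %||% 0.5,
      seed = s$seed %||% 1L)
    sampleCohort(spec)
  } else {
    readCohort(cfg$data$dir, transposed = cfg$data$transposed %||% FALSE,
               sep = cfg$data$sep %||% ",")
  }

  estimators <- cfgGet(cfg, "bfn", "estimator", "pc")
  # each element is one grid row: blocks within a row joined by "+",
  # e.g. sets: ["OH", "CV", "OH+CV"] gives three rows
  featureSets <- lapply(as.list(cfgGet(cfg, "features", "sets",
                                       list("CV"))),
                        function(s) toupper(trimws(
                          unlist(strsplit(as.character(s), "[+,]+")))))
  names(featureSets) <- vapply(featureSets, paste, character(1),
                               collapse = " + ")
  trainCfg <- trainConfig(
    embeddingDim = cfgGet(cfg, "train", "embedding_dim", 32L),
    epochs = cfgGet(cfg, "train", "epochs", 100L),
    learningRate = cfgGet(cfg, "train", "learning_rate", 1e-3),
    weightDecay = cfgGet(cfg, "train", "weight_decay", 1e-3),
    optimizer = cfgGet(cfg, "train", "optimizer", "adam"),
    batchSize = cfgGet(cfg, "train", "batch_size", NA_integer_),
    seed = cfgGet(cfg, "train", "seed", 1L))
  nRepeats <- as.integer(nRepeats %||%
                           cfgGet(cfg, "evaluation", "n_repeats", 100L))
  seed <- as.integer(seed %||% cfgGet(cfg, "evaluation", "seed", 0L))
  fraction <- cfgGet(cfg, "evaluation", "train_fraction", 0.8)

  grid <- buildGrid(cohort,
                    estimators = estimators,
                    featureSets = featureSets,
                    cfg = trainCfg, nRepeats = nRepeats, seed = seed,
                    lambda = cfgGet(cfg, "bfn", "lambda", 0.25),
                    standardize = cfgGet(cfg, "features", "standardize",
                                         TRUE),
                    zscoreOS = cfgGet(cfg, "features", "zscore_os", FALSE),
                    nsKeepFraction = cfgGet(cfg, "features",
                                            "ns_keep_fraction", 0.3),
                    binarize = cfgGet(cfg, "bfn", "binarize", FALSE),
                    keepFraction = cfgGet(cfg, "bfn",
                                          "threshold_keep_fraction", 0.3),
                    fraction = fraction)

  writeGrid(grid, file.path(outDir, "grid.csv"))
  writeLines(formatGridMarkdown(grid), file.path(outDir, "grid.md"))
  resolved <- cfg
  resolved$evaluation <- list(n_repeats = nRepeats, seed = seed,
                              train_fraction = fraction)
  yaml::write_yaml(resolved, file.path(outDir, "config-resolved.yaml"))
  jsonlite::write_json(
    list(master_seed = seed,
         split_seeds = seed + seq_len(nRepeats),
         train_seeds = (seed + 100003L + seq_len(nRepeats)) %%
           .Machine$integer.max),
    file.path(outDir, "seeds.json"), auto_unbox = TRUE, digits = NA)
  logCon <- file(file.path(outDir, "repeats.jsonl"), open = "wt")
  on.exit(close(logCon))
  for (rowName in names(grid@perRepeat)) {
    per <- grid@perRepeat[[rowName]]
    for (k in seq_len(nrow(per))) {
      rec <- c(list(row = rowName, rep = k, split_seed = seed + k),
               as.list(per[k, ]))
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA),
                 logCon)
    }
  }
  invisible(grid)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
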