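#' Random train/test split
#'
#' Draws a random 80/20 (by default) split of the sample indices,
#' deterministic given `seed`. The test set has `round((1 - fraction) * N)`
#' members. A draw that leaves the training set with a single class is
#' rejected and redrawn from a derived seed (with a `message()`), so
#' training is always well defined.
#'
#' @param labels integer 0/1 label vector (or a list of
#'   [GraphSample-class] objects, whose labels are used).
#' @param fraction training fraction (default 0.8).
#' @param seed integer split seed.
#' @return a list with integer index vectors `train` and `test`
#'   (disjoint, exhaustive) and the `seed` actually used.
#' @export
splitSamples <- function(labels, fraction = 0.8, seed = 1L) {
  if (is.list(labels))
    labels <- vapply(labels, function(s) s@label, integer(1))
  N <- length(labels)
  stopifnot(N >= 5L, fraction > 0, fraction < 1)
  nTest <- round((1 - fraction) * N)
  usedSeed <- as.integer(seed)
  for (try in 0:99) {
    set.seed(usedSeed)
    test <- sort(sample.int(N, nTest))
    train <- setdiff(seq_len(N), test)
    if (length(unique(labels[train])) == 2L)
      return(list(train = train, test = test, seed = usedSeed))
    message(sprintf(
      "split seed %d left one class out of training; redrawing", usedSeed))
    usedSeed <- as.integer((usedSeed + 7919L * (try + 1L)) %% .Machine$integer.max)
  }
  stop("could not draw a split with both classes in training")
}

#' Classification metrics of one repeat
#'
#' Computes the six study metrics from hard predictions and positive-class
#' scores: Accuracy = (TP+TN)/(TP+FP+TN+FN), Sensitivity = TP/(TP+FN),
#' Specificity = TN/(TN+FP), Precision = TP/(TP+FP),
#' F1 = 2TP/(2TP+FP+FN), and AUC as the Mann-Whitney rank statistic of the
#' scores (ties counted 1/2). A metric whose denominator is zero is
#' reported as 0 and listed in the result's `flags`.
#'
#' @param labels true 0/1 labels.
#' @param predictions predicted 0/1 labels.
#' @param scores positive-class probabilities (for AUC).
#' @param splitSeed seed bookkeeping, stored in the result.
#' @return a [RunResult-class].
#' @examples
#' r <- computeMetrics(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),
#'                     c(1, 1, 1, 0, 0, 0, 0, 0, 0, 1),
#'                     c(.9, .8, .7, .4, .3, .2, .1, .2, .3, .6))
#' metricMeans(r)
#' @export
computeMetrics <- function(labels, predictions, scores,
                           splitSeed = NA_integer_) {
  stopifnot(length(labels) == length(predictions),
            length(labels) == length(scores))
  labels <- as.integer(labels)
  predictions <- as.integer(predictions)
  tp <- sum(labels == 1L & predictions == 1L)
  fp <- sum(labels == 0L & predictions == 1L)
  tn <- sum(labels == 0L & predictions == 0L)
  fn <- sum(labels == 1L & predictions == 0L)
  flags <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) {
      flags <<- c(flags, name)
      return(0)
    }
    num / den
  }
  acc <- safe(tp + tn, tp + fp + tn + fn, "acc")
  sen <- safe(tp, tp + fn, "sen")
  spe <- safe(tn, tn + fp, "spe")
  pre <- safe(tp, tp + fp, "pre")
  f1 <- safe(2 * tp, 2 * tp + fp + fn, "f1")
  nPos <- tp + fn
  nNeg <- tn + fp
  if (nPos == 0 || nNeg == 0) {
    auc <- 0
    flags <- c(flags, "auc")
  } else {
    r <- rank(scores)                     # midranks handle ties as 1/2
    auc <- (sum(r[labels == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  }
  new("RunResult", acc = acc, sen = sen, spe = spe, pre = pre, f1 = f1,
      auc = auc,
      confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
      splitSeed = as.integer(splitSeed), flags = flags)
}

#' Repeated random-split evaluation of one pipeline configuration
#'
#' Repeats split -> train -> predict -> score `nRepeats` times with split
#' seeds `seed + k` (k = 1..nRepeats) and per-repeat training seeds
#' derived from the same master seed, then aggregates every metric to its
#' mean and population standard deviation.
#'
#' @param samples list of [GraphSample-class] objects.
#' @param cfg a [TrainConfig-class].
#' @param nRepeats number of random splits (the study protocol uses 100).
#' @param seed master seed for the repeat sequence.
#' @param fraction training fraction.
#' @return a list with `perRepeat` (data.frame of the six metrics per
#'   repeat), `mean` and `std` (named numeric vectors), `results` (the
#'   [RunResult-class] objects) and `nRepeats`.
#' @export
runExperiment <- function(samples, cfg = trainConfig(), nRepeats = 100L,
                          seed = 0L, fraction = 0.8) {
  stopifnot(length(samples) >= 5L)
  results <- vector("list", nRepeats)
  for (k in seq_len(nRepeats)) {
    res <- tryCatch({
      sp <- splitSamples(samples, fraction = fraction,
                         seed = as.integer(seed + k))
      cfgK <- cfg
      cfgK@seed <- as.integer((seed + 100003L + k) %% .Machine$integer.max)
      model <- trainGCN(samples[sp$train], cfgK)
      probs <- predictGCN(samples[sp$test], model)
      labs <- vapply(samples[sp$test], function(s) s@label, integer(1))
      computeMetrics(labs, as.integer(probs[, "prob1"] > 0.5),
                     probs[, "prob1"], splitSeed = sp$seed)
    }, error = function(e) {
      stop(sprintf("repeat %d failed: %s", k, conditionMessage(e)),
           call. = FALSE)
    })
    results[[k]] <- res
  }
  per <- do.call(rbind, lapply(results, function(r)
    as.data.frame(as.list(metricMeans(r)))))
  mu <- colMeans(per)
  sdev <- apply(per, 2L, function(x) sqrt(mean((x - mean(x))^2)))
  list(perRepeat = per, mean = mu, std = sdev, results = results,
       nRepeats = nRepeats)
}

#' The twelve feature-set rows of the ablation grid
#'
#' The single features and the combinations evaluated by the study, in
#' presentation order.
#'
#' @return a named list of character vectors of feature-block names.
#' @export
defaultFeatureGrid <- function() {
  rows <- list(c("OS"), c("OH"), c("NS"), c("CV"),
               c("OS", "OH"), c("OH", "NS"), c("OH", "CV"),
               c("NS", "CV"), c("OH", "OS", "NS"), c("OH", "OS", "CV"),
               c("OS", "NS", "CV"), c("OH", "OS", "NS", "CV"))
  names(rows) <- vapply(rows, paste, character(1), collapse = " + ")
  rows
}

#' Build the estimator x feature-set results grid
#'
#' Evaluates every (estimator, feature set) combination with
#' [runExperiment()] and assembles the mean +/- std table, flagging the
#' best row per metric (ties broken by the first row).
#'
#' @param cohort a [Cohort-class].
#' @param estimators character vector from `c("pc", "sr", "lr")`.
#' @param featureSets list of character vectors of feature-block names
#'   (default [defaultFeatureGrid()]).
#' @param cfg a [TrainConfig-class].
#' @param nRepeats random splits per cell.
#' @param seed master seed.
#' @param lambda SR/LR penalty passed to [buildGraphSamples()].
#' @param fraction training fraction per split.
#' @param ... further arguments to [buildGraphSamples()].
#' @return an [ExperimentGrid-class].
#' @export
buildGrid <- function(cohort, estimators = "pc",
                      featureSets = defaultFeatureGrid(),
                      cfg = trainConfig(), nRepeats = 100L, seed = 0L,
                      lambda = 0.25, fraction = 0.8, ...) {
  stopifnot(length(estimators) >= 1L, length(featureSets) >= 1L)
  if (!is.list(featureSets)) featureSets <- list(featureSets)
  if (is.null(names(featureSets)))
    names(featureSets) <- vapply(featureSets, paste, character(1),
                                 collapse = " + ")
  rows <- list()
  perRepeat <- list()
  for (est in estimators) {
    for (fsName in names(featureSets)) {
      samples <- buildGraphSamples(cohort, est,
                                   featureSets[[fsName]],
                                   lambda = lambda, ...)
      res <- runExperiment(samples, cfg, nRepeats = nRepeats, seed = seed,
                           fraction = fraction)
      row <- data.frame(estimator = toupper(est), features = fsName,
                        stringsAsFactors = FALSE)
      for (mName in names(res$mean)) {
        row[[paste0(mName, "_mean")]] <- unname(res$mean[mName])
        row[[paste0(mName, "_std")]] <- unname(res$std[mName])
      }
      rows[[length(rows) + 1L]] <- row
      perRepeat[[paste(toupper(est), fsName, sep = " / ")]] <-
        res$perRepeat
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  metrics <- c("acc", "sen", "spe", "pre", "f1", "auc")
  best <- vapply(metrics, function(mName)
    which.max(tab[[paste0(mName, "_mean")]]), integer(1))
  new("ExperimentGrid", table = tab, nRepeats = as.integer(nRepeats),
      best = best, perRepeat = perRepeat)
}

#' Write / read an experiment grid as CSV
#'
#' Values are written with 17 significant digits so that a write/read
#' round trip reproduces the grid exactly.
#'
#' @param grid an [ExperimentGrid-class].
#' @param path output CSV path.
#' @return `writeGrid` returns `path` invisibly; `readGrid` the restored
#'   [ExperimentGrid-class] (with `best` recomputed).
#' @export
writeGrid <- function(grid, path) {
  stopifnot(is(grid, "ExperimentGrid"))
  tab <- grid@table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(x) sprintf("%.17g", x))
  tab$n_repeats <- grid@nRepeats
  utils::write.csv(tab, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname writeGrid
#' @param path path of a CSV written by `writeGrid`.
#' @export
readGrid <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  nRepeats <- as.integer(tab$n_repeats[1L])
  tab$n_repeats <- NULL
  metrics <- c("acc", "sen", "spe", "pre", "f1", "auc")
  best <- vapply(metrics, function(mName)
    which.max(tab[[paste0(mName, "_mean")]]), integer(1))
  new("ExperimentGrid", table = tab, nRepeats = nRepeats, best = best,
      perRepeat = list())
}

#' Render an experiment grid as a Markdown table
#'
#' @param grid an [ExperimentGrid-class].
#' @return a character vector of Markdown lines; best cells are bold.
#' @export
formatGridMarkdown <- function(grid) {
  tab <- grid@table
  metrics <- c("acc", "sen", "spe", "pre", "f1", "auc")
  header <- c("Estimator", "Features",
              c(Acc = "Acc", Sen = "Sen", Spe = "Spe", Pre = "Pre",
                F1 = "F1", AUC = "AUC"))
  lines <- c(paste0("| ", paste(header, collapse = " | "), " |"),
             paste0("|", paste(rep("---", length(header)),
                               collapse = "|"), "|"))
  for (i in seq_len(nrow(tab))) {
    cells <- vapply(metrics, function(mName) {
      txt <- sprintf("%.3f ± %.3f", tab[[paste0(mName, "_mean")]][i],
                     tab[[paste0(mName, "_std")]][i])
      if (grid@best[[mName]] == i) paste0("**", txt, "**") else txt
    }, character(1))
    lines <- c(lines, paste0("| ", tab$estimator[i], " | ",
                             tab$features[i], " | ",
                             paste(cells, collapse = " | "), " |"))
  }
  lines
}
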