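#' GCN training configuration
#'
#' @param embeddingDim hidden/embedding width h (default 32).
#' @param epochs training epochs (default 100).
#' @param learningRate Adam step size (default 0.001).
#' @param weightDecay L2 penalty on weight matrices (default 1e-3).
#' @param optimizer optimizer name; only `"adam"` is implemented.
#' @param batchSize minibatch size, `NA` for full batch (the default;
#'   cohorts here are small).
#' @param seed RNG seed for weight initialization and batch shuffling.
#' @return a [TrainConfig-class].
#' @export
trainConfig <- function(embeddingDim = 32L, epochs = 100L,
                        learningRate = 1e-3, weightDecay = 1e-3,
                        optimizer = "adam", batchSize = NA_integer_,
                        seed = 1L) {
  new("TrainConfig", embeddingDim = as.integer(embeddingDim),
      epochs = as.integer(epochs), learningRate = learningRate,
      weightDecay = weightDecay, optimizer = optimizer,
      batchSize = as.integer(batchSize), seed = as.integer(seed))
}

#' Initialize GCN parameters
#'
#' Glorot-uniform initialization of the two convolution weight matrices
#' and the linear head, from the current RNG state.
#'
#' @param d input feature width.
#' @param h embedding dimension.
#' @return a [GCNParams-class].
#' @export
initGCNParams <- function(d, h) {
  glorot <- function(nin, nout) {
    lim <- sqrt(6 / (nin + nout))
    matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
  }
  new("GCNParams", W0 = glorot(d, h), W1 = glorot(h, h),
      headW = glorot(2L * h, 2L), headB = c(0, 0))
}

#' Two-layer spectral GCN forward pass
#'
#' Computes the node-embedding matrix
#' `F = ReLU(Ahat %*% ReLU(Ahat %*% X %*% W0) %*% W1)` where `Ahat` is the
#' symmetrically degree-normalized adjacency of the sample.
#'
#' @param sample a [GraphSample-class], or a plain list with elements
#'   `Ahat` (n x n) and `X` (n x d).
#' @param params a [GCNParams-class].
#' @return the n x h node-embedding matrix (all entries nonnegative).
#' @export
gcnForward <- function(sample, params) {
  if (is(sample, "GraphSample")) {
    Ahat <- sample@network@normalized
    X <- sample@features@values
  } else {
    Ahat <- sample$Ahat
    X <- sample$X
  }
  if (ncol(X) != nrow(params@W0))
    stop(sprintf("feature width %d does not match W0 input width %d",
                 ncol(X), nrow(params@W0)))
  Z1 <- pmax(Ahat %*% X %*% params@W0, 0)
  pmax(Ahat %*% Z1 %*% params@W1, 0)
}

#' Mean/max graph readout
#'
#' Aggregates node embeddings into a graph-level vector by concatenating
#' the per-feature mean over nodes with the per-feature maximum.
#'
#' @param F node-embedding matrix, n x h.
#' @return a numeric vector of length 2h: `c(colMeans(F), colMax(F))`.
#' @examples
#' gcnReadout(matrix(c(1, 0, 0, 2), 2, 2))  # 0.5 1.0 1 2
#' @export
gcnReadout <- function(F) {
  F <- as.matrix(F)
  if (nrow(F) < 1L) stop("empty embedding matrix")
  c(colMeans(F), apply(F, 2L, max))
}

# forward pass retaining intermediates for backprop; P = Ahat %*% X cached
gcnForwardFull <- function(P, Ahat, params) {
  M1 <- P %*% params@W0
  Z1 <- pmax(M1, 0)
  AZ1 <- Ahat %*% Z1
  M2 <- AZ1 %*% params@W1
  Fm <- pmax(M2, 0)
  H <- c(colMeans(Fm), apply(Fm, 2L, max))
  z <- drop(H %*% params@headW) + params@headB
  z <- z - max(z)
  p <- exp(z) / sum(exp(z))
  list(M1 = M1, Z1 = Z1, AZ1 = AZ1, M2 = M2, Fm = Fm, H = H, p = p)
}

# gradient of the cross-entropy of one sample w.r.t. all parameters
gcnBackward <- function(fw, P, Ahat, params, label) {
  h <- ncol(params@W1)
  n <- nrow(fw$Fm)
  y <- c(label == 0L, label == 1L) * 1
  dz <- fw$p - y
  dHeadW <- outer(fw$H, dz)
  dHeadB <- dz
  dH <- drop(params@headW %*% dz)
  dF <- matrix(dH[seq_len(h)] / n, n, h, byrow = TRUE)
  amax <- max.col(t(fw$Fm), ties.method = "first")   # argmax row per column
  dF[cbind(amax, seq_len(h))] <-
    dF[cbind(amax, seq_len(h))] + dH[h + seq_len(h)]
  dM2 <- dF * (fw$M2 > 0)
  dW1 <- crossprod(fw$AZ1, dM2)
  dZ1 <- Ahat %*% (dM2 %*% t(params@W1))             # Ahat is symmetric
  dM1 <- dZ1 * (fw$M1 > 0)
  dW0 <- crossprod(P, dM1)
  list(W0 = dW0, W1 = dW1, headW = dHeadW, headB = dHeadB)
}

#' Train the GCN classifier
#'
#' Minimizes the mean softmax cross-entropy of the linear head applied to
#' the mean/max readout, with Adam and L2 weight decay on the weight
#' matrices. Training is full-batch by default and fully deterministic
#' given `cfg@seed`.
#'
#' @param samples list of [GraphSample-class] objects; both classes must
#'   be present.
#' @param cfg a [TrainConfig-class].
#' @return a [GCNModel-class] carrying the learned parameters and the
#'   per-epoch training-loss trace.
#' @examples
#' coh <- sampleCohort(cohortSpec(nRois = 8, nTimepoints = 40,
#'                                nSubjectsPerGroup = 3))
#' samples <- buildGraphSamples(coh, "pc", "CV")
#' model <- trainGCN(samples, trainConfig(epochs = 5))
#' model
#' @export
trainGCN <- function(samples, cfg = trainConfig()) {
  stopifnot(length(samples) >= 2L)
  labels <- vapply(samples, function(s) s@label, integer(1))
  if (length(unique(labels)) < 2L)
    stop("training set contains a single class; cannot fit a classifier")
  set.seed(cfg@seed)
  d <- ncol(samples[[1L]]@features@values)
  h <- cfg@embeddingDim
  params <- initGCNParams(d, h)
  pre <- lapply(samples, function(s) {
    Ahat <- s@network@normalized
    list(Ahat = Ahat, P = Ahat %*% s@features@values, label = s@label)
  })
  nS <- length(pre)
  bs <- if (is.na(cfg@batchSize)) nS else min(cfg@batchSize, nS)
  opt <- adamInit(params)
  trace <- numeric(cfg@epochs)
  for (epoch in seq_len(cfg@epochs)) {
    ord <- if (bs < nS) sample.int(nS) else seq_len(nS)
    epochLoss <- 0
    for (start in seq(1L, nS, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, nS)]
      grad <- NULL
      batchLoss <- 0
      for (i in idx) {
        fw <- gcnForwardFull(pre[[i]]$P, pre[[i]]$Ahat, params)
        batchLoss <- batchLoss -
          log(max(fw$p[pre[[i]]$label + 1L], 1e-12))
        g <- gcnBackward(fw, pre[[i]]$P, pre[[i]]$Ahat, params,
                         pre[[i]]$label)
        grad <- if (is.null(grad)) g else
          Map(`+`, grad, g)
      }
      grad <- lapply(grad, `/`, length(idx))
      grad$W0 <- grad$W0 + cfg@weightDecay * params@W0
      grad$W1 <- grad$W1 + cfg@weightDecay * params@W1
      grad$headW <- grad$headW + cfg@weightDecay * params@headW
      upd <- adamStep(opt, grad, cfg@learningRate)
      opt <- upd$state
      params@W0 <- params@W0 - upd$delta$W0
      params@W1 <- params@W1 - upd$delta$W1
      params@headW <- params@headW - upd$delta$headW
      params@headB <- params@headB - upd$delta$headB
      epochLoss <- epochLoss + batchLoss
    }
    trace[epoch] <- epochLoss / nS
  }
  new("GCNModel", params = params, config = cfg, trace = trace)
}

adamInit <- function(params) {
  zeros <- list(W0 = params@W0 * 0, W1 = params@W1 * 0,
                headW = params@headW * 0, headB = params@headB * 0)
  list(m = zeros, v = zeros, t = 0L)
}

adamStep <- function(state, grad, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- Map(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grad)
  state$v <- Map(function(v, g) beta2 * v + (1 - beta2) * g^2,
                 state$v, grad)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  delta <- Map(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
               state$m, state$v)
  list(state = state, delta = delta)
}

#' Predict class probabilities for graph samples
#'
#' Runs the forward pass and softmax head for every sample.
#'
#' @param samples list of [GraphSample-class] objects.
#' @param model a [GCNModel-class] (or a bare [GCNParams-class]).
#' @return a matrix with one row per sample and columns `prob0`, `prob1`;
#'   rows sum to 1.
#' @export
predictGCN <- function(samples, model) {
  params <- if (is(model, "GCNModel")) model@params else model
  probs <- t(vapply(samples, function(s) {
    Ahat <- s@network@normalized
    if (ncol(s@features@values) != nrow(params@W0))
      stop(sprintf("feature width %d does not match trained width %d",
                   ncol(s@features@values), nrow(params@W0)))
    fw <- gcnForwardFull(Ahat %*% s@features@values, Ahat, params)
    fw$p
  }, numeric(2)))
  colnames(probs) <- c("prob0", "prob1")
  rownames(probs) <- vapply(samples, function(s) s@subjectId, character(1))
  probs
}

# mean cross-entropy of a sample set; used by tests for gradient checks
gcnLoss <- function(samples, params, weightDecay = 0) {
  ce <- vapply(samples, function(s) {
    Ahat <- s@network@normalized
    fw <- gcnForwardFull(Ahat %*% s@features@values, Ahat, params)
    -log(max(fw$p[s@label + 1L], 1e-12))
  }, numeric(1))
  mean(ce) + weightDecay / 2 *
    (sum(params@W0^2) + sum(params@W1^2) + sum(params@headW^2))
}
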