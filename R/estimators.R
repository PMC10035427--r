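#' Pearson-correlation network estimate
#'
#' Estimates a subject's functional network as the matrix of pairwise
#' Pearson correlation coefficients between ROI time series,
#' c_ij = cov(s_i, s_j) / (sd(s_i) sd(s_j)). The diagonal of the raw
#' adjacency is set to zero; the degree-normalized form is computed
#' immediately (see [normalizeAdjacency()]).
#'
#' @param ts an [RoiTimeSeries-class].
#' @return a [BrainNetwork-class] with `estimator = "PC"`.
#' @examples
#' coh <- sampleCohort(cohortSpec(nRois = 6, nTimepoints = 40,
#'                                nSubjectsPerGroup = 1))
#' net <- estimatePC(coh@subjects[[1]])
#' range(adjacency(net))
#' @export
estimatePC <- function(ts) {
  stopifnot(is(ts, "RoiTimeSeries"))
  checkConstantRows(ts)
  C <- stats::cor(t(ts@values))
  diag(C) <- 0
  C <- (C + t(C)) / 2                    # kill numerical asymmetry
  newBrainNetwork(C, "PC", list(), ts)
}

#' Sparse-representation network estimate
#'
#' Regresses each ROI's (standardized) time series on all other ROIs with
#' an L1 (lasso) penalty: for ROI i it solves
#' `min_w 0.5 * ||s_i - S_{-i} w||^2 + lambda * ||w||_1` and stores the
#' coefficients as row i of a weight matrix W with zero diagonal. The raw
#' adjacency is the symmetrized magnitude `(|W| + |W'|) / 2`. The number of
#' nonzero edges is nonincreasing in `lambda`.
#'
#' The per-ROI lasso problems are solved with the coordinate-descent
#' implementation of \pkg{glmnet}.
#'
#' @param ts an [RoiTimeSeries-class].
#' @param lambda positive L1 penalty (on the 0.5*RSS scale above).
#' @return a [BrainNetwork-class] with `estimator = "SR"`; `params$W`
#'   carries the asymmetric coefficient matrix.
#' @examples
#' coh <- sampleCohort(cohortSpec(nRois = 6, nTimepoints = 60,
#'                                nSubjectsPerGroup = 1))
#' net <- estimateSR(coh@subjects[[1]], lambda = 2)
#' sum(adjacency(net) != 0)
#' @export
estimateSR <- function(ts, lambda = 0.25) {
  stopifnot(is(ts, "RoiTimeSeries"))
  if (lambda <= 0) stop("lambda must be positive")
  checkConstantRows(ts)
  S <- scale(t(ts@values))               # m x n, columns standardized
  n <- ncol(S)
  m <- nrow(S)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    W[i, -i] <- lassoFit(S[, -i, drop = FALSE], S[, i], lambda)
  }
  raw <- (abs(W) + abs(t(W))) / 2
  diag(raw) <- 0
  newBrainNetwork(raw, "SR", list(lambda = lambda, W = W), ts)
}

# solve min_w 0.5 ||y - X w||^2 + lambda ||w||_1 (no intercept, X as given)
lassoFit <- function(X, y, lambda) {
  m <- nrow(X)
  if (ncol(X) == 1L) {                   # closed-form univariate lasso
    xx <- sum(X^2)
    xy <- sum(X * y)
    return(sign(xy) * max(abs(xy) - lambda, 0) / xx)
  }
  # glmnet minimizes RSS/(2m) + lambda_g ||w||_1, so lambda_g = lambda / m;
  # a short warm-start path ending at the target improves accuracy
  lamg <- lambda / m
  fit <- glmnet::glmnet(X, y, alpha = 1, lambda = lamg * c(16, 8, 4, 2, 1),
                        standardize = FALSE, intercept = FALSE,
                        thresh = 1e-10, maxit = 1e5)
  as.numeric(fit$beta[, ncol(fit$beta)])
}

#' Low-rank-representation network estimate
#'
#' Denoises the Pearson-correlation matrix C towards low rank by solving
#' `min_W 0.5 * ||C - W||_F^2 + lambda * ||W||_*` (nuclear norm), whose
#' closed-form solution is singular-value soft-thresholding: singular
#' values of C are shrunk by `lambda` and clipped at zero. The raw
#' adjacency is `(|W| + |W'|) / 2` with a zeroed diagonal. The rank of W
#' is nonincreasing in `lambda`.
#'
#' @param ts an [RoiTimeSeries-class].
#' @param lambda positive nuclear-norm penalty.
#' @return a [BrainNetwork-class] with `estimator = "LR"`; `params$W`
#'   carries the shrunk matrix (diagonal included).
#' @examples
#' coh <- sampleCohort(cohortSpec(nRois = 6, nTimepoints = 40,
#'                                nSubjectsPerGroup = 1))
#' net <- estimateLR(coh@subjects[[1]], lambda = 0.5)
#' @export
estimateLR <- function(ts, lambda = 0.5) {
  stopifnot(is(ts, "RoiTimeSeries"))
  if (lambda <= 0) stop("lambda must be positive")
  checkConstantRows(ts)
  C <- stats::cor(t(ts@values))
  W <- svdSoftThreshold(C, lambda)
  raw <- (abs(W) + abs(t(W))) / 2
  diag(raw) <- 0
  raw <- (raw + t(raw)) / 2
  newBrainNetwork(raw, "LR", list(lambda = lambda, W = W), ts)
}

# proximal operator of lambda * nuclear norm
svdSoftThreshold <- function(C, lambda) {
  sv <- svd(C)
  d <- pmax(sv$d - lambda, 0)
  keep <- d > 0
  if (!any(keep)) return(matrix(0, nrow(C), ncol(C)))
  sv$u[, keep, drop = FALSE] %*%
    (d[keep] * t(sv$v[, keep, drop = FALSE]))
}

#' Symmetric degree normalization of an adjacency matrix
#'
#' Produces the normalized adjacency used in spectral GCN propagation:
#' working from the magnitude matrix `|A|` (so that degrees are
#' nonnegative and the square-root inverse is real), self-loops are added
#' (`A + I`), the degree matrix `D_ii = sum_j A_ij` is formed, and the
#' result is `D^(-1/2) (A + I) D^(-1/2)`. All eigenvalues of the result
#' lie in `[-1, 1]` (in fact `[0, 1]` for nonnegative working matrices up
#' to sign conventions of the spectrum bound).
#'
#' @param adj a symmetric numeric matrix (raw adjacency, zero diagonal) or
#'   a [BrainNetwork-class].
#' @return a matrix of the same dimension, or a [BrainNetwork-class] with
#'   its `normalized` slot refreshed.
#' @examples
#' normalizeAdjacency(matrix(c(0, 1, 1, 0), 2, 2))  # all entries 0.5
#' @export
normalizeAdjacency <- function(adj) {
  if (is(adj, "BrainNetwork")) {
    adj@normalized <- normalizeAdjacency(adj@raw)
    return(adj)
  }
  A <- abs(as.matrix(adj))
  if (max(abs(A - t(A))) > 1e-8) stop("adjacency must be symmetric")
  A <- A + diag(nrow(A))
  d <- rowSums(A)
  if (any(d <= 0)) stop("zero degree after self-loops; invalid adjacency")
  dis <- 1 / sqrt(d)
  A * outer(dis, dis)
}

#' Proportional thresholding of a weighted network
#'
#' Keeps the strongest `keepFraction` of off-diagonal edges by absolute
#' weight and returns a binary 0/1 adjacency (ties at the cut weight are
#' all kept).
#'
#' @param adj symmetric matrix or [BrainNetwork-class].
#' @param keepFraction fraction of the n(n-1)/2 possible edges to keep.
#' @return a binary symmetric matrix with zero diagonal.
#' @export
binarizeAdjacency <- function(adj, keepFraction = 0.3) {
  if (is(adj, "BrainNetwork")) adj <- adj@raw
  stopifnot(keepFraction > 0, keepFraction <= 1)
  A <- abs(as.matrix(adj))
  diag(A) <- 0
  v <- A[upper.tri(A)]
  k <- ceiling(keepFraction * length(v))
  thr <- sort(v, decreasing = TRUE)[k]
  B <- (A >= max(thr, .Machine$double.eps)) * 1
  diag(B) <- 0
  B
}

newBrainNetwork <- function(raw, estimator, params, ts) {
  new("BrainNetwork", raw = raw, normalized = normalizeAdjacency(raw),
      estimator = estimator, params = params, roiIds = ts@roiIds,
      subjectId = ts@subjectId)
}

checkConstantRows <- function(ts) {
  sds <- apply(ts@values, 1L, stats::sd)
  if (any(sds == 0))
    stop(sprintf("constant (zero-variance) ROI time series: %s",
                 paste(ts@roiIds[sds == 0], collapse = ", ")))
  invisible(TRUE)
}
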