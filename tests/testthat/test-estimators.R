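test_that("Pearson estimate matches the direct-summation formula", {
  ts <- randomTimeSeries(n = 4L, m = 20L, seed = 2L)
  net <- estimatePC(ts)
  C <- oracleCorrelationMatrix(tsValues(ts))
  diag(C) <- 0
  expect_lt(max(abs(adjacency(net) - C)), 1e-10)
  expect_true(all(abs(adjacency(net)) <= 1 + 1e-12))
  expect_equal(adjacency(net), t(adjacency(net)))
})

test_that("perfect linear dependence gives correlation +/- 1", {
  set.seed(3)
  s <- rnorm(30)
  vals <- rbind(s, 2 * s + 3, -s, rnorm(30))
  net <- estimatePC(roiTimeSeries(vals))
  expect_equal(adjacency(net)[1, 2], 1)
  expect_equal(adjacency(net)[1, 3], -1)
})

test_that("constant ROI rows are rejected with the ROI named", {
  vals <- rbind(rnorm(10), rep(2, 10), rnorm(10))
  ts <- roiTimeSeries(vals, roiIds = c("A", "B", "C"))
  expect_error(estimatePC(ts), "B")
  expect_error(estimateSR(ts, 0.1), "B")
  expect_error(estimateLR(ts, 0.1), "B")
})

test_that("sparse representation shrinks to zero under a huge penalty", {
  ts <- randomTimeSeries(n = 5L, m = 30L, seed = 4L)
  net <- estimateSR(ts, lambda = 1e4)
  expect_equal(max(abs(adjacency(net))), 0)
})

test_that("sparse representation prefers the duplicated ROI", {
  set.seed(8)
  s1 <- rnorm(50)
  vals <- rbind(s1, s1, rnorm(50))
  net <- estimateSR(roiTimeSeries(vals), lambda = 0.5)
  W <- net@params$W
  expect_gt(abs(W[1, 2]), 10 * abs(W[1, 3]))
  expect_gt(abs(W[1, 2]), 0.5)
})

test_that("SR output is symmetric with zero diagonal; sparsity monotone", {
  ts <- randomTimeSeries(n = 8L, m = 40L, seed = 5L)
  nnz <- vapply(2^(-5:2), function(lam) {
    A <- adjacency(estimateSR(ts, lam))
    expect_equal(A, t(A))
    expect_equal(diag(A), rep(0, 8))
    sum(A != 0)
  }, numeric(1))
  expect_true(all(diff(nnz) <= 0))
})

test_that("regional lasso agrees with soft-thresholding on an orthonormal design", {
  # for orthonormal X, argmin 0.5||y - Xw||^2 + lambda||w||_1 is
  # sign(X'y) * max(|X'y| - lambda, 0)
  set.seed(11)
  X <- qr.Q(qr(matrix(rnorm(40 * 3), 40, 3)))
  y <- rnorm(40)
  lam <- 0.3
  expected <- sign(crossprod(X, y)) * pmax(abs(crossprod(X, y)) - lam, 0)
  got <- bfnGCN:::lassoFit(X, y, lam)
  expect_equal(got, drop(expected), tolerance = 1e-6)
})

test_that("singular-value soft-thresholding behaves as the closed form", {
  # symmetric 2x2 with singular values {3, 1}
  C <- matrix(c(2, 1, 1, 2), 2, 2)
  expect_equal(svd(C)$d, c(3, 1))
  W <- bfnGCN:::svdSoftThreshold(C, 2)
  expect_equal(svd(W)$d, c(1, 0), tolerance = 1e-12)
  # lambda beyond the largest singular value kills everything
  expect_equal(bfnGCN:::svdSoftThreshold(C, 3.5), matrix(0, 2, 2))
})

test_that("low-rank estimate recovers the correlation matrix as lambda -> 0", {
  ts <- randomTimeSeries(n = 6L, m = 40L, seed = 6L)
  C <- cor(t(tsValues(ts)))
  net <- estimateLR(ts, lambda = 1e-10)
  expect_lt(max(abs(net@params$W - C)), 1e-8)
  offC <- abs(C)
  diag(offC) <- 0
  expect_lt(max(abs(adjacency(net) - offC)), 1e-8)
  # full thresholding
  netBig <- estimateLR(ts, lambda = sum(svd(C)$d))
  expect_equal(max(abs(adjacency(netBig))), 0)
})

test_that("nuclear norm of the LR solution is nonincreasing in lambda", {
  ts <- randomTimeSeries(n = 7L, m = 35L, seed = 9L)
  nuc <- vapply(c(0.01, 0.1, 0.5, 1, 2), function(lam)
    sum(svd(estimateLR(ts, lam)@params$W)$d), numeric(1))
  expect_true(all(diff(nuc) <= 1e-10))
})

test_that("lambda <= 0 is rejected", {
  ts <- randomTimeSeries()
  expect_error(estimateSR(ts, 0), "positive")
  expect_error(estimateLR(ts, -1), "positive")
})

test_that("adjacency normalization matches hand-computed cases", {
  expect_equal(normalizeAdjacency(matrix(0, 1, 1)), matrix(1, 1, 1))
  got <- normalizeAdjacency(matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(got, matrix(0.5, 2, 2))
})

test_that("normalized adjacency has spectral radius at most one", {
  set.seed(12)
  for (rep in 1:10) {
    A <- matrix(runif(25), 5, 5)
    A <- (A + t(A)) / 2
    diag(A) <- 0
    ev <- eigen(normalizeAdjacency(A), symmetric = TRUE,
                only.values = TRUE)$values
    expect_lte(max(abs(ev)), 1 + 1e-12)
  }
})

test_that("normalization uses magnitudes so negative weights are safe", {
  A <- matrix(c(0, -0.8, -0.8, 0), 2, 2)
  got <- normalizeAdjacency(A)
  expect_true(all(is.finite(got)))
  expect_equal(got, normalizeAdjacency(abs(A)))
})

test_that("proportional thresholding keeps the requested edge fraction", {
  set.seed(13)
  A <- matrix(runif(64), 8, 8)
  A <- (A + t(A)) / 2
  diag(A) <- 0
  B <- binarizeAdjacency(A, keepFraction = 0.25)
  expect_true(all(B %in% c(0, 1)))
  expect_equal(B, t(B))
  expect_equal(sum(B[upper.tri(B)]), ceiling(0.25 * 28))
  # kept edges are exactly the strongest ones
  v <- A[upper.tri(A)]
  kept <- v[B[upper.tri(B)] == 1]
  expect_gte(min(kept), max(v[B[upper.tri(B)] == 0]))
})
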