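# Independent brute-force oracles used to validate the implementation.
# All of these stay deliberately naive: explicit loops, explicit path
# enumeration, no reuse of package internals.

# Pearson correlation by direct summation of the defining formula
oracleCorrelation <- function(si, sj) {
  di <- si - mean(si)
  dj <- sj - mean(sj)
  sum(di * dj) / (sqrt(sum(di^2)) * sqrt(sum(dj^2)))
}

oracleCorrelationMatrix <- function(values) {
  n <- nrow(values)
  C <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      C[i, j] <- oracleCorrelation(values[i, ], values[j, ])
    }
  }
  C
}

# all simple paths between s and t in a binary adjacency, by recursion
enumSimplePaths <- function(B, s, t) {
  n <- nrow(B)
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (w in seq_len(n)) {
      if (B[v, w] > 0 && !(w %in% path)) walk(c(path, w))
    }
  }
  walk(s)
  paths
}

# geodesic distance and number of shortest paths from path enumeration
oracleShortest <- function(B, s, t) {
  paths <- enumSimplePaths(B, s, t)
  if (length(paths) == 0L) return(list(d = Inf, sigma = 0, paths = list()))
  lens <- vapply(paths, length, integer(1)) - 1L
  d <- min(lens)
  list(d = d, sigma = sum(lens == d), paths = paths[lens == d])
}

oracleBetweenness <- function(B, normalized = TRUE) {
  n <- nrow(B)
  btw <- numeric(n)
  for (s in seq_len(n - 1L)) {
    for (t in (s + 1L):n) {
      sp <- oracleShortest(B, s, t)
      if (sp$sigma == 0) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        through <- sum(vapply(sp$paths, function(p) v %in% p, logical(1)))
        btw[v] <- btw[v] + through / sp$sigma
      }
    }
  }
  if (normalized && n > 2L) btw <- btw / ((n - 1) * (n - 2) / 2)
  btw
}

oracleHarmonicCloseness <- function(B) {
  n <- nrow(B)
  vapply(seq_len(n), function(i) {
    inv <- vapply(setdiff(seq_len(n), i), function(j) {
      d <- oracleShortest(B, i, j)$d
      if (is.finite(d)) 1 / d else 0
    }, numeric(1))
    sum(inv) / (n - 1)
  }, numeric(1))
}

oracleClusteringWS <- function(B) {
  n <- nrow(B)
  vapply(seq_len(n), function(i) {
    nb <- which(B[i, ] > 0)
    k <- length(nb)
    if (k < 2L) return(0)
    tri <- 0
    for (a in seq_len(k - 1L)) {
      for (b in (a + 1L):k) {
        if (B[nb[a], nb[b]] > 0) tri <- tri + 1
      }
    }
    2 * tri / (k * (k - 1))
  }, numeric(1))
}

# Onnela et al. geometric-mean clustering on max-normalized weights
oracleOnnela <- function(W) {
  W <- abs(W)
  diag(W) <- 0
  if (max(W) > 0) W <- W / max(W)
  n <- nrow(W)
  vapply(seq_len(n), function(i) {
    k <- sum(W[i, ] > 0)
    if (k < 2L) return(0)
    acc <- 0
    for (j in seq_len(n)) {
      for (l in seq_len(n)) {
        acc <- acc + (W[i, j] * W[i, l] * W[j, l])^(1 / 3)
      }
    }
    acc / (k * (k - 1))
  }, numeric(1))
}

oracleZhang <- function(W) {
  W <- abs(W)
  diag(W) <- 0
  if (max(W) > 0) W <- W / max(W)
  n <- nrow(W)
  vapply(seq_len(n), function(i) {
    num <- 0
    for (j in seq_len(n)) {
      for (l in seq_len(n)) {
        num <- num + W[i, j] * W[j, l] * W[l, i]
      }
    }
    den <- sum(W[i, ])^2 - sum(W[i, ]^2)
    if (den <= 1e-12) 0 else num / den
  }, numeric(1))
}

oracleEigenvector <- function(W, iters = 20000L) {
  W <- abs(W)
  diag(W) <- 0
  n <- nrow(W)
  if (max(W) == 0) return(rep(0, n))
  # diagonal shift: same eigenvectors, but the leading eigenvalue becomes
  # strictly dominant, so power iteration converges even on bipartite graphs
  Ws <- W + diag(max(rowSums(W)) + 1, n)
  v <- rep(1 / sqrt(n), n)
  for (k in seq_len(iters)) {
    v2 <- drop(Ws %*% v)
    nv <- sqrt(sum(v2^2))
    if (nv == 0) return(rep(0, n))
    v2 <- v2 / nv
    if (max(abs(v2 - v)) < 1e-13) {
      v <- v2
      break
    }
    v <- v2
  }
  abs(v)
}

oracleLocalEfficiency <- function(B) {
  n <- nrow(B)
  vapply(seq_len(n), function(i) {
    nb <- which(B[i, ] > 0)
    k <- length(nb)
    if (k < 2L) return(0)
    sub <- B[nb, nb, drop = FALSE]
    acc <- 0
    for (a in seq_len(k - 1L)) {
      for (b in (a + 1L):k) {
        d <- oracleShortest(sub, a, b)$d
        if (is.finite(d)) acc <- acc + 1 / d
      }
    }
    2 * acc / (k * (k - 1))
  }, numeric(1))
}

oracleNodeStatistics <- function(B, W = B) {
  cbind(cc_ws = oracleClusteringWS(B),
        cc_onnela = oracleOnnela(W),
        cc_zhang = oracleZhang(W),
        deg_c = rowSums(B) / (nrow(B) - 1),
        btw_c = oracleBetweenness(B),
        clo_c = oracleHarmonicCloseness(B),
        eig_c = oracleEigenvector(W),
        local_eff = oracleLocalEfficiency(B))
}

# AUC as the fraction of correctly ordered positive/negative pairs
oracleAUC <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  acc <- 0
  for (p in pos) {
    for (q in neg) {
      acc <- acc + (p > q) + 0.5 * (p == q)
    }
  }
  acc / (length(pos) * length(neg))
}

# random connected undirected graph on n nodes (binary adjacency)
randomConnectedGraph <- function(n, p = 0.5) {
  repeat {
    B <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (stats::runif(1) < p) B[i, j] <- B[j, i] <- 1
      }
    }
    if (all(is.finite(vapply(seq_len(n), function(j)
      oracleShortest(B, 1L, j)$d, numeric(1))))) return(B)
  }
}
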