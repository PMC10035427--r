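#' Eight per-node graph statistics
#'
#' Computes, for every node, the eight statistics used as the NS feature
#' block: three local clustering coefficients (binary Watts-Strogatz,
#' Onnela geometric-mean weighted, Zhang-Horvath weighted), four
#' centralities (degree, betweenness, closeness, eigenvector) and local
#' efficiency, in that fixed column order.
#'
#' Binary-graph definitions (Watts-Strogatz clustering, degree,
#' betweenness, closeness, local efficiency) are evaluated on
#' `binaryAdj`; weighted definitions (Onnela and Zhang-Horvath clustering,
#' eigenvector centrality) on `|weightedAdj|` rescaled by its maximum.
#' Degree, betweenness and closeness are normalized to `[0, 1]` by the
#' standard (n-1)-based factors, closeness using the harmonic convention
#' (unreachable pairs contribute zero); eigenvector centrality is the
#' L2-normalized magnitude of the principal eigenvector; local efficiency
#' of a node is the average inverse shortest-path length among its
#' neighbours (zero for degree < 2 and for unreachable neighbour pairs).
#'
#' @param binaryAdj symmetric 0/1 matrix with zero diagonal.
#' @param weightedAdj symmetric weighted matrix; defaults to `binaryAdj`.
#' @return an n x 8 matrix with columns `cc_ws`, `cc_onnela`, `cc_zhang`,
#'   `deg_c`, `btw_c`, `clo_c`, `eig_c`, `local_eff`.
#' @examples
#' k3 <- matrix(1, 3, 3) - diag(3)
#' nodeStatistics(k3)  # clustering 1, betweenness 0, efficiency 1
#' @export
nodeStatistics <- function(binaryAdj, weightedAdj = binaryAdj) {
  B <- as.matrix(binaryAdj)
  n <- nrow(B)
  stopifnot(ncol(B) == n, all(B %in% c(0, 1)), all(diag(B) == 0))
  Wm <- abs(as.matrix(weightedAdj))
  diag(Wm) <- 0
  if (max(Wm) > 0) Wm <- Wm / max(Wm)

  g <- igraph::graph_from_adjacency_matrix(B, mode = "undirected")
  deg <- igraph::degree(g)

  ccWs <- igraph::transitivity(g, type = "local", isolates = "zero")
  ccOn <- onnelaClustering(Wm)
  ccZh <- zhangClustering(Wm)

  degC <- if (n > 1L) deg / (n - 1L) else rep(0, n)
  btwC <- igraph::betweenness(g, directed = FALSE,
                              normalized = n > 2L)
  cloC <- igraph::harmonic_centrality(g, normalized = TRUE)
  eigC <- principalEigenvector(Wm)
  locE <- localEfficiency(B)

  out <- cbind(cc_ws = ccWs, cc_onnela = ccOn, cc_zhang = ccZh,
               deg_c = degC, btw_c = btwC, clo_c = cloC, eig_c = eigC,
               local_eff = locE)
  rownames(out) <- rownames(B)
  out
}

# Onnela et al. geometric-mean weighted clustering, weights in [0,1]
onnelaClustering <- function(W) {
  k <- rowSums(W > 0)
  W3 <- W^(1 / 3)
  num <- diag(W3 %*% W3 %*% W3)
  cc <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  pmin(pmax(cc, 0), 1)
}

# Zhang & Horvath weighted clustering, weights in [0,1]
zhangClustering <- function(W) {
  num <- diag(W %*% W %*% W)
  den <- rowSums(W)^2 - rowSums(W^2)
  cc <- ifelse(den > 1e-12, num / den, 0)
  pmin(pmax(cc, 0), 1)
}

principalEigenvector <- function(W) {
  n <- nrow(W)
  if (max(W) == 0) return(rep(0, n))
  v <- eigen(W, symmetric = TRUE)$vectors[, 1L]
  v <- abs(v)
  v / sqrt(sum(v^2))
}

# mean inverse shortest-path length within each node's neighbourhood
localEfficiency <- function(B) {
  n <- nrow(B)
  g <- igraph::graph_from_adjacency_matrix(B, mode = "undirected")
  vapply(seq_len(n), function(i) {
    nb <- which(B[i, ] > 0)
    k <- length(nb)
    if (k < 2L) return(0)
    sub <- igraph::induced_subgraph(g, nb)
    d <- igraph::distances(sub)
    inv <- 1 / d[upper.tri(d)]
    inv[!is.finite(inv)] <- 0
    2 * sum(inv) / (k * (k - 1L))
  }, numeric(1))
}
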