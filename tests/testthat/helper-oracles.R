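# Independent brute-force oracles used to validate the package's
# implementations. These deliberately share no code with the package.

# P(overlap >= r) by exhaustive enumeration of all n-subsets of 1..m,
# with the mRNA's t miRNAs fixed as 1..t. Feasible for m <= ~12.
enumHypergeomTail <- function(m, t, n, r) {
  draws <- utils::combn(m, n)
  overlap <- colSums(draws <= t)
  mean(overlap >= r)
}

# All-pairs shortest paths + path counts by BFS-free dynamic programming on
# distances (small graphs only). edges: 2-column matrix of 1-based ids.
bruteCentralities <- function(nNodes, edges) {
  adj <- matrix(FALSE, nNodes, nNodes)
  if (nrow(edges)) {
    adj[edges] <- TRUE
    adj[edges[, 2:1, drop = FALSE]] <- TRUE
  }
  D <- matrix(Inf, nNodes, nNodes)
  diag(D) <- 0
  D[adj] <- 1
  for (k in seq_len(nNodes)) for (i in seq_len(nNodes))
    for (j in seq_len(nNodes))
      if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  # number of shortest paths between every pair
  S <- matrix(0, nNodes, nNodes)
  diag(S) <- 1
  S[adj & D == 1] <- 1
  maxD <- max(D[is.finite(D)])
  if (maxD >= 2) for (len in 2:maxD) {
    for (i in seq_len(nNodes)) for (j in seq_len(nNodes)) {
      if (is.finite(D[i, j]) && D[i, j] == len) {
        pred <- which(adj[, j] & D[i, ] == len - 1)
        S[i, j] <- sum(S[i, pred])
      }
    }
  }
  deg <- rowSums(adj)
  btwRaw <- numeric(nNodes)
  for (v in seq_len(nNodes)) {
    for (s in seq_len(nNodes)) for (t in seq_len(nNodes)) {
      if (s < t && s != v && t != v && is.finite(D[s, t]) &&
          is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t]) {
        btwRaw[v] <- btwRaw[v] + S[s, v] * S[v, t] / S[s, t]
      }
    }
  }
  norm <- if (nNodes > 2) (nNodes - 1) * (nNodes - 2) / 2 else 1
  clo <- vapply(seq_len(nNodes), function(v) {
    d <- D[v, -v]
    d <- d[is.finite(d)]
    if (!length(d)) 0 else length(d) / sum(d)
  }, numeric(1))
  list(degree = deg, betweennessRaw = btwRaw,
       betweenness = btwRaw / norm, closeness = clo)
}

# Exact two-sided rank-sum p-value by full enumeration of group assignments.
enumRankSumP <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  na <- length(a)
  ranks <- rank(pooled)
  wObs <- sum(ranks[seq_len(na)]) - na * (na + 1) / 2
  splits <- utils::combn(length(pooled), na)
  wAll <- apply(splits, 2, function(idx)
    sum(ranks[idx]) - na * (na + 1) / 2)
  mu <- na * length(b) / 2
  mean(abs(wAll - mu) >= abs(wObs - mu))
}

# small random undirected simple graph as an edge matrix
randomGraphEdges <- function(nNodes, pEdge) {
  pairs <- t(utils::combn(nNodes, 2))
  pairs[stats::runif(nrow(pairs)) < pEdge, , drop = FALSE]
}
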