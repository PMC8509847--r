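# Independent brute-force graph-metric oracles used to cross-check the
# package implementation. Deliberately written from first principles
# (Floyd-Warshall, triangle counting, shortest-path counting via adjacency
# powers) without igraph.

randomAdjacency <- function(n, p) {
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  A + t(A)
}

graphToAdjacency <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
}

adjacencyToGraph <- function(A) {
  dimnames(A) <- list(sprintf("N%02d", seq_len(nrow(A))),
                      sprintf("N%02d", seq_len(nrow(A))))
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

# all-pairs shortest path lengths, Floyd-Warshall
bfDistances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

bfClustering <- function(A) {
  n <- nrow(A)
  k <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2
  ifelse(k < 2, 0, 2 * tri / (k * (k - 1)))
}

bfHarmonicL <- function(A) {
  n <- nrow(A)
  D <- bfDistances(A)
  inv <- 1 / D
  diag(inv) <- 0
  s <- sum(inv)
  if (s == 0) Inf else n * (n - 1) / s
}

bfGlobalEff <- function(A) {
  n <- nrow(A)
  inv <- 1 / bfDistances(A)
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

bfLocalEff <- function(A) {
  n <- nrow(A)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) next
    out[i] <- bfGlobalEff(A[nb, nb, drop = FALSE])
  }
  out
}

# shortest-path counts: every length-d walk between nodes at distance d is
# necessarily a shortest path, so (A^d)[s, t] counts them exactly
bfBetweenness <- function(A) {
  n <- nrow(A)
  D <- bfDistances(A)
  maxd <- max(D[is.finite(D)])
  pows <- vector("list", max(1, maxd))
  P <- A
  for (d in seq_len(max(1, maxd))) { pows[[d]] <- P; P <- P %*% A }
  sigma <- function(s, t) {
    if (s == t) return(1)
    d <- D[s, t]
    if (!is.finite(d)) return(0)
    pows[[d]][s, t]
  }
  b <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s >= t || s == i || t == i) next
      st <- sigma(s, t)
      if (st == 0) next
      if (is.finite(D[s, i]) && is.finite(D[i, t]) &&
          D[s, i] + D[i, t] == D[s, t])
        acc <- acc + sigma(s, i) * sigma(i, t) / st
    }
    b[i] <- acc / ((n - 1) * (n - 2) / 2)
  }
  b
}

bfParticipation <- function(A, membership) {
  n <- nrow(A)
  y <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(A[i, ])
    if (k == 0) next
    acc <- 0
    for (m in unique(membership))
      acc <- acc + (sum(A[i, membership == m]) / k)^2
    y[i] <- 1 - acc
  }
  y
}

bfWithinModuleZ <- function(A, membership) {
  n <- nrow(A)
  z <- numeric(n)
  for (m in unique(membership)) {
    idx <- which(membership == m)
    kin <- vapply(idx, function(i) sum(A[i, idx]), numeric(1))
    mu <- mean(kin)
    sdp <- sqrt(mean((kin - mu)^2))
    z[idx] <- if (length(idx) < 2 || sdp == 0) 0 else (kin - mu) / sdp
  }
  z
}

# exhaustive sign-permutation p-value by direct enumeration over sign
# vectors built with expand.grid (independent of the package's bit tricks)
bfSignPermP <- function(diffs) {
  n <- length(diffs)
  S <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  Dp <- S %*% diffs / n
  D <- mean(diffs)
  if (D >= 0) mean(Dp >= D - 1e-12) else mean(Dp <= D + 1e-12)
}
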