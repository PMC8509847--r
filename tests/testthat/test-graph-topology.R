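connMat <- function(V) {
  V <- (V + t(V)) / 2
  V <- pmin(pmax(V, -1), 1)
  diag(V) <- 1
  new("ConnectivityMatrix", values = V, bandIndex = 1L, subjectId = "s01",
      session = "pre", nVolumesUsed = 100L)
}

test_that("density thresholding keeps the strongest positive connections", {
  set.seed(1)
  n <- 76
  W <- matrix(runif(n * n, 0.01, 1), n, n)     # all positive
  g <- thresholdByDensity(connMat(W), 0.10)
  expect_equal(igraph::gsize(g), 285)           # 10% of 2850
  gfull <- thresholdByDensity(connMat(W), 1.0)
  expect_equal(igraph::gsize(gfull), 2850)      # complete graph
  # 4-node toy with ties at the cutoff: weights 0.9, 0.8, 0.8, 0.1, -0.5, -0.9
  Wt <- matrix(0, 4, 4)
  Wt[1, 2] <- 0.9; Wt[1, 3] <- 0.8; Wt[1, 4] <- 0.8
  Wt[2, 3] <- 0.1; Wt[2, 4] <- -0.5; Wt[3, 4] <- -0.9
  gt <- thresholdByDensity(connMat(Wt), 0.5)    # target 3 of 6
  expect_equal(igraph::gsize(gt), 3)
  A <- graphToAdjacency(gt)
  expect_equal(A[1, 2], 1); expect_equal(A[1, 3], 1); expect_equal(A[1, 4], 1)
  # negatives never selected even when positives run short
  Wn <- matrix(-0.5, 4, 4); Wn[1, 2] <- 0.3; Wn[2, 1] <- 0.3
  expect_warning(gn <- thresholdByDensity(connMat(Wn), 0.5),
                 "positive weights")
  expect_equal(igraph::gsize(gn), 1)
})

test_that("edge sets are nested along the density grid", {
  set.seed(2)
  n <- 30
  W <- matrix(rnorm(n * n, 0.2, 0.4), n, n)
  stack <- densityGraphStack(connMat(W), seq(0.10, 0.50, by = 0.05))
  els <- lapply(stackGraphs(stack), function(g)
    apply(igraph::as_edgelist(g, names = FALSE), 1, function(e)
      paste(sort(e), collapse = "-")))
  for (k in seq_len(length(els) - 1))
    expect_true(all(els[[k]] %in% els[[k + 1]]))
})

test_that("clustering, path length and efficiency match hand-computed toys", {
  tri <- adjacencyToGraph(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))
  expect_equal(unname(nodalClustering(tri)), rep(1, 3))
  star <- makeToyGraph("star", n = 5)
  expect_equal(unname(nodalClustering(star))[1], 0)
  # K4 minus one edge: degree-3 nodes have C = 2/3 and Eloc = mean(1,1,1/2)...
  A <- matrix(1, 4, 4) - diag(4); A[3, 4] <- 0; A[4, 3] <- 0
  k4m <- adjacencyToGraph(A)
  expect_equal(unname(nodalClustering(k4m))[1], 2 / 3)
  expect_equal(unname(localEfficiency(k4m))[1], bfLocalEff(A)[1])
  # harmonic path lengths
  p3 <- makeToyGraph("path", n = 3)
  expect_equal(characteristicPathLength(p3), 6 / 5)
  expect_equal(globalEfficiency(p3), 5 / 6)
  k5 <- makeToyGraph("complete", n = 5)
  expect_equal(characteristicPathLength(k5), 1)
  expect_equal(globalEfficiency(k5), 1)
  expect_equal(unname(localEfficiency(k5)), rep(1, 5))
  expect_equal(unname(localEfficiency(star))[1], 0)
  # two disjoint edges: disconnected pairs contribute 0
  A2 <- matrix(0, 4, 4); A2[1, 2] <- A2[2, 1] <- 1; A2[3, 4] <- A2[4, 3] <- 1
  expect_equal(characteristicPathLength(adjacencyToGraph(A2)), 3)
  # empty graph
  A0 <- matrix(0, 3, 3)
  expect_equal(globalEfficiency(adjacencyToGraph(A0)), 0)
  expect_equal(characteristicPathLength(adjacencyToGraph(A0)), Inf)
})

test_that("betweenness centrality is the normalized shortest-path fraction", {
  p3 <- makeToyGraph("path", n = 3)
  expect_equal(unname(betweennessCentrality(p3))[2], 1)
  star5 <- makeToyGraph("star", n = 5)
  expect_equal(unname(betweennessCentrality(star5))[1], 1)
  c4 <- adjacencyToGraph(matrix(c(0, 1, 0, 1, 1, 0, 1, 0, 0, 1, 0, 1,
                                  1, 0, 1, 0), 4))
  expect_equal(unname(betweennessCentrality(c4)), rep(1 / 6, 4))
})

test_that("degree and strength count connections and sum weights", {
  set.seed(3)
  W <- matrix(runif(16, 0.1, 1), 4, 4)
  C <- connMat(W)
  g <- thresholdByDensity(C, 1.0)
  ds <- degreeAndStrength(g)
  expect_equal(ds$degree, rep(3L, 4))
  expect_equal(ds$strength, rowSums(bandValues(C)) - 1, tolerance = 1e-12,
               ignore_attr = TRUE)
  iso <- adjacencyToGraph(matrix(0, 3, 3))
  expect_equal(degreeAndStrength(iso)$degree, rep(0L, 3))
})

test_that("module detection recovers planted structure", {
  # two disjoint K5s
  A <- matrix(0, 10, 10)
  A[1:5, 1:5] <- 1; A[6:10, 6:10] <- 1; diag(A) <- 0
  m <- detectModules(adjacencyToGraph(A))
  expect_equal(length(unique(m)), 2)
  expect_true(all(m[1:5] == m[1]) && all(m[6:10] == m[6]))
  # complete graph collapses to one module
  mk <- detectModules(makeToyGraph("complete", n = 6))
  expect_equal(length(unique(mk)), 1)
  # edgeless graph: every node its own module
  m0 <- detectModules(adjacencyToGraph(matrix(0, 4, 4)))
  expect_equal(length(unique(m0)), 4)
  # planted two-block graph: Rand index vs truth >= 0.95
  set.seed(9)
  n <- 40
  truth <- rep(1:2, each = 20)
  P <- ifelse(outer(truth, truth, "=="), 0.9, 0.05)
  A2 <- matrix(0, n, n)
  A2[upper.tri(A2)] <- rbinom(n * (n - 1) / 2, 1, P[upper.tri(P)])
  A2 <- A2 + t(A2)
  mm <- detectModules(adjacencyToGraph(A2))
  pairsAgree <- function(a, b) {
    sameA <- outer(a, a, "==")[upper.tri(diag(length(a)))]
    sameB <- outer(b, b, "==")[upper.tri(diag(length(b)))]
    mean(sameA == sameB)
  }
  expect_gte(pairsAgree(mm, truth), 0.95)
})

test_that("participation coefficient follows the within-module degree formula", {
  # all edges inside one module -> 0
  A <- matrix(0, 6, 6); A[1, 2] <- A[2, 1] <- 1; A[1, 3] <- A[3, 1] <- 1
  g <- adjacencyToGraph(A)
  expect_equal(unname(participationCoefficient(g, c(1, 1, 1, 2, 2, 2)))[1], 0)
  # degree 4 split 2/2 across two modules -> 0.5
  A2 <- matrix(0, 5, 5); A2[1, 2:5] <- 1; A2[2:5, 1] <- 1
  g2 <- adjacencyToGraph(A2)
  expect_equal(unname(participationCoefficient(g2, c(1, 1, 1, 2, 2)))[1], 0.5)
  # degree 3 split 1/1/1 across three modules -> 2/3
  A3 <- matrix(0, 4, 4); A3[1, 2:4] <- 1; A3[2:4, 1] <- 1
  g3 <- adjacencyToGraph(A3)
  expect_equal(unname(participationCoefficient(g3, c(1, 1, 2, 3)))[1], 2 / 3)
  # isolated node -> 0
  expect_equal(unname(participationCoefficient(g3, c(1, 1, 2, 3)))[
    which(igraph::degree(g3) == 0)], numeric(0))
})

test_that("within-module degree z-score uses the population SD", {
  # module = star of 4 nodes: within-degrees 3,1,1,1 -> center z = 1.732
  A <- matrix(0, 4, 4); A[1, 2:4] <- 1; A[2:4, 1] <- 1
  g <- adjacencyToGraph(A)
  wz <- withinModuleDegreeZ(g, rep(1, 4))
  expect_equal(wz$z[1], (3 - 1.5) / sqrt(mean((c(3, 1, 1, 1) - 1.5)^2)),
               tolerance = 1e-12)
  expect_equal(wz$z[1], 1.732, tolerance = 1e-3)
  # clique module: SD = 0 -> all z = 0
  k4 <- makeToyGraph("complete", n = 4)
  expect_equal(withinModuleDegreeZ(k4, rep(1, 4))$z, rep(0, 4))
  # singleton module warns and returns 0
  expect_warning(wz2 <- withinModuleDegreeZ(g, c(1, 1, 1, 2)), "singleton")
  expect_equal(wz2$z[4], 0)
})

test_that("random references preserve the degree sequence exactly", {
  g <- makeToyGraph("watts_strogatz", n = 40, k = 6, p = 0.2, seed = 4)
  set.seed(10)
  for (r in 1:5) {
    gr <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 * igraph::gsize(g)))
    expect_equal(igraph::degree(gr), igraph::degree(g))
  }
  # complete graphs cannot be rewired: references equal the graph itself
  k5 <- makeToyGraph("complete", n = 5)
  ref <- randomReference(k5, nRand = 5, seed = 1)
  expect_equal(unname(ref), c(1, 1))
  gm <- globalMetrics(k5, nRand = 5, seed = 1)
  expect_equal(gm$sigma, 1)
  expect_equal(gm$Cnorm, 1)
})

test_that("lattices are more clustered than degree-matched random graphs", {
  g <- makeToyGraph("ring_lattice", n = 76, k = 8)
  ref <- randomReference(g, nRand = 100, seed = 2)
  expect_gt(mean(nodalClustering(g)) / ref[["Crand"]], 1)
})

test_that("smallworldness separates small-world from random topologies", {
  ws <- makeToyGraph("watts_strogatz", n = 76, k = 8, p = 0.1, seed = 5)
  expect_gt(smallworldness(ws, nRand = 50, seed = 1), 1)
  er <- makeToyGraph("erdos_renyi", n = 76, p = 8 / 75, seed = 6)
  expect_equal(smallworldness(er, nRand = 50, seed = 1), 1, tolerance = 0.2)
})

test_that("metric AUC is the mean over a uniform density grid", {
  mc <- new("MetricCurve", metric = "Cnet", densities = seq(0.1, 0.5, 0.1),
            values = rep(0.42, 5), auc = mean(rep(0.42, 5)))
  expect_equal(aucOf(mc), 0.42)
  set.seed(11)
  W <- matrix(runif(20 * 20, 0.05, 1), 20, 20)
  stack <- densityGraphStack(connMat(W), seq(0.1, 0.5, by = 0.1))
  curves <- metricCurves(stack, metrics = c("Cnet", "degree"))
  expect_equal(aucOf(curves$Cnet), mean(curves$Cnet@values))
  expect_equal(aucOf(curves$degree), rowMeans(curves$degree@values),
               ignore_attr = TRUE)
  # mean degree grows linearly with density on an all-positive matrix
  # (edge counts 19, 38, 57, 76, 95), so its AUC equals the midpoint value
  expect_equal(mean(aucOf(curves$degree)),
               mean(curves$degree@values[, 3]), tolerance = 1e-12)
  single <- densityGraphStack(connMat(W), 0.3)
  c1 <- metricCurves(single, metrics = "Cnet")
  expect_equal(aucOf(c1$Cnet), c1$Cnet@values[1])
  # non-uniform grids are refused
  bad <- densityGraphStack(connMat(W), c(0.1, 0.2, 0.4))
  expect_error(metricCurves(bad, metrics = "Cnet"), "uniform")
})

test_that("graph export round-trips as edge list", {
  set.seed(12)
  W <- matrix(runif(36, 0.1, 1), 6, 6)
  g <- thresholdByDensity(connMat(W), 0.5)
  f <- tempfile(fileext = ".tsv")
  writeGraphTsv(g, f)
  el <- read.delim(f)
  expect_equal(nrow(el), igraph::gsize(g))
  expect_true(all(c("i_label", "j_label", "weight") %in% names(el)))
})
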