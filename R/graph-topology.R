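#' @importFrom igraph graph_from_adjacency_matrix gorder gsize distances
#'   transitivity degree strength betweenness neighbors induced_subgraph
#'   cluster_fast_greedy membership rewire keeping_degseq V ecount
#'   components E
NULL

.roundHalfAway <- function(x) trunc(x + 0.5 * sign(x))

#' Proportional (density) thresholding of a connectivity matrix
#'
#' Keeps the strongest positive connections as binary edges: the target edge
#' count is \code{density} times the number of unique pairs (rounded half
#' away from zero). Negative and zero weights are never selected, even if
#' that leaves the graph below the target count (a warning reports the
#' shortfall). Ties at the cutoff weight are admitted in a fixed
#' lexicographic (i, j) order until the target count is reached, which makes
#' thresholding deterministic and edge sets nested across a density grid.
#'
#' @param C a [ConnectivityMatrix-class] or symmetric numeric matrix.
#' @param density fraction of possible edges to keep, in (0, 1].
#' @return An undirected \pkg{igraph} graph with the source weight stored on
#'   each edge as attribute \code{weight}.
#' @export
thresholdByDensity <- function(C, density) {
  stopifnot(density > 0, density <= 1)
  W <- if (is(C, "ConnectivityMatrix")) C@values else as.matrix(C)
  n <- nrow(W)
  pairs <- .edgePairs(n)
  w <- W[upper.tri(W)]
  npairs <- length(w)
  target <- .roundHalfAway(density * npairs)
  pos <- which(w > 0)
  keep <- integer(0)
  if (length(pos) == 0L) {
    warning("no positive weights; returning an empty graph")
  } else if (length(pos) <= target) {
    if (length(pos) < target)
      warning(sprintf("only %d positive weights available for a target of %d edges",
                      length(pos), target))
    keep <- pos
  } else {
    wp <- w[pos]
    cutoff <- sort(wp, decreasing = TRUE)[target]
    above <- pos[w[pos] > cutoff]
    ties <- pos[w[pos] == cutoff]
    # lexicographic (i, j) order among cutoff ties
    ties <- ties[order(pairs[ties, 1], pairs[ties, 2])]
    keep <- c(above, ties[seq_len(target - length(above))])
  }
  Wmask <- matrix(0, n, n)
  Wmask[cbind(pairs[keep, 1], pairs[keep, 2])] <- w[keep]
  Wmask <- Wmask + t(Wmask)
  dimnames(Wmask) <- dimnames(W)
  if (is.null(rownames(Wmask)))
    dimnames(Wmask) <- list(sprintf("R%02d", 1:n), sprintf("R%02d", 1:n))
  # kept weights are strictly positive, so the weighted adjacency encodes
  # exactly the selected edge set
  igraph::graph_from_adjacency_matrix(Wmask, mode = "undirected",
                                      weighted = if (length(keep)) TRUE else NULL)
}

#' Graphs over a density grid
#'
#' Applies [thresholdByDensity()] at each density of a uniform grid
#' (default 10\% to 50\% in steps of 1\%), the range over which small-world
#' topology is summarized by AUC.
#'
#' @param C a [ConnectivityMatrix-class].
#' @param densities strictly increasing density grid within (0, 1].
#' @return A [DensityGraphStack-class].
#' @export
densityGraphStack <- function(C, densities = seq(0.10, 0.50, by = 0.01)) {
  stopifnot(is(C, "ConnectivityMatrix"))
  graphs <- lapply(densities, function(d) thresholdByDensity(C, d))
  new("DensityGraphStack", source = C, densities = densities, graphs = graphs)
}

#' Nodal clustering coefficient
#'
#' Ratio of closed triangles to connected triples at each node,
#' \eqn{C_i = 2 t_i / (k_i (k_i - 1))}; 0 for nodes of degree < 2.
#'
#' @param g an undirected \pkg{igraph} graph.
#' @return Numeric vector over nodes.
#' @export
nodalClustering <- function(g) {
  ci <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  names(ci) <- igraph::V(g)$name
  ci
}

#' Harmonic characteristic path length
#'
#' \eqn{L_{net} = n(n-1) / \sum_{i \ne j} d_{ij}^{-1}} over ordered pairs;
#' disconnected pairs contribute 0 to the sum (their reciprocal distance is
#' 0), so the measure stays finite on disconnected graphs with at least one
#' edge. A graph with no edges returns \code{Inf}.
#'
#' @param g an undirected \pkg{igraph} graph with at least 2 nodes.
#' @return Scalar path length (>= 1 for any graph with an edge).
#' @export
characteristicPathLength <- function(g) {
  n <- igraph::gorder(g)
  stopifnot(n >= 2)
  inv <- 1 / igraph::distances(g, weights = NA)
  diag(inv) <- 0
  s <- sum(inv)
  if (s == 0) return(Inf)
  n * (n - 1) / s
}

#' Global efficiency
#'
#' Mean of \eqn{1/d_{ij}} over ordered pairs (0 for disconnected pairs).
#'
#' @inheritParams characteristicPathLength
#' @return Scalar in [0, 1].
#' @export
globalEfficiency <- function(g) {
  n <- igraph::gorder(g)
  stopifnot(n >= 2)
  inv <- 1 / igraph::distances(g, weights = NA)
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Nodal local efficiency
#'
#' For each node, the global efficiency of the subgraph induced by its
#' one-hop neighborhood: the mean reciprocal shortest-path length between
#' its neighbors, with paths restricted to the neighborhood. 0 for nodes of
#' degree < 2.
#'
#' @inheritParams characteristicPathLength
#' @return Numeric vector over nodes, each in [0, 1].
#' @export
localEfficiency <- function(g) {
  n <- igraph::gorder(g)
  out <- numeric(n)
  names(out) <- igraph::V(g)$name
  for (i in seq_len(n)) {
    nb <- as.integer(igraph::neighbors(g, i))
    k <- length(nb)
    if (k < 2) next
    sub <- igraph::induced_subgraph(g, nb)
    inv <- 1 / igraph::distances(sub, weights = NA)
    diag(inv) <- 0
    out[i] <- sum(inv) / (k * (k - 1))
  }
  out
}

#' Normalized betweenness centrality
#'
#' Fraction of all shortest paths that pass through each node, normalized by
#' the number of outside pairs \eqn{(n-1)(n-2)/2} so values lie in [0, 1].
#'
#' @param g an undirected \pkg{igraph} graph with at least 3 nodes.
#' @return Numeric vector over nodes.
#' @export
betweennessCentrality <- function(g) {
  n <- igraph::gorder(g)
  stopifnot(n >= 3)
  b <- igraph::betweenness(g, directed = FALSE, weights = NA)
  b / ((n - 1) * (n - 2) / 2)
}

#' Degree and strength
#'
#' Degree counts binary connections at each node; strength sums the source
#' connectivity weights over those connections (equal to degree when the
#' graph carries no weights).
#'
#' @param g an undirected \pkg{igraph} graph.
#' @return data.frame with columns \code{degree} and \code{strength}.
#' @export
degreeAndStrength <- function(g) {
  k <- igraph::degree(g)
  s <- if ("weight" %in% igraph::edge_attr_names(g))
    igraph::strength(g) else as.numeric(k)
  data.frame(degree = as.integer(k), strength = s,
             row.names = igraph::V(g)$name)
}

#' Module (community) detection
#'
#' Non-overlapping covering partition by greedy modularity maximization
#' (deterministic; the seed argument is accepted for interface uniformity).
#' An edgeless graph puts every node in its own module.
#'
#' @param g an undirected \pkg{igraph} graph.
#' @param seed unused by the greedy method; kept for a stable interface.
#' @return Integer module assignment vector over nodes.
#' @export
detectModules <- function(g, seed = 1L) {
  n <- igraph::gorder(g)
  if (igraph::gsize(g) == 0L) {
    m <- seq_len(n)
  } else {
    # weights = NA: modules are detected on the binary topology even when
    # the graph carries source connectivity weights
    m <- as.integer(igraph::membership(
      igraph::cluster_fast_greedy(g, weights = NA)))
    # the greedy merge can stop short of the trivial partition even when
    # that one has higher modularity (Q = 0, e.g., complete graphs)
    if (igraph::modularity(g, m, weights = rep(1, igraph::gsize(g))) <= 0)
      m <- rep(1L, n)
  }
  names(m) <- igraph::V(g)$name
  m
}

#' Participation coefficient
#'
#' \eqn{y_i = 1 - \sum_m (k_i^{(m)} / k_i)^2}, where \eqn{k_i^{(m)}} counts
#' node i's connections into module m: 0 when all of a node's connections
#' stay inside one module, approaching 1 when they spread evenly across
#' modules. Nodes with degree 0 get 0.
#'
#' @param g an undirected \pkg{igraph} graph.
#' @param membership integer module assignment covering all nodes.
#' @return Numeric vector over nodes, each in [0, 1].
#' @export
participationCoefficient <- function(g, membership) {
  n <- igraph::gorder(g)
  stopifnot(length(membership) == n)
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  k <- rowSums(A)
  mods <- sort(unique(membership))
  km2 <- matrix(0, n, length(mods))
  for (mi in seq_along(mods))
    km2[, mi] <- rowSums(A[, membership == mods[mi], drop = FALSE])^2
  y <- ifelse(k == 0, 0, 1 - rowSums(km2) / k^2)
  names(y) <- igraph::V(g)$name
  y
}

#' Within-module degree and its z-score
#'
#' Standardizes each node's within-module degree against the mean and
#' population standard deviation (divide by module size) of within-module
#' degrees in its own module. Modules with zero spread give z = 0; singleton
#' modules give z = 0 with a warning.
#'
#' @inheritParams participationCoefficient
#' @return data.frame with columns \code{withinDegree} and \code{z}.
#' @export
withinModuleDegreeZ <- function(g, membership) {
  n <- igraph::gorder(g)
  stopifnot(length(membership) == n)
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  kw <- numeric(n)
  z <- numeric(n)
  for (m in unique(membership)) {
    idx <- which(membership == m)
    kin <- rowSums(A[idx, idx, drop = FALSE])
    kw[idx] <- kin
    if (length(idx) < 2L) {
      warning(sprintf("singleton module %s: z-score undefined, set to 0", m))
      z[idx] <- 0
      next
    }
    sdp <- sqrt(mean((kin - mean(kin))^2))
    z[idx] <- if (sdp == 0) 0 else (kin - mean(kin)) / sdp
  }
  data.frame(withinDegree = as.integer(kw), z = z,
             row.names = igraph::V(g)$name)
}

#' Degree-preserving random-network reference
#'
#' Mean clustering coefficient and harmonic path length over \code{nRand}
#' rewired graphs with the same number of nodes, edges and degree sequence
#' as \code{g} (double-edge swaps, 10 |E| attempted swaps per sample).
#' Graphs admitting no swap (e.g., complete graphs) return their own
#' metrics.
#'
#' @param g an undirected \pkg{igraph} graph with at least 2 edges.
#' @param nRand number of rewired reference graphs (default 100).
#' @param seed integer seed; the whole reference set is reproducible.
#' @return Named numeric vector \code{c(Crand, Lrand)}.
#' @export
randomReference <- function(g, nRand = 100L, seed = 1L) {
  stopifnot(igraph::gsize(g) >= 2)
  niter <- 10L * igraph::gsize(g)
  set.seed(seed)
  cs <- numeric(nRand)
  ls <- numeric(nRand)
  for (r in seq_len(nRand)) {
    gr <- igraph::rewire(g, igraph::keeping_degseq(niter = niter))
    cs[r] <- mean(nodalClustering(gr))
    ls[r] <- characteristicPathLength(gr)
  }
  c(Crand = mean(cs), Lrand = mean(ls))
}

#' Smallworldness
#'
#' \eqn{\sigma = (C_{net}/C_{rand}) / (L_{net}/L_{rand})} with random-network
#' normalization from [randomReference()]; \eqn{\sigma > 1} indicates
#' small-world organization (high clustering with short paths).
#'
#' @inheritParams randomReference
#' @return Scalar sigma.
#' @export
smallworldness <- function(g, nRand = 100L, seed = 1L) {
  globalMetrics(g, nRand = nRand, seed = seed)[["sigma"]]
}

#' All global topological metrics of one graph
#'
#' @inheritParams randomReference
#' @return Named list: \code{Cnet} (mean nodal clustering), \code{Lnet}
#'   (harmonic characteristic path length), \code{Eglob}, \code{Crand},
#'   \code{Lrand}, \code{Cnorm}, \code{Lnorm}, \code{sigma}.
#' @export
globalMetrics <- function(g, nRand = 100L, seed = 1L) {
  Cnet <- mean(nodalClustering(g))
  Lnet <- characteristicPathLength(g)
  Eglob <- globalEfficiency(g)
  ref <- randomReference(g, nRand = nRand, seed = seed)
  Cnorm <- Cnet / ref[["Crand"]]
  Lnorm <- Lnet / ref[["Lrand"]]
  list(Cnet = Cnet, Lnet = Lnet, Eglob = Eglob,
       Crand = ref[["Crand"]], Lrand = ref[["Lrand"]],
       Cnorm = Cnorm, Lnorm = Lnorm, sigma = Cnorm / Lnorm)
}

#' All nodal topological metrics of one graph
#'
#' The modularity partition is detected once and shared by the participation
#' coefficient and within-module degree z-score.
#'
#' @param g an undirected \pkg{igraph} graph.
#' @param membership optional precomputed module assignment; detected with
#'   [detectModules()] when missing.
#' @param seed passed to [detectModules()].
#' @return data.frame over nodes: \code{clustering}, \code{localEfficiency},
#'   \code{degree}, \code{strength}, \code{betweenness},
#'   \code{participation}, \code{withinDegree}, \code{withinModuleZ},
#'   \code{module}.
#' @export
nodalMetrics <- function(g, membership = NULL, seed = 1L) {
  if (is.null(membership)) membership <- detectModules(g, seed = seed)
  ds <- degreeAndStrength(g)
  wz <- suppressWarnings(withinModuleDegreeZ(g, membership))
  data.frame(
    clustering = nodalClustering(g),
    localEfficiency = localEfficiency(g),
    degree = ds$degree,
    strength = ds$strength,
    betweenness = betweennessCentrality(g),
    participation = participationCoefficient(g, membership),
    withinDegree = wz$withinDegree,
    withinModuleZ = wz$z,
    module = as.integer(membership),
    row.names = igraph::V(g)$name
  )
}

#' Metric curves and AUC over a density grid
#'
#' Evaluates the requested global and nodal metrics on every graph of a
#' [DensityGraphStack-class]. On a uniformly sampled grid the area under the
#' curve reduces to the arithmetic mean across densities, which is how every
#' AUC here is computed.
#'
#' @param stack a [DensityGraphStack-class] (uniform density grid).
#' @param metrics character vector among \code{"Cnet"}, \code{"Lnet"},
#'   \code{"Eglob"}, \code{"Cnorm"}, \code{"Lnorm"}, \code{"sigma"}
#'   (global) and \code{"clustering"}, \code{"localEfficiency"},
#'   \code{"degree"}, \code{"strength"}, \code{"betweenness"},
#'   \code{"participation"}, \code{"withinModuleZ"} (nodal).
#' @param nRand,seed passed to [globalMetrics()] when a normalized global
#'   metric is requested.
#' @return Named list of [MetricCurve-class] objects.
#' @export
metricCurves <- function(stack,
                         metrics = c("Cnet", "Lnet", "sigma", "degree"),
                         nRand = 100L, seed = 1L) {
  stopifnot(is(stack, "DensityGraphStack"))
  dgrid <- stack@densities
  if (length(dgrid) > 1L) {
    steps <- diff(dgrid)
    if (max(abs(steps - steps[1])) > 1e-9)
      stop("metricCurves requires a uniform density grid")
  }
  globalNames <- c("Cnet", "Lnet", "Eglob", "Cnorm", "Lnorm", "sigma")
  nodalNames <- c("clustering", "localEfficiency", "degree", "strength",
                  "betweenness", "participation", "withinModuleZ")
  bad <- setdiff(metrics, c(globalNames, nodalNames))
  if (length(bad)) stop("unknown metric(s): ", paste(bad, collapse = ", "))
  needNorm <- any(metrics %in% c("Cnorm", "Lnorm", "sigma"))
  glob <- lapply(seq_along(stack@graphs), function(ii) {
    g <- stack@graphs[[ii]]
    if (needNorm) globalMetrics(g, nRand = nRand, seed = seed + ii)
    else list(Cnet = mean(nodalClustering(g)),
              Lnet = characteristicPathLength(g),
              Eglob = globalEfficiency(g))
  })
  nod <- if (any(metrics %in% nodalNames))
    lapply(stack@graphs, function(g) nodalMetrics(g)) else NULL
  out <- list()
  for (m in metrics) {
    if (m %in% globalNames) {
      v <- vapply(glob, function(x) x[[m]], numeric(1))
      out[[m]] <- new("MetricCurve", metric = m, densities = dgrid,
                      values = v, auc = mean(v))
    } else {
      M <- vapply(nod, function(df) df[[m]], numeric(nrow(nod[[1]])))
      M <- matrix(M, nrow = nrow(nod[[1]]),
                  dimnames = list(rownames(nod[[1]]), NULL))
      out[[m]] <- new("MetricCurve", metric = m, densities = dgrid,
                      values = M, auc = rowMeans(M))
    }
  }
  out
}

#' Export a graph as edge-list or adjacency TSV
#'
#' @param g an undirected \pkg{igraph} graph.
#' @param path output file.
#' @param what \code{"edgelist"} (columns i_label, j_label, weight) or
#'   \code{"adjacency"}.
#' @return \code{path}, invisibly.
#' @export
writeGraphTsv <- function(g, path, what = c("edgelist", "adjacency")) {
  what <- match.arg(what)
  if (what == "edgelist") {
    el <- igraph::as_edgelist(g)
    w <- if ("weight" %in% igraph::edge_attr_names(g))
      igraph::E(g)$weight else rep(1, nrow(el))
    df <- data.frame(i_label = el[, 1], j_label = el[, 2], weight = w)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
    utils::write.table(data.frame(region = rownames(A), A,
                                  check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
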