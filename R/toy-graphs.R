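#' Toy graphs with known topology
#'
#' Small graph families used as fixtures with closed-form or easily
#' enumerated metric values: ring lattices (every node linked to its k
#' nearest ring neighbors, clustering \eqn{3(k-2)/(4(k-1))}), Watts-Strogatz
#' rewirings of a ring lattice, Erdos-Renyi random graphs, and complete,
#' star and path graphs.
#'
#' @param kind one of \code{"ring_lattice"}, \code{"watts_strogatz"},
#'   \code{"erdos_renyi"}, \code{"complete"}, \code{"star"}, \code{"path"}.
#' @param n number of nodes.
#' @param k even neighbor count for ring-lattice families (k/2 on each side).
#' @param p rewiring probability (Watts-Strogatz) or edge probability
#'   (Erdos-Renyi).
#' @param seed integer seed for the stochastic families.
#' @return A simple undirected \pkg{igraph} graph.
#' @examples
#' g <- makeToyGraph("ring_lattice", n = 76, k = 4)
#' unique(round(nodalClustering(g), 10))  # 3(k-2)/(4(k-1)) = 0.5
#' @export
makeToyGraph <- function(kind = c("ring_lattice", "watts_strogatz",
                                  "erdos_renyi", "complete", "star", "path"),
                         n, k = 4L, p = 0.1, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(n >= 2)
  if (kind %in% c("ring_lattice", "watts_strogatz")) {
    if (k %% 2 != 0 || k < 2)
      stop("ring-lattice neighbor count k must be a positive even number")
    if (k >= n) stop("k must be smaller than n")
  }
  g <- switch(kind,
    ring_lattice = igraph::sample_smallworld(1, n, k / 2, 0),
    watts_strogatz = {
      stopifnot(p >= 0, p <= 1)
      set.seed(seed)
      igraph::sample_smallworld(1, n, k / 2, p)
    },
    erdos_renyi = {
      stopifnot(p >= 0, p <= 1)
      set.seed(seed)
      igraph::sample_gnp(n, p)
    },
    complete = igraph::make_full_graph(n),
    star = igraph::make_star(n, mode = "undirected", center = 1),
    path = igraph::make_ring(n, circular = FALSE)
  )
  g <- igraph::simplify(g)
  igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
  g
}
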