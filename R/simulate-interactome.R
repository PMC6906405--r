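#' Simulate a background interactome with a planted seed module
#'
#' Grows a scale-free background network by preferential attachment
#' (heavy-tailed degree distribution, as in real protein interactomes)
#' and plants a dense module: a random set of nodes whose missing
#' within-module edges are each added with probability
#' \code{seed_module_extra_edge_prob}. The planted nodes are returned
#' as the seed gene list, so the topology test's alternative hypothesis
#' (a more clustered, tighter module than degree-matched chance) is
#' realizable on synthetic data.
#'
#' @param n_nodes Number of nodes in the background graph.
#' @param attachment_edges Edges added per node during
#'   preferential-attachment growth (1 gives a tree).
#' @param seed_module_size Number of planted module nodes (0 disables
#'   planting); must not exceed \code{n_nodes}.
#' @param seed_module_extra_edge_prob Probability in [0, 1] for each
#'   within-module node pair to receive an edge (on top of background
#'   edges); 1 forces a clique.
#' @param rng_seed Integer seed; identical seeds give identical graphs.
#' @return List with \code{graph} (named \code{igraph} simple graph,
#'   vertices \code{P00001}, ...) and \code{seeds} (sorted character
#'   vector of planted module nodes).
#' @examples
#' sim <- simulate_interactome(200, attachment_edges = 2,
#'                             seed_module_size = 12,
#'                             seed_module_extra_edge_prob = 0.4,
#'                             rng_seed = 7)
#' igraph::vcount(sim$graph)
#' @export
simulate_interactome <- function(n_nodes, attachment_edges = 2,
                                 seed_module_size = 0,
                                 seed_module_extra_edge_prob = 0,
                                 rng_seed = 1L) {
  if (n_nodes < 1) stop_param("n_nodes must be >= 1")
  if (attachment_edges < 1) stop_param("attachment_edges must be >= 1")
  if (seed_module_size > n_nodes)
    stop_param("seed_module_size exceeds n_nodes")
  check_prob(seed_module_extra_edge_prob, "seed_module_extra_edge_prob")
  set.seed(rng_seed)
  g <- igraph::sample_pa(n_nodes, power = 1, m = attachment_edges,
                         directed = FALSE)
  ids <- sprintf("P%05d", seq_len(n_nodes))
  igraph::V(g)$name <- ids
  seeds <- character(0)
  if (seed_module_size > 0) {
    seeds <- sort(sample(ids, seed_module_size))
    if (seed_module_size >= 2 && seed_module_extra_edge_prob > 0) {
      pairs <- utils::combn(seeds, 2)
      add <- stats::runif(ncol(pairs)) < seed_module_extra_edge_prob
      if (any(add))
        g <- igraph::add_edges(g, as.vector(pairs[, add, drop = FALSE]))
    }
  }
  g <- igraph::simplify(g)
  list(graph = g, seeds = seeds)
}
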