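# Independent brute-force oracles, deliberately written against plain
# edge lists / adjacency lists so they share no code with the
# implementation under test.

# adjacency list from a 2-column character edge matrix
oracle_adj <- function(nodes, edges) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  if (nrow(edges) > 0) {
    for (i in seq_len(nrow(edges))) {
      a <- edges[i, 1]; b <- edges[i, 2]
      adj[[a]] <- union(adj[[a]], b)
      adj[[b]] <- union(adj[[b]], a)
    }
  }
  adj
}

# connected components by BFS flood fill; returns list of node vectors
oracle_components <- function(nodes, edges) {
  adj <- oracle_adj(nodes, edges)
  seen <- character(0); comps <- list()
  for (v in nodes) {
    if (v %in% seen) next
    queue <- v; comp <- character(0)
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      if (u %in% comp) next
      comp <- c(comp, u)
      queue <- c(queue, setdiff(adj[[u]], comp))
    }
    comps[[length(comps) + 1]] <- sort(comp)
    seen <- c(seen, comp)
  }
  comps
}

# all-pairs BFS shortest-path mean over unordered pairs (connected graph)
oracle_apl <- function(nodes, edges) {
  adj <- oracle_adj(nodes, edges)
  total <- 0; npair <- 0
  for (i in seq_along(nodes)) {
    dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
    dist[nodes[i]] <- 0
    queue <- nodes[i]
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      for (w in adj[[u]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[u] + 1
          queue <- c(queue, w)
        }
      }
    }
    if (i < length(nodes)) {
      others <- nodes[(i + 1):length(nodes)]
      total <- total + sum(dist[others]); npair <- npair + length(others)
    }
  }
  total / npair
}

# mean local clustering coefficient, degree-<2 nodes contributing 0
oracle_acc <- function(nodes, edges) {
  adj <- oracle_adj(nodes, edges)
  local <- vapply(nodes, function(v) {
    nb <- adj[[v]]
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      if (nb[j] %in% adj[[nb[i]]]) links <- links + 1
    }
    links / (k * (k - 1) / 2)
  }, numeric(1))
  mean(local)
}

# AUC by explicit positive-negative pair count (ties score 0.5)
oracle_auc <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(sp) * length(sn))
}

# brute-force interval category for a position against gene intervals
oracle_category <- function(pos, genes, flank) {
  body <- any(pos >= genes$start & pos <= genes$end)
  near <- any(pos >= genes$start - flank & pos <= genes$end + flank)
  if (body) "body" else if (near) "flank" else "outside"
}

# random named undirected simple graph for oracle comparisons
random_test_graph <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n))
  pairs <- t(utils::combn(nodes, 2))
  keep <- stats::runif(nrow(pairs)) < p
  edges <- pairs[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE),
    directed = FALSE, vertices = nodes)
  list(graph = g, nodes = nodes, edges = edges)
}
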