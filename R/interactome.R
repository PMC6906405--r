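#' Read a background interactome from a two-column edge list
#'
#' Reads an undirected PPI network from a whitespace/tab-separated edge
#' list (two identifier columns; extra columns are ignored). Duplicate
#' edges are collapsed and self-loops dropped, with counts reported via
#' \code{message()}. Vertex order is deterministic (lexicographic), so
#' downstream permutation results are reproducible across loads.
#'
#' @param path Path to the edge-list file. Lines starting with \code{#}
#'   are treated as comments.
#' @return An \code{igraph} undirected simple graph with named vertices.
#' @export
load_interactome <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty edge list: returning an empty interactome")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  bad <- which(vapply(fields, length, integer(1)) < 2)
  if (length(bad) > 0)
    stop_param(sprintf("malformed edge-list line %d: fewer than 2 columns",
                       bad[1]))
  a <- vapply(fields, `[[`, character(1), 1)
  b <- vapply(fields, `[[`, character(1), 2)
  loops <- a == b
  if (any(loops))
    message(sum(loops), " self-loop(s) dropped")
  a2 <- a[!loops]; b2 <- b[!loops]
  # unordered pair for dedup accounting
  key <- ifelse(a2 < b2, paste(a2, b2), paste(b2, a2))
  ndup <- sum(duplicated(key))
  if (ndup > 0)
    message(ndup, " duplicate edge(s) collapsed")
  keep <- !duplicated(key)
  verts <- sort(unique(c(a, b)))
  igraph::graph_from_data_frame(
    data.frame(from = a2[keep], to = b2[keep], stringsAsFactors = FALSE),
    directed = FALSE, vertices = verts)
}

#' Expand a seed gene set to its first PPI neighbours
#'
#' Builds the seed network: the union of the seed identifiers and every
#' protein with a direct interaction to a seed in the background
#' interactome. Seeds absent from the interactome are retained as
#' isolated members (they keep their place in the bookkeeping even
#' without interaction records) and reported via \code{message()}.
#'
#' @param interactome An \code{igraph} graph with named vertices.
#' @param seeds Character vector of seed identifiers (non-empty).
#' @return An object of class \code{seed_network}: a list with
#'   \code{seeds}, \code{members} (seeds plus first neighbours, sorted),
#'   and \code{missing_seeds} (seeds with no vertex in the interactome).
#' @export
expand_seed_network <- function(interactome, seeds) {
  if (length(seeds) == 0) stop_param("seed list is empty")
  seeds <- unique(as.character(seeds))
  nodes <- igraph::V(interactome)$name
  present <- intersect(seeds, nodes)
  missing <- setdiff(seeds, nodes)
  if (length(missing) > 0)
    message(length(missing),
            " seed(s) absent from the interactome; kept as isolated members")
  neigh <- character(0)
  if (length(present) > 0) {
    ego <- igraph::ego(interactome, order = 1, nodes = present)
    neigh <- unique(unlist(lapply(ego, names)))
  }
  members <- sort(unique(c(seeds, neigh)))
  structure(list(seeds = sort(seeds), members = members,
                 missing_seeds = sort(missing)),
            class = "seed_network")
}

#' @export
print.seed_network <- function(x, ...) {
  cat("Seed network:", length(x$seeds), "seeds ->", length(x$members),
      "members (", length(x$missing_seeds), "seed(s) without PPI records )\n")
  invisible(x)
}

#' Build a category-annotated induced subnetwork
#'
#' Induces the subgraph of the background interactome on a set of
#' categorized nodes (e.g. seed genes, GWAS hits, exome hits, novel
#' candidates). Nodes carrying a category but absent from the
#' interactome are included as isolated vertices so per-category counts
#' stay faithful to the input.
#'
#' @param interactome An \code{igraph} graph with named vertices.
#' @param category_map Data frame with columns \code{id} and
#'   \code{category}; a node may appear in several rows (multiple
#'   labels).
#' @return An object of class \code{categorized_subnetwork}: list with
#'   the induced \code{graph}, \code{categories} (named list of label
#'   sets), \code{category_counts}, \code{n_edges} and \code{lcc_size}.
#' @export
build_categorized_subnetwork <- function(interactome, category_map) {
  if (is.null(category_map) || nrow(category_map) == 0)
    stop_param("category_map is empty")
  ids <- unique(as.character(category_map$id))
  nodes <- igraph::V(interactome)$name
  present <- intersect(nodes, ids)
  g <- igraph::induced_subgraph(interactome, present)
  absent <- setdiff(ids, nodes)
  if (length(absent) > 0)
    g <- igraph::add_vertices(g, length(absent), name = absent)
  g <- igraph::permute(g, order(order(igraph::V(g)$name)))
  cats <- lapply(split(as.character(category_map$category),
                       as.character(category_map$id)),
                 function(v) sort(unique(v)))
  comp <- igraph::components(g)
  structure(list(
    graph = g,
    categories = cats,
    category_counts = table(unlist(cats)),
    n_edges = igraph::ecount(g),
    lcc_size = if (comp$no > 0) max(comp$csize) else 0L
  ), class = "categorized_subnetwork")
}

#' Retrieve genes near a set of genomic loci
#'
#' Returns gene identifiers whose interval overlaps a symmetric window
#' around each locus (e.g. 250 kbp up- and downstream of reported GWAS
#' positions), matching on chromosome after label normalization.
#'
#' @param genes Data frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end} (1-based inclusive).
#' @param loci Data frame with columns \code{chrom} and \code{pos}.
#' @param flank Non-negative window half-width in bp.
#' @return Sorted character vector of gene identifiers.
#' @export
genes_near_loci <- function(genes, loci, flank) {
  if (flank < 0) stop_param("flank must be >= 0")
  if (nrow(genes) == 0 || nrow(loci) == 0) return(character(0))
  g <- GenomicRanges::GRanges(norm_chrom(genes$chrom),
                              IRanges::IRanges(genes$start, genes$end))
  l <- GenomicRanges::GRanges(norm_chrom(loci$chrom),
                              IRanges::IRanges(pmax(1, loci$pos - flank),
                                               loci$pos + flank))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(g, l))
  sort(unique(genes$gene_id[S4Vectors::queryHits(hits)]))
}

#' Largest connected component of a graph
#'
#' Returns the induced subgraph on the node-maximal connected
#' component. Ties between equal-size components are broken in favour
#' of the component containing the lexicographically smallest vertex
#' name, so the choice is deterministic.
#'
#' @param graph An \code{igraph} graph (named vertices).
#' @return The induced subgraph on the chosen component (empty graph in,
#'   empty graph out).
#' @export
largest_connected_component <- function(graph) {
  if (igraph::vcount(graph) == 0) return(graph)
  comp <- igraph::components(graph)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1) {
    firsts <- vapply(best, function(k) {
      min(igraph::V(graph)$name[comp$membership == k])
    }, character(1))
    best <- best[order(firsts)][1]
  }
  igraph::induced_subgraph(graph,
                           which(comp$membership == best[1]))
}

#' Average path length and clustering coefficient of a subnetwork
#'
#' Computes, on the largest connected component (LCC) of the input
#' graph, the average shortest-path length (APL; mean geodesic distance
#' over unordered node pairs) and the average local clustering
#' coefficient (ACC; mean over LCC nodes, with nodes of degree < 2
#' contributing 0).
#'
#' @param graph An \code{igraph} graph.
#' @return Object of class \code{topology_metrics}: list with
#'   \code{apl} (\code{NA} and \code{apl_defined = FALSE} when the LCC
#'   has fewer than 2 nodes), \code{acc} and \code{lcc_size}.
#' @export
topology_metrics <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0) {
    return(structure(list(apl = NA_real_, acc = 0, lcc_size = 0L,
                          apl_defined = FALSE),
                     class = "topology_metrics"))
  }
  lcc <- largest_connected_component(graph)
  k <- igraph::vcount(lcc)
  apl <- if (k >= 2) {
    igraph::mean_distance(lcc, directed = FALSE, unconnected = FALSE)
  } else NA_real_
  local <- igraph::transitivity(lcc, type = "local", isolates = "zero")
  acc <- if (k >= 1) mean(local) else 0
  structure(list(apl = apl, acc = acc, lcc_size = as.integer(k),
                 apl_defined = k >= 2),
            class = "topology_metrics")
}

#' @export
print.topology_metrics <- function(x, ...) {
  cat(sprintf("Topology: LCC size %d, APL %s, ACC %.4f\n", x$lcc_size,
              if (x$apl_defined) sprintf("%.4f", x$apl) else "undefined",
              x$acc))
  invisible(x)
}
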