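
test_that("edge-list loader deduplicates, drops self-loops, orders nodes", {
  d <- withr::local_tempdir()
  f <- file.path(d, "e.tsv")
  writeLines(c("A\tB", "B\tA", "A\tA"), f)
  g <- suppressMessages(load_interactome(f))
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 1)
  expect_identical(igraph::V(g)$name, c("A", "B"))

  writeLines(character(0), f)
  expect_warning(g0 <- load_interactome(f), "empty")
  expect_equal(igraph::vcount(g0), 0)

  writeLines(c("A B extra", "B C"), f)
  g2 <- load_interactome(f)
  expect_equal(unname(igraph::degree(g2)["B"]), 2)

  writeLines(c("A B", "lonely"), f)
  expect_error(load_interactome(f), "line 2")
})

test_that("seed expansion returns seeds plus first neighbours", {
  star <- igraph::make_star(6, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("s", paste0("n", 1:5))
  net <- expand_seed_network(star, "s")
  expect_setequal(net$members, igraph::V(star)$name)

  # isolated / absent seed is retained and logged
  expect_message(net2 <- expand_seed_network(star, c("s", "x")),
                 "absent")
  expect_true("x" %in% net2$members)
  expect_identical(net2$missing_seeds, "x")

  expect_error(expand_seed_network(star, character(0)), "empty")
})

test_that("seed expansion matches a set-union oracle and is idempotent", {
  sim <- simulate_interactome(500, 2, 20, 0.3, rng_seed = 31)
  net <- expand_seed_network(sim$graph, sim$seeds)
  el <- igraph::as_edgelist(sim$graph)
  expected <- sort(unique(c(
    sim$seeds,
    el[el[, 1] %in% sim$seeds, 2], el[el[, 2] %in% sim$seeds, 1])))
  expect_identical(net$members, expected)
  # re-expansion with the same seeds yields the same member set
  expect_identical(expand_seed_network(sim$graph, sim$seeds)$members,
                   net$members)
})

test_that("categorized subnetwork induces the right edges and LCC", {
  tri <- igraph::make_graph(~ A - B, B - C, C - A)
  cm <- data.frame(id = c("A", "B", "C"), category = "SEED")
  sub <- build_categorized_subnetwork(tri, cm)
  expect_equal(igraph::vcount(sub$graph), 3)
  expect_equal(sub$n_edges, 3)
  expect_equal(sub$lcc_size, 3)

  two <- igraph::make_graph(~ A - B, C - D)
  sub2 <- build_categorized_subnetwork(
    two, data.frame(id = c("A", "B", "C", "D"),
                    category = c("SEED", "GWAS_HIT", "WES_HIT",
                                 "CANDIDATE")))
  expect_equal(sub2$lcc_size, 2)
  expect_error(build_categorized_subnetwork(two, data.frame()), "empty")
})

test_that("induced edge count equals a brute-force pair scan", {
  sim <- simulate_interactome(300, 2, rng_seed = 17)
  set.seed(4)
  picked <- sample(igraph::V(sim$graph)$name, 74)
  sub <- build_categorized_subnetwork(
    sim$graph, data.frame(id = picked, category = "CANDIDATE"))
  el <- igraph::as_edgelist(sim$graph)
  brute <- sum(el[, 1] %in% picked & el[, 2] %in% picked)
  expect_equal(sub$n_edges, brute)
})

test_that("genes near loci: inclusive window and oracle agreement", {
  genes <- data.frame(gene_id = "G1", chrom = "1",
                      start = 1000, end = 2000)
  locus <- data.frame(chrom = "1", pos = 2500)
  expect_identical(genes_near_loci(genes, locus, flank = 500), "G1")
  expect_identical(genes_near_loci(genes, locus, flank = 499),
                   character(0))
  expect_error(genes_near_loci(genes, locus, flank = -1), "flank")

  set.seed(8)
  rg <- data.frame(gene_id = sprintf("g%02d", 1:50),
                   chrom = sample(c("1", "2"), 50, TRUE),
                   start = sample(1e6, 50))
  rg$end <- rg$start + sample(5e4, 50)
  rl <- data.frame(chrom = sample(c("1", "2"), 20, TRUE),
                   pos = sample(1e6, 20))
  flank <- 250000
  brute <- sort(unique(unlist(lapply(seq_len(20), function(i) {
    hit <- rg$chrom == rl$chrom[i] &
      rg$end >= rl$pos[i] - flank & rg$start <= rl$pos[i] + flank
    rg$gene_id[hit]
  }))))
  expect_identical(genes_near_loci(rg, rl, flank), brute)
})

test_that("largest connected component with deterministic tie-break", {
  g <- igraph::make_graph(~ A - B, B - C, C - A, D)
  lcc <- largest_connected_component(g)
  expect_setequal(igraph::V(lcc)$name, c("A", "B", "C"))

  tie <- igraph::make_graph(~ C - D, A - B)
  expect_setequal(igraph::V(largest_connected_component(tie))$name,
                  c("A", "B"))

  sim <- random_test_graph(40, 0.04, seed = 3)
  comps <- oracle_components(sim$nodes, sim$edges)
  sizes <- sort(vapply(comps, length, integer(1)))
  ig <- sort(igraph::components(sim$graph)$csize)
  expect_equal(ig, sizes)
  expect_equal(igraph::vcount(largest_connected_component(sim$graph)),
               max(sizes))
  # LCC of a connected graph is the graph itself
  tri <- igraph::make_graph(~ A - B, B - C, C - A)
  expect_equal(igraph::vcount(largest_connected_component(tri)), 3)
})

test_that("topology metrics match hand-worked and oracle values", {
  tri <- igraph::make_graph(~ A - B, B - C, C - A)
  tm <- topology_metrics(tri)
  expect_equal(tm$apl, 1.0)
  expect_equal(tm$acc, 1.0)

  path <- igraph::make_graph(~ A - B, B - C)
  tm2 <- topology_metrics(path)
  expect_equal(tm2$apl, 4 / 3)
  expect_equal(tm2$acc, 0)

  chord <- igraph::make_graph(~ A - B, B - C, C - D, D - A, A - C)
  tm3 <- topology_metrics(chord)
  expect_equal(tm3$apl, 7 / 6)
  expect_equal(tm3$acc, 5 / 6)

  # complete graphs: apl = acc = 1 for all n >= 3
  for (n in c(3, 5, 8)) {
    kn <- igraph::make_full_graph(n)
    igraph::V(kn)$name <- letters[seq_len(n)]
    tmk <- topology_metrics(kn)
    expect_equal(tmk$apl, 1)
    expect_equal(tmk$acc, 1)
  }

  # degenerate graphs
  single <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(single)$name <- "A"
  tm4 <- topology_metrics(single)
  expect_false(tm4$apl_defined)
  expect_equal(tm4$acc, 0)
})

test_that("APL/ACC agree with all-pairs BFS on random graphs <= 50 nodes", {
  for (s in 1:6) {
    rt <- random_test_graph(10 + 7 * s, 0.12, seed = 100 + s)
    lcc_nodes <- sort(igraph::V(
      largest_connected_component(rt$graph))$name)
    keep <- rt$edges[rt$edges[, 1] %in% lcc_nodes &
                       rt$edges[, 2] %in% lcc_nodes, , drop = FALSE]
    tm <- topology_metrics(rt$graph)
    expect_equal(tm$apl, oracle_apl(lcc_nodes, keep), tolerance = 1e-12)
    expect_equal(tm$acc, oracle_acc(lcc_nodes, keep), tolerance = 1e-12)
  }
})
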