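#' Simulate a complete study bundle on disk
#'
#' Generates every input the pipeline consumes, wired together so the
#' planted structure is recoverable: a scale-free background
#' interactome with a dense planted seed module, a gene map whose gene
#' identifiers are interactome nodes (seed-module genes included),
#' body/flank/outside variants with truth categories, two causal
#' variants placed in seed-module genes, and discovery plus
#' replication case-control panels drawn under the additive logistic
#' disease model with mild two-subpopulation stratification.
#'
#' Default effect sizes (odds ratios 2.2 and 1.64 at allele
#' frequencies 0.05 and 0.12) correspond to the magnitude of the
#' strongest exome signals this kind of targeted scan is designed to
#' detect.
#'
#' @param out_dir Directory to write the bundle into (created if
#'   needed).
#' @param n_nodes Interactome size (default 500).
#' @param module_size Planted seed-module size (default 20).
#' @param module_edge_prob Within-module extra-edge probability
#'   (default 0.3).
#' @param n_genes Number of mapped genes (default 60; includes all
#'   seed-module genes).
#' @param causal_or Odds ratios of the causal variants.
#' @param causal_maf Allele frequencies of the causal variants.
#' @param n_cases,n_controls Discovery group sizes.
#' @param n_rep_cases,n_rep_controls Replication group sizes.
#' @param prevalence Baseline disease prevalence.
#' @param fst Subpopulation differentiation for all variants.
#' @param rng_seed Integer master seed.
#' @return List with file \code{paths}, the in-memory objects
#'   (\code{graph}, \code{seeds}, \code{genes}, \code{variants}) and
#'   the \code{truth} parameters (also written as a JSON sidecar).
#' @export
simulate_study_bundle <- function(out_dir,
                                  n_nodes = 500, module_size = 20,
                                  module_edge_prob = 0.8,
                                  n_genes = 60,
                                  causal_or = c(2.2, 1.64),
                                  causal_maf = c(0.05, 0.12),
                                  n_cases = 300, n_controls = 300,
                                  n_rep_cases = 150,
                                  n_rep_controls = 1500,
                                  prevalence = 0.1, fst = 0.01,
                                  rng_seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_interactome(n_nodes, attachment_edges = 2,
                              seed_module_size = module_size,
                              seed_module_extra_edge_prob = module_edge_prob,
                              rng_seed = rng_seed)
  set.seed(rng_seed + 1000L)
  others <- setdiff(igraph::V(sim$graph)$name, sim$seeds)
  gene_ids <- c(sim$seeds, sample(others, n_genes - length(sim$seeds)))

  # explicit placements: two body variants per gene plus outside decoys
  gene_length <- 2000; spacing <- 50000; flank <- 20000
  offset <- flank + spacing
  starts <- offset + (seq_len(n_genes) - 1) * (gene_length + spacing)
  body_pos <- as.vector(vapply(starts, function(s) {
    s + sample.int(gene_length, 2) - 1
  }, numeric(2)))
  flank_pos <- starts[seq(1, n_genes, by = 3)] - sample.int(flank, length(seq(1, n_genes, by = 3)))
  out_hi <- starts[n_genes] + gene_length - 1 + flank
  outside_pos <- out_hi + sample.int(spacing, 10)
  gm <- simulate_gene_map(n_genes, gene_length = gene_length,
                          spacing = spacing, flank = flank,
                          positions = c(body_pos, flank_pos, outside_pos),
                          gene_ids = gene_ids, chrom = "S",
                          rng_seed = rng_seed + 2000L)

  v <- gm$variants
  specs <- do.call(rbind, lapply(seq_len(nrow(v)), function(i) {
    variant_spec(v$id[i], maf = stats::runif(1, 0.05, 0.4),
                 odds_ratio = 1, gene_id = v$gene_id[i],
                 chrom = v$chrom[i], position = v$pos[i], fst = fst)
  }))
  # causal variants: first body variant of the first seed-module genes
  seed_body <- which(v$category == "body" & v$gene_id %in% sim$seeds)
  causal_idx <- seed_body[seq_along(causal_or)]
  specs$odds_ratio[causal_idx] <- causal_or
  specs$maf[causal_idx] <- causal_maf

  disc <- simulate_cohort(n_cases, n_controls, specs,
                          baseline_prevalence = prevalence,
                          rng_seed = rng_seed + 1L)
  repl <- simulate_cohort(n_rep_cases, n_rep_controls, specs,
                          baseline_prevalence = prevalence,
                          rng_seed = rng_seed + 2L)

  paths <- list(
    edges = file.path(out_dir, "edges.tsv"),
    seeds = file.path(out_dir, "seeds.txt"),
    genes_bed = file.path(out_dir, "genes.bed"),
    discovery_vcf = file.path(out_dir, "discovery.vcf"),
    discovery_pheno = file.path(out_dir, "discovery_pheno.tsv"),
    replication_vcf = file.path(out_dir, "replication.vcf"),
    replication_pheno = file.path(out_dir, "replication_pheno.tsv"),
    truth = file.path(out_dir, "truth.json"))
  write_edge_list(sim$graph, paths$edges)
  write_seed_list(sim$seeds, paths$seeds)
  write_bed(gm$genes, paths$genes_bed)
  write_vcf(disc, paths$discovery_vcf)
  write_phenotypes(disc, paths$discovery_pheno)
  write_vcf(repl, paths$replication_vcf)
  write_phenotypes(repl, paths$replication_pheno)
  truth <- list(causal_variants = v$id[causal_idx],
                causal_or = causal_or, causal_maf = causal_maf,
                seeds = sim$seeds, fst = fst,
                prevalence = prevalence, rng_seed = rng_seed,
                variant_categories = stats::setNames(v$category, v$id))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  list(paths = paths, graph = sim$graph, seeds = sim$seeds,
       genes = gm$genes, variants = v, discovery = disc,
       replication = repl, truth = truth)
}
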