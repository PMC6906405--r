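#' Simulate a gene map with truth-labelled variant placements
#'
#' Lays out non-overlapping genes on one synthetic chromosome and
#' assigns each variant a position either inside a gene body, inside a
#' flanking window, or outside both, recording the true category so the
#' gene-window variant filter can be tested against ground truth.
#'
#' Boundary placements are exact: a "flank" variant may sit exactly
#' \code{flank} bp from a gene edge, and an "outside" variant at least
#' \code{flank + 1} bp away from every gene.
#'
#' @param n_genes Number of genes.
#' @param gene_length Gene body length in bp.
#' @param spacing Gap between consecutive genes in bp (> 0). Gaps are
#'   only used for "outside" placements when wider than
#'   \code{2 * flank}; the regions before the first and after the last
#'   gene are always available.
#' @param n_variants Number of variants to place (ignored when
#'   \code{positions} is given).
#' @param positions Optional explicit positions; categories are then
#'   computed from the intervals instead of sampled.
#' @param flank Flanking window width in bp (default 20000).
#' @param gene_ids Optional gene identifiers (default \code{G001}...).
#' @param chrom Chromosome label.
#' @param rng_seed Integer seed.
#' @return List with \code{genes} (data frame \code{gene_id},
#'   \code{chrom}, \code{start}, \code{end}, \code{strand}; 1-based
#'   inclusive) and \code{variants} (data frame \code{id},
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt},
#'   \code{category} in \{body, flank, outside\}, \code{gene_id} of the
#'   assigned gene or \code{NA}).
#' @export
simulate_gene_map <- function(n_genes, gene_length = 1000,
                              spacing = 50000, n_variants = 100,
                              positions = NULL, flank = 20000,
                              gene_ids = NULL, chrom = "S",
                              rng_seed = 1L) {
  if (spacing <= 0) stop_param("spacing must be > 0")
  if (n_genes < 1) stop_param("n_genes must be >= 1")
  set.seed(rng_seed)
  offset <- flank + spacing
  starts <- offset + (seq_len(n_genes) - 1) * (gene_length + spacing)
  if (is.null(gene_ids)) gene_ids <- sprintf("G%03d", seq_len(n_genes))
  genes <- data.frame(gene_id = gene_ids, chrom = chrom,
                      start = starts, end = starts + gene_length - 1,
                      strand = "+", stringsAsFactors = FALSE)

  classify <- function(pos) {
    inside <- pos >= genes$start & pos <= genes$end
    near <- pos >= genes$start - flank & pos <= genes$end + flank
    if (any(inside)) {
      list(category = "body", gene = genes$gene_id[which(inside)[1]])
    } else if (any(near)) {
      list(category = "flank", gene = genes$gene_id[which(near)[1]])
    } else list(category = "outside", gene = NA_character_)
  }

  pick1 <- function(lo, hi) lo + sample.int(hi - lo + 1, 1) - 1
  if (is.null(positions)) {
    cat_draw <- sample(c("body", "flank", "outside"), n_variants,
                       replace = TRUE)
    last_end <- genes$end[n_genes]
    positions <- vapply(cat_draw, function(ct) {
      g <- sample.int(n_genes, 1)
      if (ct == "body") {
        pick1(genes$start[g], genes$end[g])
      } else if (ct == "flank") {
        if (stats::runif(1) < 0.5)
          pick1(genes$start[g] - flank, genes$start[g] - 1)
        else pick1(genes$end[g] + 1, genes$end[g] + flank)
      } else {
        # regions guaranteed farther than `flank` from every gene
        hi1 <- genes$start[1] - flank - 1
        if (stats::runif(1) < 0.5 && hi1 >= 1) pick1(1, hi1)
        else pick1(last_end + flank + 1, last_end + flank + spacing)
      }
    }, numeric(1))
  }
  n_variants <- length(positions)
  lab <- lapply(positions, classify)
  variants <- data.frame(
    id = sprintf("v%04d", seq_len(n_variants)), chrom = chrom,
    pos = as.integer(positions), ref = "A", alt = "G",
    category = vapply(lab, `[[`, character(1), "category"),
    gene_id = vapply(lab, `[[`, character(1), "gene"),
    stringsAsFactors = FALSE)
  list(genes = genes, variants = variants)
}
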