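#' Load gene intervals from a BED file
#'
#' Reads a BED (0-based half-open, >= 4 columns) file via
#' \pkg{rtracklayer} and converts to 1-based inclusive coordinates.
#' Strand is taken from column 6 when present, otherwise
#' \code{"unknown"}.
#'
#' @param bed_path Path to the BED file.
#' @return Data frame with \code{gene_id}, \code{chrom}, \code{start},
#'   \code{end} (1-based inclusive) and \code{strand} in
#'   \code{\{+, -, unknown\}}.
#' @export
load_genes <- function(bed_path) {
  gr <- rtracklayer::import(bed_path, format = "BED")
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "unknown"
  ids <- gr$name
  if (is.null(ids)) ids <- paste0("gene", seq_along(gr))
  out <- data.frame(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = strand, stringsAsFactors = FALSE)
  bad <- which(out$start > out$end)
  if (length(bad) > 0)
    stop_param("invalid interval at BED record ", bad[1])
  out
}

#' Filter variants to a gene set plus flanking windows
#'
#' Keeps a variant iff its position lies within
#' \code{[start - flank, end + flank]} (both ends inclusive, clipped at
#' 1) of at least one gene whose identifier belongs to
#' \code{member_ids}. The flank is applied symmetrically on both sides
#' regardless of strand (an "upstream or downstream" window). All
#' matching genes are recorded per variant.
#'
#' @param variants Data frame with \code{chrom} and \code{pos} (or
#'   \code{position}) columns; other columns are carried through.
#' @param genes Data frame of gene intervals (see
#'   \code{\link{load_genes}}).
#' @param member_ids Identifiers of genes in the target set (e.g. the
#'   members of a seed network); default all genes.
#' @param flank Non-negative window in bp (default 20000).
#' @return List with \code{kept} (subset of \code{variants}, original
#'   order) and \code{assignment} (data frame \code{variant_id}/row
#'   index, \code{gene_id}, one row per variant-gene match).
#' @export
filter_variants_to_geneset <- function(variants, genes,
                                       member_ids = genes$gene_id,
                                       flank = 20000) {
  if (flank < 0) stop_param("flank must be >= 0")
  pos <- variants$pos %||% variants$position
  if (is.null(pos)) stop_param("variants need a pos/position column")
  g <- genes[genes$gene_id %in% member_ids, , drop = FALSE]
  if (nrow(g) == 0 || nrow(variants) == 0) {
    return(list(kept = variants[integer(0), , drop = FALSE],
                assignment = data.frame(variant = integer(0),
                                        gene_id = character(0))))
  }
  vr <- GenomicRanges::GRanges(norm_chrom(variants$chrom),
                               IRanges::IRanges(pos, pos))
  gr <- GenomicRanges::GRanges(
    norm_chrom(g$chrom),
    IRanges::IRanges(pmax(1, g$start - flank), g$end + flank))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(vr, gr))
  vi <- S4Vectors::queryHits(hits)
  assignment <- data.frame(variant = vi,
                           gene_id = g$gene_id[S4Vectors::subjectHits(hits)],
                           stringsAsFactors = FALSE)
  if ("id" %in% names(variants))
    assignment$variant_id <- variants$id[vi]
  keep_idx <- sort(unique(vi))
  list(kept = variants[keep_idx, , drop = FALSE],
       assignment = assignment)
}

#' Intersect variant sets across cohorts
#'
#' Returns the variants present in every cohort, matching on
#' normalized keys: chromosome labels are stripped of a \code{chr}
#' prefix, alleles upper-cased, and multi-allelic ALT fields
#' (comma-separated) expanded into biallelic keys before comparison.
#' Allele strand flips are not reconciled; cohorts are assumed to be on
#' the same reference strand.
#'
#' @param cohorts List (length >= 2) of data frames, each with
#'   \code{chrom}, \code{pos} (or \code{position}), \code{ref},
#'   \code{alt}.
#' @return List with \code{keys} (sorted common biallelic keys,
#'   \code{"chrom:pos:REF:ALT"}) and \code{excluded} (per-cohort count
#'   of keys not shared by all).
#' @export
intersect_cohorts <- function(cohorts) {
  if (length(cohorts) < 2) stop_param("need at least 2 cohorts")
  keysets <- lapply(cohorts, function(v) {
    pos <- v$pos %||% v$position
    alts <- strsplit(as.character(v$alt), ",", fixed = TRUE)
    n_alt <- lengths(alts)
    unique(make_variant_key(rep(v$chrom, n_alt), rep(pos, n_alt),
                            rep(v$ref, n_alt), unlist(alts)))
  })
  common <- Reduce(intersect, keysets)
  list(keys = sort(common),
       excluded = vapply(keysets,
                         function(k) length(setdiff(k, common)),
                         integer(1)))
}
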