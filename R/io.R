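# Readers/writers for the plain-text interchange formats used by the
# pipeline. VCF reading goes through vcfR; writing uses a minimal
# VCF v4.2 text emitter (GT-only, diploid unphased) so outputs stay
# uncompressed and diffable.

#' Write a genotype panel as an uncompressed VCF v4.2
#'
#' Emits a multi-sample VCF with a single \code{GT} FORMAT field,
#' diploid unphased genotypes (\code{0/0}, \code{0/1}, \code{1/1},
#' \code{./.} for missing).
#'
#' @param panel A \code{genotype_panel}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(panel, path) {
  v <- panel$variants
  chrom <- if ("chrom" %in% names(v)) v$chrom else "1"
  pos <- if ("position" %in% names(v)) v$position else v$pos
  ref <- if ("ref" %in% names(v)) v$ref else "A"
  alt <- if ("alt" %in% names(v)) v$alt else "G"
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  G <- t(panel$dosages)  # variants x samples
  gt <- matrix("./.", nrow = nrow(G), ncol = ncol(G))
  ok <- !is.na(G)
  gt[ok] <- gt_code[as.character(G[ok])]
  body <- paste(chrom, pos, v$id, ref, alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=netseed",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", rownames(panel$dosages)), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write the phenotype/covariate table of a panel
#'
#' TSV with columns \code{sample_id}, \code{status} (1 = control,
#' 2 = case, the usual case-control file coding), \code{age},
#' \code{sex} and \code{PC1}..\code{PC10} when present.
#'
#' @param panel A \code{genotype_panel}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_phenotypes <- function(panel, path) {
  s <- panel$samples
  out <- data.frame(sample_id = s$sample_id, status = s$status + 1L,
                    age = s$age, sex = s$sex, stringsAsFactors = FALSE)
  pc_cols <- grep("^PC[0-9]+$", names(s), value = TRUE)
  if (length(pc_cols) > 0)
    out <- cbind(out, round(s[pc_cols], 6))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a genotype panel from VCF plus a phenotype table
#'
#' Reads genotypes with \pkg{vcfR} and converts \code{GT} calls to
#' alt-allele dosages; sample order follows the phenotype table.
#' Status is accepted as 1/2 (control/case) or 0/1.
#'
#' @param vcf_path Path to a VCF (v4.x) with a GT field.
#' @param pheno_path Path to the phenotype TSV (columns
#'   \code{sample_id}, \code{status}, optionally \code{age},
#'   \code{sex}, \code{PC1}...).
#' @return A \code{genotype_panel}.
#' @export
read_genotype_panel <- function(vcf_path, pheno_path) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))
  dos <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean %in% c("0/0")] <- 0L
  dos[clean %in% c("0/1", "1/0")] <- 1L
  dos[clean %in% c("1/1")] <- 2L
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- make_variant_key(
    fix[is.na(ids) | ids == ".", "CHROM"],
    fix[is.na(ids) | ids == ".", "POS"],
    fix[is.na(ids) | ids == ".", "REF"],
    fix[is.na(ids) | ids == ".", "ALT"])
  variants <- data.frame(id = ids, chrom = fix[, "CHROM"],
                         position = as.integer(fix[, "POS"]),
                         ref = fix[, "REF"], alt = fix[, "ALT"],
                         stringsAsFactors = FALSE)
  pheno <- utils::read.table(pheno_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  if (!all(c("sample_id", "status") %in% names(pheno)))
    stop_param("phenotype table needs sample_id and status columns")
  miss <- setdiff(pheno$sample_id, colnames(dos))
  if (length(miss) > 0)
    stop_param("sample(s) in phenotype table absent from VCF: ",
               paste(utils::head(miss, 3), collapse = ", "))
  dosages <- t(dos[, pheno$sample_id, drop = FALSE])
  colnames(dosages) <- variants$id
  status <- pheno$status
  if (all(status %in% c(1L, 2L))) status <- status - 1L
  pheno$status <- as.integer(status)
  genotype_panel(dosages, variants, pheno)
}

#' Write an interactome as a two-column TSV edge list
#'
#' @param graph An \code{igraph} graph with named vertices.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a seed gene list (one identifier per line)
#'
#' @param seeds Character vector.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_seed_list <- function(seeds, path) {
  writeLines(seeds, path)
  invisible(path)
}

#' Read a seed gene list
#'
#' One identifier per line; \code{#} comments and blank lines are
#' skipped.
#'
#' @param path Input path.
#' @return Character vector of identifiers.
#' @export
read_seed_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- sub("#.*$", "", x)
  x[nzchar(trimws(x))]
}

#' Write gene intervals as 6-column BED
#'
#' Converts the package's 1-based inclusive intervals to BED's 0-based
#' half-open convention via \pkg{rtracklayer}.
#'
#' @param genes Data frame with \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end} and optional \code{strand}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(genes, path) {
  strand <- genes$strand %||% "*"
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end),
    strand = strand)
  names(gr) <- genes$gene_id
  gr$score <- 0
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
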