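#' Default analysis configuration
#'
#' The tunable parameters of the genetics arm with their default
#' values: candidate p-value ladder 0.05 down to 0.00005, at least 11
#' candidates ("more than ten"), family-wise alpha 0.05, a 20 kbp
#' gene flank, 10 principal-component covariates, PRS case-frequency
#' tolerance 0.5, and 10000 permutations over 30 degree bins for the
#' topology null.
#'
#' @param ... Named overrides of any default.
#' @return Named list of settings.
#' @export
analysis_config <- function(...) {
  cfg <- list(candidate_thresholds = c(0.05, 0.005, 5e-4, 5e-5),
              selection_min_variants = 11,
              bonferroni_alpha = 0.05,
              flank = 20000,
              n_pcs = 10,
              prs_maf_tolerance = 0.5,
              n_permutations = 10000,
              n_bins = 30)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0)
    stop_param("unknown setting(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(all(diff(cfg$candidate_thresholds) < 0))
  cfg
}

#' Run the network-guided exome association workflow end to end
#'
#' Orchestrates the full analysis from one configuration: load the
#' interactome, expand the seed network, filter discovery variants to
#' the member gene set plus flank, run the single-variant logistic
#' scan with PC covariates, compute the genomic inflation factor,
#' scan candidate thresholds, re-test candidates in the replication
#' panel (age added to covariates, Bonferroni cutoff), select PRS
#' variants, score and test the PRS in replication, fit and evaluate
#' the variant and PRS prediction models (train = discovery, test =
#' replication), and run the degree-binned label-permutation topology
#' test on the seed + candidate-gene subnetwork. Deterministic given
#' the config seeds; the report contains no timestamps so reruns are
#' byte-identical.
#'
#' Missing replication inputs degrade gracefully: discovery and
#' network stages still run, replication-dependent stages are skipped
#' with a warning.
#'
#' @param config Path to a YAML configuration file, or an equivalent
#'   named list. Required entries: \code{inputs} (paths \code{edges},
#'   \code{seeds}, \code{genes_bed}, \code{discovery_vcf},
#'   \code{discovery_pheno}, optional \code{replication_vcf} /
#'   \code{replication_pheno}); optional \code{analysis} overrides
#'   (see \code{\link{analysis_config}}), \code{seed} (default 1),
#'   \code{exclusions}, \code{ld_blocks}, \code{ld_representatives},
#'   and \code{network_test} (\code{enabled},
#'   \code{n_permutations}, \code{n_bins}).
#' @param out_dir Optional output directory; when given, per-stage
#'   tables (filtered variants, discovery/replication association
#'   TSVs, PRS report, prediction report, topology JSON) and the run
#'   report JSON are written there.
#' @return Object of class \code{run_report}: per-stage counts,
#'   lambda, thresholds, selected variants, result tables, seeds and
#'   package version.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  inputs <- config$inputs
  if (is.null(inputs)) stop_param("config has no 'inputs' section")
  for (req in c("edges", "seeds", "genes_bed", "discovery_vcf",
                "discovery_pheno")) {
    if (is.null(inputs[[req]]) || !file.exists(inputs[[req]]))
      stop_param("missing required input: ", req)
  }
  cfg <- do.call(analysis_config, config$analysis %||% list())
  cfg$candidate_thresholds <- as.numeric(cfg$candidate_thresholds)
  seed <- config$seed %||% 1L
  nt <- config$network_test %||% list()
  nt_enabled <- nt$enabled %||% TRUE

  report <- list(version = as.character(utils::packageVersion("netseed")),
                 seed = seed, config = cfg, stages = list())
  log_stage <- function(name, ...) {
    report$stages[[name]] <<- list(...)
    message("[", name, "] ",
            paste(names(list(...)), unlist(list(...)),
                  sep = "=", collapse = " "))
  }

  # -- network expansion ----------------------------------------------
  net <- load_interactome(inputs$edges)
  seeds <- read_seed_list(inputs$seeds)
  expanded <- expand_seed_network(net, seeds)
  log_stage("expand", n_seeds = length(expanded$seeds),
            n_members = length(expanded$members))

  # -- variant filtering ----------------------------------------------
  genes <- load_genes(inputs$genes_bed)
  disc <- read_genotype_panel(inputs$discovery_vcf,
                              inputs$discovery_pheno)
  filt <- filter_variants_to_geneset(disc$variants, genes,
                                     expanded$members,
                                     flank = cfg$flank)
  disc_f <- subset_panel(disc, filt$kept$id)
  log_stage("filter", variants_in = nrow(disc$variants),
            variants_kept = nrow(filt$kept))

  # -- discovery SVA ---------------------------------------------------
  sva_d <- logistic_sva(disc_f, n_pcs = cfg$n_pcs)
  ok <- sva_d$fit_status %in% c("ok", "separation")
  lambda <- genomic_lambda(sva_d$p[ok])
  sel <- select_candidate_threshold(
    stats::setNames(sva_d$p, sva_d$id),
    thresholds = cfg$candidate_thresholds,
    min_variants = cfg$selection_min_variants)
  candidates <- sva_d$id[sel$selected]
  log_stage("sva_discovery", n_tested = sum(ok), lambda = lambda,
            threshold = sel$threshold,
            n_candidates = length(candidates))

  # -- replication -----------------------------------------------------
  have_rep <- !is.null(inputs$replication_vcf) &&
    file.exists(inputs$replication_vcf %||% "")
  sva_r <- NULL; repl <- NULL; bonf <- NA_real_
  if (have_rep) {
    repl <- read_genotype_panel(inputs$replication_vcf,
                                inputs$replication_pheno)
    rep_ids <- intersect(candidates, colnames(repl$dosages))
    if (length(rep_ids) > 0) {
      sva_r <- logistic_sva(subset_panel(repl, rep_ids),
                            n_pcs = cfg$n_pcs, include_age = TRUE)
      bonf <- bonferroni_threshold(cfg$bonferroni_alpha,
                                   length(rep_ids))
      log_stage("sva_replication", n_tested = length(rep_ids),
                bonferroni_cutoff = bonf,
                n_significant = sum(sva_r$p < bonf, na.rm = TRUE))
    }
  } else {
    warning("replication panel not configured; ",
            "replication-dependent stages skipped")
  }

  # -- PRS -------------------------------------------------------------
  prs_out <- NULL; prs_variants <- character(0)
  if (!is.null(sva_r)) {
    selection <- select_prs_variants(
      sva_d, sva_r,
      ld_blocks = lapply(config$ld_blocks %||% list(), unlist),
      ld_representatives = unlist(config$ld_representatives),
      exclusions = unlist(config$exclusions) %||% character(0),
      p_cutoff = sel$threshold,
      maf_tolerance = cfg$prs_maf_tolerance)
    prs_variants <- selection$variants
    if (length(prs_variants) > 0) {
      model <- build_prs_model(sva_d, prs_variants)
      scores <- compute_prs(repl, model)
      quart <- prs_quartile_summary(scores, repl$samples$status)
      assoc <- prs_association(repl, scores, n_pcs = cfg$n_pcs)
      prs_out <- list(model = model, scores_summary = list(
        mean = mean(scores), min = min(scores), max = max(scores)),
        quartile = quart, association = assoc)
      log_stage("prs", n_variants = length(prs_variants),
                score_mean = round(mean(scores), 4),
                prs_or = round(assoc$or[assoc$term == "prs"], 4),
                prs_p = signif(assoc$p[assoc$term == "prs"], 4))
    } else {
      warning("no variants passed PRS selection; PRS stage skipped")
    }
  }

  # -- prediction ------------------------------------------------------
  pred_out <- NULL
  if (!is.null(prs_out)) {
    vm <- fit_variant_model(subset_panel(disc_f, prs_variants),
                            prs_variants, rng_seed = seed)
    vm_class <- predict(vm, repl)
    vm_prob <- predict(vm, repl, type = "prob")
    vm_eval <- eval_classifier(repl$samples$status, vm_class, vm_prob)
    train_scores <- compute_prs(disc_f, prs_out$model)
    pm <- fit_prs_model(train_scores, disc_f$samples$status)
    rep_scores <- compute_prs(repl, prs_out$model)
    pm_class <- predict(pm, rep_scores)
    pm_eval <- eval_classifier(repl$samples$status, pm_class,
                               rep_scores)
    pred_out <- list(variant_model = vm_eval, prs_model = pm_eval,
                     importances = vm$importances)
    log_stage("predict",
              variant_bal_acc = round(vm_eval$balanced_accuracy, 3),
              prs_bal_acc = round(pm_eval$balanced_accuracy, 3))
  }

  # -- topology null test ---------------------------------------------
  topo <- NULL
  if (isTRUE(nt_enabled)) {
    cand_genes <- unique(filt$assignment$gene_id[
      filt$assignment$variant_id %in% candidates])
    subset <- intersect(unique(c(expanded$seeds, cand_genes)),
                        igraph::V(net)$name)
    if (length(subset) >= 3) {
      topo <- null_topology_distribution(
        net, subset,
        n_permutations = nt$n_permutations %||% cfg$n_permutations,
        n_bins = nt$n_bins %||% cfg$n_bins,
        rng_seed = seed)
      log_stage("topology", subnet_size = length(subset),
                p_apl_lower = topo$p_apl_lower,
                p_acc_upper = topo$p_acc_upper)
    }
  }

  report <- c(report, list(
    lambda = lambda, threshold = sel$threshold,
    bonferroni_cutoff = bonf, candidates = candidates,
    prs_variants = prs_variants,
    sva_discovery = sva_d, sva_replication = sva_r,
    prs = prs_out, prediction = pred_out, topology = topo))
  class(report) <- "run_report"

  if (!is.null(out_dir)) write_run_outputs(report, out_dir)
  report
}

# Serialize per-stage artifacts; numbers only, no timestamps, so a
# rerun with the same config is byte-identical.
write_run_outputs <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) utils::write.table(
    df, file.path(out_dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE)
  wt(report$sva_discovery, "sva_discovery.tsv")
  if (!is.null(report$sva_replication))
    wt(report$sva_replication, "sva_replication.tsv")
  if (!is.null(report$prs)) {
    wt(report$prs$association, "prs_association.tsv")
    jsonlite::write_json(
      list(variants = report$prs$model$variants,
           weights = as.list(report$prs$model$weights),
           scores = report$prs$scores_summary,
           quartile = report$prs$quartile),
      file.path(out_dir, "prs_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(report$prediction))
    jsonlite::write_json(report$prediction,
                         file.path(out_dir, "prediction_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(report$topology)) {
    t <- report$topology
    jsonlite::write_json(
      list(observed = unclass(t$observed), p_apl_lower = t$p_apl_lower,
           p_acc_upper = t$p_acc_upper,
           n_permutations = t$n_permutations,
           n_degenerate = t$n_degenerate, n_bins = t$n_bins),
      file.path(out_dir, "topology.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  summary <- list(
    version = report$version, seed = report$seed,
    stages = report$stages, lambda = report$lambda,
    threshold = report$threshold,
    bonferroni_cutoff = report$bonferroni_cutoff,
    candidates = report$candidates,
    prs_variants = report$prs_variants)
  jsonlite::write_json(summary, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("netseed run (seed ", x$seed, ")\n", sep = "")
  cat("  lambda:", round(x$lambda, 3),
      " candidate threshold:", x$threshold,
      " candidates:", length(x$candidates),
      " PRS variants:", length(x$prs_variants), "\n")
  invisible(x)
}
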