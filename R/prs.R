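#' Build a PRS model from association results
#'
#' Takes the selected variants and weights them by the natural
#' logarithm of their (discovery-set) odds ratios.
#'
#' @param sva_results Data frame with \code{id} and \code{or} columns
#'   (e.g. output of \code{\link{logistic_sva}}).
#' @param variant_ids Identifiers of the selected variants.
#' @param source Free-text label for where the weights came from.
#' @return Object of class \code{prs_model}: list with
#'   \code{variants}, \code{weights} (named \code{ln(OR)} vector) and
#'   \code{source}.
#' @export
build_prs_model <- function(sva_results, variant_ids,
                            source = "discovery") {
  idx <- match(variant_ids, sva_results$id)
  if (anyNA(idx))
    stop_param("variant(s) absent from results: ",
               paste(variant_ids[is.na(idx)], collapse = ", "))
  w <- log(sva_results$or[idx])
  if (any(!is.finite(w)))
    stop_param("non-finite log odds-ratio weight")
  structure(list(variants = variant_ids,
                 weights = stats::setNames(w, variant_ids),
                 source = source),
            class = "prs_model")
}

#' @export
print.prs_model <- function(x, ...) {
  cat("PRS model (", x$source, " weights):\n", sep = "")
  print(round(x$weights, 4))
  invisible(x)
}

#' Compute per-sample polygenic risk scores
#'
#' \deqn{score_i = \sum_j dosage_{ij} \cdot \ln(OR_j)} Missing
#' dosages contribute 0 (deterministic and conservative; scores stay
#' comparable across samples) and are flagged per sample.
#'
#' @param panel A \code{genotype_panel} containing every model
#'   variant.
#' @param model A \code{prs_model} (or data frame with \code{id} and
#'   \code{weight}).
#' @return Numeric vector of scores (one per sample, named) with
#'   attribute \code{missing_any}: logical vector flagging samples
#'   whose score omitted a missing genotype.
#' @export
compute_prs <- function(panel, model) {
  if (is.data.frame(model)) {
    model <- structure(list(variants = model$id,
                            weights = stats::setNames(model$weight,
                                                      model$id)),
                       class = "prs_model")
  }
  miss <- setdiff(model$variants, colnames(panel$dosages))
  if (length(miss) > 0)
    stop_param("model variant(s) absent from panel: ",
               paste(miss, collapse = ", "))
  D <- panel$dosages[, model$variants, drop = FALSE]
  missing_any <- apply(is.na(D), 1, any)
  D[is.na(D)] <- 0L
  scores <- as.vector(D %*% model$weights[model$variants])
  names(scores) <- rownames(panel$dosages)
  attr(scores, "missing_any") <- missing_any
  scores
}

#' Upper-quartile membership of PRS by phenotype group
#'
#' Cuts at the 75th percentile of the combined score distribution and
#' reports the fraction of each phenotype group strictly above the
#' cut (samples exactly at the cut count as below).
#'
#' @param scores Numeric PRS vector (>= 4 samples).
#' @param status Binary phenotype (1 = case, 0 = control), same
#'   length.
#' @return List with \code{cut}, \code{case_fraction},
#'   \code{control_fraction}, and \code{degenerate} (TRUE when all
#'   scores are equal, in which case both fractions are 0).
#' @export
prs_quartile_summary <- function(scores, status) {
  if (length(scores) < 4) stop_param("need at least 4 samples")
  if (length(scores) != length(status))
    stop_param("scores and status lengths differ")
  cut <- stats::quantile(scores, 0.75, names = FALSE)
  degenerate <- max(scores) == min(scores)
  above <- scores > cut
  list(cut = cut,
       case_fraction = if (degenerate) 0 else mean(above[status == 1]),
       control_fraction = if (degenerate) 0 else mean(above[status == 0]),
       degenerate = degenerate)
}

#' Test the PRS association with disease
#'
#' Fits \code{status ~ PRS + age + PC1..PCk} by logistic regression
#' and reports, for a configurable set of terms (by default PRS, age
#' and PC1), the estimate, standard error, Wald statistic and p-value,
#' the odds ratio with Wald 95\% confidence interval, and
#' Benjamini-Hochberg (FDR) plus Bonferroni adjustments of the
#' reported p-values across those terms.
#'
#' @param panel A \code{genotype_panel} (replication panel).
#' @param scores Per-sample PRS vector aligned with the panel.
#' @param n_pcs Number of PC covariates included in the fit (default
#'   10).
#' @param include_age Include age as a covariate (default TRUE).
#' @param report_terms Model terms to report (default
#'   \code{c("prs", "age", "PC1")}).
#' @return Data frame with one row per reported term: \code{term},
#'   \code{estimate}, \code{std_error}, \code{statistic}, \code{p},
#'   \code{fdr}, \code{bonf}, \code{or}, \code{ci_low},
#'   \code{ci_high}, plus attribute \code{converged}. PRS constant
#'   across samples is an error (degenerate design).
#' @export
prs_association <- function(panel, scores, n_pcs = 10,
                            include_age = TRUE,
                            report_terms = c("prs", "age", "PC1")) {
  y <- panel$samples$status
  if (length(unique(y)) < 2)
    stop_param("phenotype must contain both classes")
  if (max(scores) == min(scores))
    stop_param("PRS is constant across samples: coefficient undefined")
  dat <- data.frame(y = y, prs = as.vector(scores))
  if (include_age) dat$age <- panel$samples$age
  if (n_pcs > 0) {
    pc_cols <- paste0("PC", seq_len(n_pcs))
    dat <- cbind(dat, panel$samples[pc_cols])
  }
  fit <- suppressWarnings(
    stats::glm(y ~ ., data = dat, family = stats::binomial()))
  co <- summary(fit)$coefficients
  terms <- intersect(report_terms, rownames(co))
  est <- co[terms, "Estimate"]
  se <- co[terms, "Std. Error"]
  p <- co[terms, "Pr(>|z|)"]
  out <- data.frame(
    term = terms, estimate = est, std_error = se,
    statistic = co[terms, "z value"], p = p,
    fdr = stats::p.adjust(p, method = "BH"),
    bonf = stats::p.adjust(p, method = "bonferroni"),
    or = exp(est),
    ci_low = exp(est - 1.96 * se), ci_high = exp(est + 1.96 * se),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "converged") <- fit$converged
  out
}
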