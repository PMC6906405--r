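#' Allele counts and frequencies by case-control status
#'
#' Counts alt (allele 1) alleles among cases and controls over
#' non-missing genotypes; frequencies divide by twice the non-missing
#' group size (complete-case denominators per variant).
#'
#' @param panel A \code{genotype_panel}.
#' @param variant_id Identifier of a variant in the panel.
#' @return List with \code{c_a}, \code{c_u} (alt-allele counts in
#'   cases/controls), \code{f_a}, \code{f_u} (frequencies; \code{NaN}
#'   when a group is fully missing, with \code{all_missing} flagged),
#'   and non-missing group sizes \code{n_cases}, \code{n_controls}.
#' @export
allele_stats <- function(panel, variant_id) {
  if (!variant_id %in% colnames(panel$dosages))
    stop_param("variant not in panel: ", variant_id)
  d <- panel$dosages[, variant_id]
  case <- panel$samples$status == 1
  dc <- d[case]; du <- d[!case]
  n_ca <- sum(!is.na(dc)); n_co <- sum(!is.na(du))
  c_a <- sum(dc, na.rm = TRUE); c_u <- sum(du, na.rm = TRUE)
  list(c_a = c_a, c_u = c_u,
       f_a = if (n_ca > 0) c_a / (2 * n_ca) else NaN,
       f_u = if (n_co > 0) c_u / (2 * n_co) else NaN,
       n_cases = n_ca, n_controls = n_co,
       all_missing = (n_ca + n_co) == 0)
}

#' Crude (unadjusted) allelic odds ratio from a 2x2 table
#'
#' Cross-product odds ratio on allele counts; a diagnostic companion
#' to the covariate-adjusted regression estimates. When any cell is 0
#' the Haldane-Anscombe continuity correction (+0.5 to every cell) is
#' applied and flagged.
#'
#' @param c_a Alt-allele count among case alleles.
#' @param n_case_alleles Total case alleles (2 x non-missing cases).
#' @param c_u Alt-allele count among control alleles.
#' @param n_control_alleles Total control alleles.
#' @return List with \code{or} and \code{corrected} (logical).
#' @export
crude_odds_ratio <- function(c_a, n_case_alleles, c_u,
                             n_control_alleles) {
  if (any(c(c_a, n_case_alleles, c_u, n_control_alleles) < 0))
    stop_param("counts must be non-negative")
  if (n_case_alleles == 0 || n_control_alleles == 0)
    stop_param("a margin is 0: odds ratio undefined")
  a <- c_a; b <- n_case_alleles - c_a
  c <- c_u; d <- n_control_alleles - c_u
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  list(or = (a / b) / (c / d), corrected = corrected)
}

#' Single-variant logistic association scan
#'
#' Fits, for each variant, \code{status ~ dosage + PC1..PCk (+ age)}
#' by maximum-likelihood logistic regression on the per-variant
#' complete cases, reporting the per-allele odds ratio
#' (\code{exp} of the dosage coefficient), its Wald p-value, and
#' case/control allele counts and frequencies. Monomorphic variants
#' are skipped with a reason; non-convergence and suspected complete
#' separation are flagged, never silently dropped.
#'
#' @param panel A \code{genotype_panel} with at least 2 cases and 2
#'   controls.
#' @param n_pcs Number of principal-component covariates (default 10;
#'   0 fits the crude model).
#' @param include_age Add age to the covariates (the replication-stage
#'   setting).
#' @param test \code{"wald"} (default) or \code{"lrt"}
#'   (likelihood-ratio) for the dosage p-value.
#' @return Data frame with one row per variant: \code{id},
#'   \code{chrom}, \code{pos}, \code{or}, \code{beta}, \code{se},
#'   \code{p}, \code{c_a}, \code{c_u}, \code{f_a}, \code{f_u},
#'   \code{n_eff} and \code{fit_status} in
#'   \{ok, monomorphic, non_converged, separation\}.
#' @export
logistic_sva <- function(panel, n_pcs = 10, include_age = FALSE,
                         test = c("wald", "lrt")) {
  test <- match.arg(test)
  y_all <- panel$samples$status
  if (sum(y_all == 1) < 2 || sum(y_all == 0) < 2)
    stop_param("need at least 2 cases and 2 controls")
  pc_cols <- paste0("PC", seq_len(n_pcs))
  if (n_pcs > 0 && !all(pc_cols %in% names(panel$samples)))
    stop_param("panel lacks the requested PC columns")
  if (include_age && !"age" %in% names(panel$samples))
    stop_param("panel lacks an age column")
  v <- panel$variants
  pos <- v$position %||% v$pos
  rows <- lapply(seq_len(ncol(panel$dosages)), function(j) {
    id <- colnames(panel$dosages)[j]
    d <- panel$dosages[, j]
    keep <- !is.na(d)
    st <- allele_stats(panel, id)
    out <- data.frame(id = id, chrom = v$chrom[j], pos = pos[j],
                      or = NA_real_, beta = NA_real_, se = NA_real_,
                      p = NA_real_, c_a = st$c_a, c_u = st$c_u,
                      f_a = st$f_a, f_u = st$f_u,
                      n_eff = sum(keep), fit_status = "ok",
                      stringsAsFactors = FALSE)
    if (length(unique(d[keep])) < 2) {
      out$fit_status <- "monomorphic"
      return(out)
    }
    dat <- data.frame(y = y_all[keep], dosage = d[keep])
    if (n_pcs > 0)
      dat <- cbind(dat, panel$samples[keep, pc_cols, drop = FALSE])
    if (include_age) dat$age <- panel$samples$age[keep]
    fit <- suppressWarnings(
      stats::glm(y ~ ., data = dat, family = stats::binomial()))
    co <- suppressWarnings(summary(fit)$coefficients)
    if (!"dosage" %in% rownames(co)) {
      out$fit_status <- "non_converged"
      return(out)
    }
    out$beta <- co["dosage", "Estimate"]
    out$se <- co["dosage", "Std. Error"]
    out$or <- exp(out$beta)
    out$p <- if (test == "wald") {
      co["dosage", "Pr(>|z|)"]
    } else {
      fit0 <- suppressWarnings(
        stats::glm(y ~ . - dosage, data = dat,
                   family = stats::binomial()))
      stats::pchisq(fit0$deviance - fit$deviance, df = 1,
                    lower.tail = FALSE)
    }
    if (!fit$converged) {
      out$fit_status <- "non_converged"
    } else if (abs(out$beta) > 10 || out$se > 50) {
      out$fit_status <- "separation"
    }
    out
  })
  do.call(rbind, rows)
}

#' Genomic inflation factor (median chi-square)
#'
#' \deqn{\lambda = median(\chi^2_{obs}) / median(\chi^2_1)} where the
#' observed chi-squares are the \eqn{\chi^2_1} quantile transforms of
#' the p-values and the reference median is computed from the quantile
#' function at full precision (about 0.4549), not a rounded constant.
#' Values near 1 indicate well-calibrated tests.
#'
#' @param p_values Numeric vector of p-values (NAs dropped).
#' @return Single number, \eqn{\lambda}.
#' @export
genomic_lambda <- function(p_values) {
  p <- p_values[!is.na(p_values)]
  if (length(p) == 0) stop_param("no valid p-values")
  chi <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, df = 1)
}

#' Select a candidate p-value threshold by scanning a ladder
#'
#' Scans a descending ladder of p-value thresholds and returns the
#' smallest one under which at least \code{min_variants} variants fall
#' (strict \code{p < t}), keeping the false-positive rate low while
#' retaining a workable candidate set. If no threshold qualifies, the
#' largest is returned with a warning.
#'
#' @param p_values Named (or plain) numeric vector of p-values.
#' @param thresholds Strictly decreasing probability ladder (default
#'   0.05, 0.005, 0.0005, 0.00005).
#' @param min_variants Minimum candidate count required (default 11,
#'   i.e. "more than ten").
#' @return List with \code{threshold}, \code{selected} (indices into
#'   \code{p_values}; named if input was named), \code{counts} per
#'   threshold and \code{fallback} (logical).
#' @export
select_candidate_threshold <- function(p_values,
                                       thresholds = c(0.05, 0.005,
                                                      5e-4, 5e-5),
                                       min_variants = 11) {
  if (any(diff(thresholds) >= 0))
    stop_param("thresholds must be strictly decreasing")
  counts <- vapply(thresholds,
                   function(t) sum(p_values < t, na.rm = TRUE),
                   numeric(1))
  ok <- which(counts >= min_variants)
  fallback <- length(ok) == 0
  pick <- if (fallback) 1L else max(ok)
  if (fallback)
    warning("no threshold yielded ", min_variants,
            " variants; falling back to ", thresholds[1])
  sel <- which(p_values < thresholds[pick])
  list(threshold = thresholds[pick], selected = sel,
       counts = stats::setNames(counts, thresholds),
       fallback = fallback)
}

#' Bonferroni-corrected significance cutoff
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param m Number of tests (>= 1).
#' @return \code{alpha / m}.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (m < 1) stop_param("m must be >= 1")
  alpha / m
}

#' Select variants for the polygenic risk score
#'
#' Applies the PRS inclusion rules to paired discovery/replication
#' association results: (i) discovery p below the candidate cutoff;
#' (ii) not on the exclusion list (e.g. variants that failed
#' validation); (iii) case allele frequency similar between datasets
#' (relative difference to the discovery frequency at most
#' \code{maf_tolerance}); (iv) one representative per declared LD
#' block (the configured one, else the block member with the smallest
#' discovery p).
#'
#' @param discovery,replication Data frames with at least \code{id},
#'   \code{p} and \code{f_a}, sharing identifiers.
#' @param ld_blocks List of character vectors, each a declared LD
#'   block; blocks must not overlap.
#' @param ld_representatives Optional character vector, one per block
#'   (NA = pick by smallest discovery p); an error if a configured
#'   representative is not in its block.
#' @param exclusions Variant identifiers to drop.
#' @param p_cutoff Discovery p-value cutoff (default 5e-4).
#' @param maf_tolerance Maximum relative case-frequency difference
#'   (default 0.5).
#' @return List with \code{variants} (kept identifiers) and
#'   \code{dropped} (data frame \code{id}, \code{reason}).
#' @export
select_prs_variants <- function(discovery, replication,
                                ld_blocks = list(),
                                ld_representatives = NULL,
                                exclusions = character(0),
                                p_cutoff = 5e-4, maf_tolerance = 0.5) {
  if (length(ld_blocks) > 0 && !is.null(ld_representatives)) {
    if (length(ld_representatives) != length(ld_blocks))
      stop_param("need one representative (or NA) per LD block")
    for (b in seq_along(ld_blocks)) {
      r <- ld_representatives[b]
      if (!is.na(r) && !r %in% ld_blocks[[b]])
        stop_param("representative ", r, " not in its LD block")
    }
  }
  dropped <- data.frame(id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  note <- function(ids, why) {
    if (length(ids) > 0)
      dropped <<- rbind(dropped, data.frame(id = ids, reason = why,
                                            stringsAsFactors = FALSE))
  }
  cand <- discovery$id[!is.na(discovery$p) & discovery$p < p_cutoff]
  note(setdiff(discovery$id, cand), "discovery_p")
  keep <- setdiff(cand, exclusions)
  note(intersect(cand, exclusions), "excluded")
  # case-frequency concordance between datasets
  fd <- discovery$f_a[match(keep, discovery$id)]
  fr <- replication$f_a[match(keep, replication$id)]
  rel <- ifelse(fd > 0, abs(fd - fr) / fd, Inf)
  rel[is.na(rel)] <- Inf
  note(keep[rel > maf_tolerance], "maf_dissimilar")
  keep <- keep[rel <= maf_tolerance]
  # LD block pruning
  for (b in seq_along(ld_blocks)) {
    inblk <- intersect(keep, ld_blocks[[b]])
    if (length(inblk) <= 1) next
    rep_id <- if (!is.null(ld_representatives) &&
                  !is.na(ld_representatives[b])) {
      ld_representatives[b]
    } else {
      inblk[which.min(discovery$p[match(inblk, discovery$id)])]
    }
    if (!rep_id %in% inblk) rep_id <- inblk[1]
    note(setdiff(inblk, rep_id), "ld_block")
    keep <- setdiff(keep, setdiff(inblk, rep_id))
  }
  list(variants = keep[order(match(keep, discovery$id))],
       dropped = dropped)
}
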