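#' Specify a simulated variant
#'
#' Convenience constructor for the per-variant rows consumed by
#' \code{\link{simulate_cohort}}.
#'
#' @param id Variant identifier (e.g. an rsID-style label).
#' @param maf Minor (risk) allele frequency in (0, 0.5].
#' @param odds_ratio Per-allele odds ratio on disease (> 0; 1 = null).
#' @param gene_id Gene the variant belongs to (optional).
#' @param chrom Chromosome label.
#' @param position 1-based coordinate.
#' @param fst Wright's fixation index in [0, 1): differentiation
#'   between the two simulated subpopulations (0 = no stratification).
#' @return One-row data frame.
#' @export
variant_spec <- function(id, maf, odds_ratio = 1, gene_id = NA_character_,
                         chrom = "1", position = 1L, fst = 0) {
  if (maf <= 0 || maf > 0.5) stop_param("maf must be in (0, 0.5]")
  if (odds_ratio <= 0) stop_param("odds_ratio must be > 0")
  if (fst < 0 || fst >= 1) stop_param("fst must be in [0, 1)")
  data.frame(id = id, maf = maf, odds_ratio = odds_ratio,
             gene_id = gene_id, chrom = as.character(chrom),
             position = as.integer(position), fst = fst,
             stringsAsFactors = FALSE)
}

#' Simulate a stratified case-control genotype panel
#'
#' Draws unlinked diploid genotypes for two subpopulations whose
#' allele frequencies drift from the shared MAF by the Balding-Nichols
#' model (frequencies drawn from
#' \code{Beta(maf(1-fst)/fst, (1-maf)(1-fst)/fst)}; \code{fst = 0}
#' short-circuits to the shared MAF). Disease status follows an
#' additive logistic model,
#' \code{logit P(case) = alpha + sum_j ln(OR_j) * dosage_j},
#' with the intercept solved numerically so the population prevalence
#' matches \code{baseline_prevalence}. Individuals are drawn by
#' rejection sampling until exactly \code{n_cases} cases and
#' \code{n_controls} controls are collected. The top 10 principal
#' components of the mean-imputed, centred dosage matrix are attached
#' as ancestry covariates (zero-padded when fewer are estimable; on
#' panels narrower than 25 variants all PC columns are zero, since
#' components computed from a handful of variants are collinear with
#' the tested dosages rather than with ancestry structure), and ages
#' are drawn uniformly from \code{age_range}.
#'
#' @param n_cases,n_controls Positive group sizes.
#' @param variants Data frame of variant rows (see
#'   \code{\link{variant_spec}}); positions must be unique per
#'   chromosome.
#' @param baseline_prevalence Target population disease prevalence.
#' @param admixture_fraction Proportion of draws from subpopulation 2.
#' @param age_range Length-2 numeric range for uniform ages (years).
#' @param missing_rate Per-genotype missingness probability.
#' @param rng_seed Integer seed; identical seeds give identical panels.
#' @param max_draws Rejection-sampling cap before a convergence error.
#' @return Object of class \code{genotype_panel}: list with
#'   \code{dosages} (samples x variants matrix in \{0,1,2,NA\}),
#'   \code{variants} (the input rows plus any annotation), and
#'   \code{samples} (data frame: \code{sample_id}, \code{status} 1 =
#'   case / 0 = control, \code{age}, \code{sex}, \code{subpop},
#'   \code{PC1}..\code{PC10}), plus a \code{truth} element recording
#'   the solved intercept and subpopulation frequencies.
#' @export
simulate_cohort <- function(n_cases, n_controls, variants,
                            baseline_prevalence = 0.1,
                            admixture_fraction = 0.5,
                            age_range = c(40, 80), missing_rate = 0,
                            rng_seed = 1L, max_draws = 1e7) {
  if (n_cases < 1 || n_controls < 1)
    stop_param("n_cases and n_controls must be positive")
  check_prob(baseline_prevalence, "baseline_prevalence", 1e-6, 1 - 1e-6)
  check_prob(admixture_fraction, "admixture_fraction")
  check_prob(missing_rate, "missing_rate")
  if (any(duplicated(variants[c("chrom", "position")])))
    stop_param("variant positions must be unique per chromosome")
  m <- nrow(variants)
  set.seed(rng_seed)

  # Balding-Nichols subpopulation allele frequencies
  freqs <- matrix(rep(variants$maf, each = 2), nrow = 2)
  for (j in seq_len(m)) {
    f <- variants$fst[j]; p <- variants$maf[j]
    if (f > 0)
      freqs[, j] <- stats::rbeta(2, p * (1 - f) / f,
                                 (1 - p) * (1 - f) / f)
  }
  beta <- log(variants$odds_ratio)

  draw_genotypes <- function(k) {
    pop <- stats::rbinom(k, 1, admixture_fraction) + 1L
    G <- matrix(0L, nrow = k, ncol = m)
    for (j in seq_len(m))
      G[, j] <- stats::rbinom(k, 2, freqs[pop, j])
    list(G = G, pop = pop)
  }

  # solve the intercept on a reference pool of genotype scores
  pool <- draw_genotypes(20000)
  s <- as.vector(pool$G %*% beta)
  alpha <- stats::uniroot(
    function(a) mean(stats::plogis(a + s)) - baseline_prevalence,
    interval = c(-50, 50), tol = 1e-10)$root

  # rejection sampling to the two quotas
  need_ca <- n_cases; need_co <- n_controls
  G_ca <- G_co <- matrix(0L, 0, m); pop_ca <- pop_co <- integer(0)
  drawn <- 0; total_cases <- 0
  chunk <- max(2000, ceiling((n_cases + n_controls) / 2))
  while (need_ca > 0 || need_co > 0) {
    if (drawn >= max_draws) {
      stop_param(sprintf(
        paste0("prevalence unattainable: after %d draws the empirical ",
               "prevalence was %.4g but %d case(s) and %d control(s) ",
               "are still needed"),
        drawn, total_cases / max(drawn, 1), need_ca, need_co))
    }
    d <- draw_genotypes(chunk)
    drawn <- drawn + chunk
    pr <- stats::plogis(alpha + as.vector(d$G %*% beta))
    y <- stats::rbinom(chunk, 1, pr)
    total_cases <- total_cases + sum(y)
    ica <- which(y == 1)[seq_len(min(need_ca, sum(y == 1)))]
    ico <- which(y == 0)[seq_len(min(need_co, sum(y == 0)))]
    if (length(ica) > 0) {
      G_ca <- rbind(G_ca, d$G[ica, , drop = FALSE])
      pop_ca <- c(pop_ca, d$pop[ica]); need_ca <- need_ca - length(ica)
    }
    if (length(ico) > 0) {
      G_co <- rbind(G_co, d$G[ico, , drop = FALSE])
      pop_co <- c(pop_co, d$pop[ico]); need_co <- need_co - length(ico)
    }
  }

  n <- n_cases + n_controls
  G <- rbind(G_ca, G_co)
  status <- c(rep(1L, n_cases), rep(0L, n_controls))
  subpop <- c(pop_ca, pop_co)
  ord <- sample(n)  # shuffle so file order carries no phenotype signal
  G <- G[ord, , drop = FALSE]; status <- status[ord]; subpop <- subpop[ord]

  storage.mode(G) <- "integer"
  if (missing_rate > 0)
    G[stats::runif(length(G)) < missing_rate] <- NA_integer_
  rownames(G) <- sprintf("S%05d", seq_len(n))
  colnames(G) <- variants$id

  samples <- data.frame(
    sample_id = rownames(G), status = status,
    age = round(stats::runif(n, age_range[1], age_range[2]), 1),
    sex = sample(c(1L, 2L), n, replace = TRUE), subpop = subpop,
    stringsAsFactors = FALSE)
  # Ancestry PCs are only estimable when the panel is wide enough that
  # no single variant dominates a component; on a narrow panel the top
  # PCs are linear combinations of the tested dosages themselves and
  # would absorb the association signal. Below 25 variants the PC
  # columns are attached as zeros (equivalent to omitting them).
  pcs <- if (m >= 25) dosage_pcs(G, n_pcs = 10) else
    matrix(0, n, 10, dimnames = list(NULL, paste0("PC", 1:10)))
  samples <- cbind(samples, pcs)

  structure(list(dosages = G, variants = variants, samples = samples,
                 truth = list(intercept = alpha, subpop_freqs = freqs,
                              rng_seed = rng_seed)),
            class = "genotype_panel")
}

# Top principal components of the mean-imputed, centred dosage matrix,
# zero-padded to n_pcs columns (PC1..PCn) when fewer are estimable.
dosage_pcs <- function(G, n_pcs = 10) {
  X <- apply(G, 2, function(col) {
    mu <- mean(col, na.rm = TRUE)
    col[is.na(col)] <- if (is.nan(mu)) 0 else mu
    col
  })
  X <- scale(X, center = TRUE, scale = FALSE)
  k_max <- min(dim(X)) - 1
  out <- matrix(0, nrow = nrow(G), ncol = n_pcs,
                dimnames = list(NULL, paste0("PC", seq_len(n_pcs))))
  if (k_max >= 1) {
    pr <- stats::prcomp(X, center = FALSE)
    k <- min(n_pcs, ncol(pr$x))
    out[, seq_len(k)] <- pr$x[, seq_len(k)]
  }
  out
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("Genotype panel: %d samples (%d cases / %d controls), %d variant(s)\n",
              nrow(x$dosages), sum(x$samples$status == 1),
              sum(x$samples$status == 0), ncol(x$dosages)))
  invisible(x)
}

#' Construct a genotype panel from components
#'
#' Low-level constructor used when reading panels from files or
#' building small panels in tests.
#'
#' @param dosages Samples x variants integer matrix in \{0,1,2,NA\}
#'   with row and column names.
#' @param variants Data frame with one row per dosage column (must
#'   include \code{id}); recycled minimal columns are filled if absent.
#' @param samples Data frame with \code{sample_id} and binary
#'   \code{status} (1 = case); \code{age}, \code{sex} and PC columns
#'   are optional.
#' @return A \code{genotype_panel}.
#' @export
genotype_panel <- function(dosages, variants, samples) {
  stopifnot(nrow(dosages) == nrow(samples),
            ncol(dosages) == nrow(variants))
  if (anyNA(samples$status)) stop_param("phenotype must be non-missing")
  if (!all(samples$status %in% c(0L, 1L)))
    stop_param("status must be coded 1 = case, 0 = control")
  ok <- dosages %in% c(0L, 1L, 2L) | is.na(dosages)
  if (!all(ok)) stop_param("dosages must be 0, 1, 2 or missing")
  structure(list(dosages = dosages, variants = variants,
                 samples = samples),
            class = "genotype_panel")
}

#' Restrict a panel to a subset of variants
#'
#' @param panel A \code{genotype_panel}.
#' @param variant_ids Variant identifiers to keep (order preserved).
#' @return A \code{genotype_panel} with the selected columns; sample
#'   covariates (including PCs) are unchanged.
#' @export
subset_panel <- function(panel, variant_ids) {
  miss <- setdiff(variant_ids, colnames(panel$dosages))
  if (length(miss) > 0)
    stop_param("variant(s) absent from panel: ",
               paste(miss, collapse = ", "))
  idx <- match(variant_ids, panel$variants$id)
  structure(list(dosages = panel$dosages[, variant_ids, drop = FALSE],
                 variants = panel$variants[idx, , drop = FALSE],
                 samples = panel$samples,
                 truth = panel$truth),
            class = "genotype_panel")
}
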