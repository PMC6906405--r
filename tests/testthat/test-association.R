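# tiny panel builder: dosage columns given explicitly
panel_from_dosages <- function(D, status, age = NULL) {
  n <- nrow(D)
  samples <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)), status = status,
    age = age %||% rep(50, n), sex = 1L)
  for (k in 1:10) samples[[paste0("PC", k)]] <- 0
  variants <- data.frame(id = colnames(D), chrom = "1",
                         position = seq_len(ncol(D)),
                         ref = "A", alt = "G")
  genotype_panel(D, variants, samples)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("allele counts and frequencies use non-missing denominators", {
  # replication-set layout: 60 cases with 10 alt alleles,
  # 8214 controls with 676 alt alleles
  D <- matrix(0L, nrow = 60 + 8214, ncol = 1,
              dimnames = list(NULL, "gba"))
  status <- c(rep(1L, 60), rep(0L, 8214))
  D[1:10, 1] <- 1L
  D[61:736, 1] <- 1L
  p <- panel_from_dosages(D, status)
  st <- allele_stats(p, "gba")
  expect_equal(st$c_a, 10)
  expect_equal(st$c_u, 676)
  expect_equal(round(st$f_a, 3), 0.083)
  expect_equal(round(st$f_u, 5), 0.04115)

  # missing genotypes shrink the denominator
  D[1:5, 1] <- NA
  p2 <- panel_from_dosages(D, status)
  st2 <- allele_stats(p2, "gba")
  expect_equal(st2$n_cases, 55)
  expect_equal(st2$f_a, st2$c_a / 110)
})

test_that("crude odds ratio matches the cross product, with correction", {
  expect_equal(crude_odds_ratio(5, 100, 5, 100)$or, 1.0)
  r <- crude_odds_ratio(10, 120, 676, 16428)
  expect_equal(round(r$or, 3), 2.118)
  expect_false(r$corrected)
  z <- crude_odds_ratio(0, 100, 10, 200)
  expect_true(z$corrected)
  expect_true(is.finite(z$or) && z$or < 1)
  expect_error(crude_odds_ratio(1, 0, 1, 10), "margin")
})

test_that("SVA agrees with the crude OR when no covariates are used", {
  set.seed(3)
  D <- matrix(rbinom(400, 1, 0.3), ncol = 1,
              dimnames = list(NULL, "v"))
  status <- rbinom(400, 1, stats::plogis(-1 + 0.8 * D[, 1]))
  p <- panel_from_dosages(D, status)
  s <- logistic_sva(p, n_pcs = 0)
  # {0,1} dosages make the logistic slope the 2x2 log odds ratio,
  # with table cells counted on samples rather than alleles
  tab <- table(D[, 1], status)
  or22 <- (tab["1", "1"] / tab["1", "0"]) / (tab["0", "1"] / tab["0", "0"])
  expect_equal(s$or, or22, tolerance = 1e-6)
})

test_that("SVA skips monomorphic variants and flags them", {
  D <- cbind(mono = rep(0L, 40), poly = rep(c(0L, 1L), 20))
  p <- panel_from_dosages(D, rep(c(1L, 0L), each = 20))
  s <- logistic_sva(p, n_pcs = 0)
  expect_equal(s$fit_status[s$id == "mono"], "monomorphic")
  expect_true(is.na(s$p[s$id == "mono"]))
  expect_equal(s$fit_status[s$id == "poly"], "ok")
  expect_error(logistic_sva(panel_from_dosages(D, rep(1L, 40))),
               "2 cases")
})

test_that("genomic inflation factor is exact at the null median", {
  expect_equal(genomic_lambda(rep(0.5, 7)), 1.0)
  # scale equivariance: doubling the chi-squares doubles lambda
  set.seed(9)
  p <- runif(200)
  chi2 <- 2 * qchisq(p, 1, lower.tail = FALSE)
  p2 <- pchisq(chi2, 1, lower.tail = FALSE)
  expect_equal(genomic_lambda(p2), 2 * genomic_lambda(p),
               tolerance = 1e-10)
  set.seed(10)
  expect_equal(genomic_lambda(runif(10001)), 1.0, tolerance = 0.05)
  expect_error(genomic_lambda(NA_real_), "p-values")
  # invariant to order
  expect_equal(genomic_lambda(p), genomic_lambda(rev(p)))
})

test_that("threshold scan picks the smallest qualifying cutoff", {
  set.seed(12)
  p <- c(runif(11, 0, 4e-4), runif(89, 0.01, 1))
  sel <- select_candidate_threshold(p, thresholds = c(0.05, 5e-4),
                                    min_variants = 11)
  expect_equal(sel$threshold, 5e-4)
  expect_equal(length(sel$selected), 11)
  expect_false(sel$fallback)
  # brute-force scan agrees
  for (t in c(0.05, 5e-4))
    expect_equal(unname(sel$counts[as.character(t)]), sum(p < t))

  expect_warning(
    fb <- select_candidate_threshold(runif(20, 0.2, 1),
                                     thresholds = c(0.05, 5e-4),
                                     min_variants = 11),
    "falling back")
  expect_equal(fb$threshold, 0.05)
  expect_true(fb$fallback)
  expect_error(select_candidate_threshold(p, thresholds = c(0.01, 0.05)),
               "decreasing")
})

test_that("Bonferroni cutoff", {
  expect_equal(round(bonferroni_threshold(0.05, 11), 4), 0.0045)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 2), 0.025)
  expect_error(bonferroni_threshold(0.05, 0), "m must")
})

test_that("PRS variant selection applies p, exclusion, MAF and LD rules", {
  # discovery/replication rows shaped like a candidate table
  disc <- data.frame(
    id = c("u1", "gba", "t1", "t2", "t3", "t4", "t5", "ik", "mir",
           "ina", "kars", "null1"),
    p = c(8e-4, 8.9e-6, 4.3e-4, 3.3e-4, 3.3e-4, 3.3e-4, 3.3e-4,
          1e-4, 1.1e-11, 5.1e-5, 5.2e-5, 0.4),
    f_a = c(0.0148, 0.0855, 0.1378, 0.1355, 0.1355, 0.1355, 0.1355,
            0.0353, 0.0966, 0.0294, 0.0957, 0.2))
  repl <- data.frame(
    id = disc$id,
    f_a = c(0, 0.083, 0.167, 0.167, 0.167, 0.167, 0.167,
            0, 0.000609, 0.05, 0.15, 0.21))
  sel <- select_prs_variants(
    disc, repl,
    ld_blocks = list(c("t1", "t2", "t3", "t4", "t5")),
    ld_representatives = "t5",
    exclusions = c("mir", "ina"),
    p_cutoff = 5e-4, maf_tolerance = 0.5)
  expect_setequal(sel$variants, c("gba", "t5"))
  reasons <- setNames(sel$dropped$reason, sel$dropped$id)
  expect_equal(unname(reasons["u1"]), "discovery_p")   # p >= 5e-4
  expect_equal(unname(reasons["mir"]), "excluded")
  expect_equal(unname(reasons["kars"]), "maf_dissimilar")
  expect_equal(unname(reasons["ik"]), "maf_dissimilar")
  expect_equal(unname(reasons["t1"]), "ld_block")

  # representative must belong to its block
  expect_error(select_prs_variants(disc, repl,
                                   ld_blocks = list(c("t1", "t2")),
                                   ld_representatives = "gba"),
               "not in its LD block")

  # degenerate config: pure p + MAF filter
  sel2 <- select_prs_variants(disc, repl, p_cutoff = 5e-4,
                              maf_tolerance = 0.5)
  expect_setequal(sel2$variants, c("gba", "t1", "t2", "t3", "t4", "t5"))
})
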