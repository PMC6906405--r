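test_that("confusion metrics reproduce hand-computed values", {
  m <- confusion_metrics(tp = 23, fn = 37, fp = 2199, tn = 6015)
  expect_equal(round(m$sensitivity, 2), 0.38)
  expect_equal(round(m$specificity, 2), 0.73)
  expect_equal(round(m$accuracy, 2), 0.73)
  expect_equal(round(m$balanced_accuracy, 2), 0.56)

  chance <- confusion_metrics(tp = 10, fn = 10, fp = 25, tn = 25)
  expect_equal(chance$balanced_accuracy, 0.5)

  perfect <- confusion_metrics(tp = 5, fn = 0, fp = 0, tn = 20)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$accuracy, 1)

  expect_error(confusion_metrics(tp = 0, fn = 0, fp = 0, tn = 0),
               "empty")
  # list input (confusion_matrix output) works too
  cm <- confusion_matrix(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(confusion_metrics(cm)$accuracy, 0.5)
})

test_that("AUC equals the pair-count oracle and handles ties", {
  labels <- c(rep(1, 5), rep(0, 5))
  expect_equal(auc_with_ci(c(6:10, 1:5), labels)$auc, 1.0)
  expect_equal(auc_with_ci(rep(3, 10), labels)$auc, 0.5)

  set.seed(20)
  for (i in 1:5) {
    sc <- sample(1:8, 30, replace = TRUE)  # forces ties
    lb <- rbinom(30, 1, 0.4)
    if (length(unique(lb)) < 2) next
    a <- auc_with_ci(sc, lb)
    expect_equal(a$auc, oracle_auc(sc, lb), tolerance = 1e-12)
    expect_true(a$ci_low <= a$auc && a$auc <= a$ci_high)
    expect_true(a$ci_low >= 0 && a$ci_high <= 1)
  }
  expect_error(auc_with_ci(1:4, rep(1, 4)), "both classes")
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(21)
  sc <- rnorm(40)
  lb <- rbinom(40, 1, 0.5)
  a1 <- auc_with_ci(sc, lb)$auc
  expect_equal(auc_with_ci(exp(sc), lb)$auc, a1)
  expect_equal(auc_with_ci(qlogis(plogis(sc)), lb)$auc, a1,
               tolerance = 1e-12)
})

sim_two_feature_panel <- function(n_cases, n_controls, or1, or2, seed) {
  v <- rbind(variant_spec("inf", 0.2, or1, position = 10),
             variant_spec("noise", 0.2, or2, position = 20))
  simulate_cohort(n_cases, n_controls, v, rng_seed = seed)
}

test_that("random forest importances rank informative over noise", {
  hits <- 0
  for (r in 1:10) {
    p <- sim_two_feature_panel(400, 400, or1 = 3, or2 = 1,
                               seed = 900 + r)
    fit <- fit_variant_model(p, c("inf", "noise"), n_trees = 200,
                             rng_seed = r)
    expect_equal(sum(fit$importances), 1, tolerance = 1e-12)
    expect_true(all(fit$importances >= 0))
    if (fit$importances["inf"] > 0.5) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("random forest is deterministic under a fixed seed", {
  p <- sim_two_feature_panel(150, 150, 2.5, 1, seed = 5)
  f1 <- fit_variant_model(p, c("inf", "noise"), n_trees = 100,
                          rng_seed = 42)
  f2 <- fit_variant_model(p, c("inf", "noise"), n_trees = 100,
                          rng_seed = 42)
  expect_identical(f1$importances, f2$importances)
  expect_identical(predict(f1, p, type = "prob"),
                   predict(f2, p, type = "prob"))
  expect_error(fit_variant_model(
    genotype_panel(p$dosages,
                   p$variants,
                   transform(p$samples, status = 0L)),
    c("inf", "noise")), "single class")
})

test_that("duplicate features still give normalized importances", {
  p <- sim_two_feature_panel(200, 200, 2.5, 2.5, seed = 6)
  # make the second column a duplicate of the first
  p$dosages[, "noise"] <- p$dosages[, "inf"]
  fit <- fit_variant_model(p, c("inf", "noise"), n_trees = 100,
                           rng_seed = 1)
  expect_equal(sum(fit$importances), 1, tolerance = 1e-12)
})

test_that("PRS classifier separates separable classes", {
  set.seed(30)
  tr_sc <- c(rnorm(200, 0), rnorm(50, 4))
  tr_lb <- c(rep(0, 200), rep(1, 50))
  fit <- fit_prs_model(tr_sc, tr_lb)
  te_sc <- c(rnorm(400, 0), rnorm(100, 4))
  te_lb <- c(rep(0, 400), rep(1, 100))
  pred <- predict(fit, te_sc)
  m <- confusion_metrics(confusion_matrix(te_lb, pred))
  expect_gt(m$balanced_accuracy, 0.9)
  expect_error(fit_prs_model(rep(1, 10), rep(c(0, 1), 5)), "constant")
})

test_that("PRS classifier is at chance under independent labels", {
  set.seed(31)
  tr_sc <- rnorm(2000); tr_lb <- rbinom(2000, 1, 0.2)
  fit <- fit_prs_model(tr_sc, tr_lb)
  te_sc <- rnorm(5000); te_lb <- rbinom(5000, 1, 0.2)
  m <- confusion_metrics(confusion_matrix(te_lb, predict(fit, te_sc)))
  expect_lt(abs(m$balanced_accuracy - 0.5), 0.05)
})

test_that("decision rule is invariant to monotone probability transforms", {
  set.seed(32)
  sc <- rnorm(100)
  fit <- fit_prs_model(sc, rbinom(100, 1, plogis(sc)))
  prob <- predict(fit, sc, type = "prob")
  expect_identical(predict(fit, sc),
                   as.integer(qlogis(prob) > qlogis(fit$threshold)))
})

test_that("classifier evaluation combines confusion metrics and AUC", {
  set.seed(33)
  lb <- rbinom(80, 1, 0.5)
  sc <- lb + rnorm(80, sd = 0.8)
  ev <- eval_classifier(lb, as.integer(sc > 0.5), sc)
  expect_equal(ev$balanced_accuracy,
               (ev$sensitivity + ev$specificity) / 2)
  expect_equal(ev$auc, oracle_auc(sc, lb), tolerance = 1e-12)
})
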