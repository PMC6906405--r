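#' Threshold classification metrics from a confusion matrix
#'
#' Sensitivity \code{tp/(tp+fn)}, specificity \code{tn/(fp+tn)},
#' accuracy \code{(tp+tn)/total} and balanced accuracy (the arithmetic
#' mean of sensitivity and specificity, robust to heavy class
#' imbalance).
#'
#' @param tp,fn,fp,tn Non-negative counts; alternatively pass a list
#'   with those elements as \code{tp}.
#' @return List with \code{sensitivity}, \code{specificity},
#'   \code{accuracy}, \code{balanced_accuracy} and the input counts.
#'   An empty actual class makes the affected metrics \code{NaN} (and
#'   is rejected when both margins are empty).
#' @export
confusion_metrics <- function(tp, fn = NULL, fp = NULL, tn = NULL) {
  if (is.list(tp)) {
    cm <- tp; tp <- cm$tp; fn <- cm$fn; fp <- cm$fp; tn <- cm$tn
  }
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0)) stop_param("counts must be non-negative")
  if (tp + fn == 0 && fp + tn == 0)
    stop_param("confusion matrix is empty")
  sens <- tp / (tp + fn)
  spec <- tn / (fp + tn)
  list(sensitivity = sens, specificity = spec,
       accuracy = (tp + tn) / sum(counts),
       balanced_accuracy = (sens + spec) / 2,
       tp = tp, fn = fn, fp = fp, tn = tn)
}

#' Confusion matrix from actual and predicted classes
#'
#' @param actual Binary vector (1 = case).
#' @param predicted Binary vector of predicted classes.
#' @return List with \code{tp}, \code{fn}, \code{fp}, \code{tn}.
#' @export
confusion_matrix <- function(actual, predicted) {
  list(tp = sum(actual == 1 & predicted == 1),
       fn = sum(actual == 1 & predicted == 0),
       fp = sum(actual == 0 & predicted == 1),
       tn = sum(actual == 0 & predicted == 0))
}

#' AUC with DeLong 95% confidence interval
#'
#' AUC as the Mann-Whitney probability that a random case outscores a
#' random control, ties counting one half; the confidence interval
#' uses the DeLong variance estimate (via \pkg{pROC}), clipped to
#' [0, 1].
#'
#' @param scores Numeric classifier scores.
#' @param labels Binary labels (1 = case); both classes must be
#'   present.
#' @return List with \code{auc}, \code{ci_low}, \code{ci_high}.
#' @export
auc_with_ci <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop_param("both classes must be present")
  r <- pROC::roc(response = labels, predictor = as.numeric(scores),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  ci <- suppressWarnings(
    as.numeric(pROC::ci.auc(r, method = "delong")))
  list(auc = as.numeric(pROC::auc(r)),
       ci_low = max(0, ci[1]), ci_high = min(1, ci[3]))
}

#' Fit the variant prediction model (balanced random forest)
#'
#' Trains a random-forest classifier on the allele dosages of the
#' selected variants. Class balancing uses stratified down-sampling
#' (each tree sees equal numbers of cases and controls), so the model
#' is not dominated by the control majority. Feature importance is
#' mean decrease in impurity (MDI): the accumulated Gini-impurity
#' reduction per feature, normalized to sum to 1.
#'
#' @param panel Training \code{genotype_panel}.
#' @param variant_ids Feature variants (dosage columns).
#' @param n_trees Ensemble size (default 500).
#' @param rng_seed Integer seed; fixed seed gives identical forests.
#' @return Object of class \code{variant_model}: list with
#'   \code{forest}, \code{importances} (named, sums to 1) and
#'   \code{features}.
#' @export
fit_variant_model <- function(panel, variant_ids, n_trees = 500,
                              rng_seed = 1L) {
  y <- factor(panel$samples$status, levels = c(0, 1),
              labels = c("control", "case"))
  if (length(unique(panel$samples$status)) < 2)
    stop_param("training labels contain a single class")
  X <- panel$dosages[, variant_ids, drop = FALSE]
  X[is.na(X)] <- 0L
  X <- as.data.frame(X)
  nmin <- min(table(y))
  set.seed(rng_seed)
  rf <- randomForest::randomForest(
    x = X, y = y, ntree = n_trees, strata = y,
    sampsize = c(nmin, nmin))
  imp <- rf$importance[, "MeanDecreaseGini"]
  tot <- sum(imp)
  importances <- if (tot > 0) imp / tot else imp
  structure(list(forest = rf,
                 importances = stats::setNames(importances, variant_ids),
                 features = variant_ids),
            class = "variant_model")
}

#' @export
predict.variant_model <- function(object, panel,
                                  type = c("class", "prob"),
                                  threshold = 0.5, ...) {
  type <- match.arg(type)
  X <- panel$dosages[, object$features, drop = FALSE]
  X[is.na(X)] <- 0L
  pr <- stats::predict(object$forest, as.data.frame(X),
                       type = "prob")[, "case"]
  if (type == "prob") return(pr)
  as.integer(pr > threshold)
}

#' Fit the PRS prediction model (weighted logistic classifier)
#'
#' Univariate logistic regression of case status on the PRS, with
#' inverse-class-frequency observation weights so the decision rule is
#' not degenerate under heavy case-control imbalance. The predicted
#' class is 1 when the class-weighted probability exceeds the
#' threshold.
#'
#' @param train_scores Numeric PRS vector (non-constant).
#' @param train_labels Binary labels (1 = case), both classes present.
#' @param threshold Probability decision threshold (default 0.5).
#' @return Object of class \code{prs_classifier}: list with
#'   \code{coefficients}, \code{threshold} and the fitted \code{glm}.
#' @export
fit_prs_model <- function(train_scores, train_labels,
                          threshold = 0.5) {
  y <- as.integer(train_labels)
  if (length(unique(y)) < 2)
    stop_param("both classes must be present")
  if (max(train_scores) == min(train_scores))
    stop_param("constant scores: classifier undefined")
  n <- length(y)
  w <- ifelse(y == 1, n / (2 * sum(y == 1)), n / (2 * sum(y == 0)))
  dat <- data.frame(y = y, score = as.numeric(train_scores))
  fit <- suppressWarnings(
    stats::glm(y ~ score, data = dat, family = stats::binomial(),
               weights = w))
  structure(list(coefficients = stats::coef(fit),
                 threshold = threshold, fit = fit),
            class = "prs_classifier")
}

#' @export
predict.prs_classifier <- function(object, scores,
                                   type = c("class", "prob"), ...) {
  type <- match.arg(type)
  pr <- stats::plogis(object$coefficients[1] +
                        object$coefficients[2] * as.numeric(scores))
  if (type == "prob") return(unname(pr))
  unname(as.integer(pr > object$threshold))
}

#' Evaluate a classifier on held-out labels
#'
#' Combines the confusion-matrix metrics with AUC and its DeLong 95\%
#' confidence interval.
#'
#' @param actual Binary labels (1 = case).
#' @param predicted Predicted binary classes.
#' @param scores Optional continuous scores for the AUC (defaults to
#'   \code{predicted}).
#' @return List with the confusion counts, threshold metrics,
#'   \code{auc}, \code{auc_ci_low} and \code{auc_ci_high}.
#' @export
eval_classifier <- function(actual, predicted, scores = NULL) {
  cm <- confusion_matrix(actual, predicted)
  metrics <- confusion_metrics(cm)
  if (is.null(scores)) scores <- predicted
  a <- auc_with_ci(scores, actual)
  c(metrics, list(auc = a$auc, auc_ci_low = a$ci_low,
                  auc_ci_high = a$ci_high))
}
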