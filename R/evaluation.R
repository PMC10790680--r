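# ROC/AUC machinery, confusion-matrix metrics, stratified k-fold
# cross-validation of the PLS classifier, and DeLong comparison of
# correlated ROC curves.

#' ROC curve and AUC with standard error and confidence interval
#'
#' AUC by the Mann-Whitney estimator (ties count 0.5): the probability
#' that a random responder scores above a random nonresponder. Standard
#' error by the Hanley-McNeil formula; 95% CI by the logit-normal
#' approximation, clipped to `[0, 1]` (degenerate at the point estimate
#' when the SE is zero). ROC points use the strict rule
#' "positive iff score > threshold", matching [predict.pls_model()].
#'
#' @param scores numeric scores.
#' @param y response labels (`"responder"` = positive / `"nonresponder"`).
#' @return object of class `roc_result`: `points` (threshold, fpr, tpr),
#'   `auc`, `se`, `ci` (length 2), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, y) {
  yy <- code_response(y)
  n1 <- sum(yy == 1); n2 <- sum(yy == -1)
  if (n1 == 0L || n2 == 0L) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  auc <- (sum(r[yy == 1]) - n1 * (n1 + 1) / 2) / (n1 * n2)

  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n2 - 1) * (q2 - auc^2)) / (n1 * n2))
  if (!is.finite(se) || se <= 0 || auc <= 0 || auc >= 1) {
    ci <- c(auc, auc)
  } else {
    lg <- stats::qlogis(auc)
    se_lg <- se / (auc * (1 - auc))
    ci <- stats::plogis(lg + c(-1, 1) * stats::qnorm(0.975) * se_lg)
  }
  ci <- pmin(pmax(ci, 0), 1)

  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pos <- scores[yy == 1]; neg <- scores[yy == -1]
  points <- data.frame(threshold = thr,
                       fpr = vapply(thr, function(t) mean(neg > t), 0),
                       tpr = vapply(thr, function(t) mean(pos > t), 0))
  structure(list(points = points, auc = auc, se = se, ci = ci,
                 n_pos = n1, n_neg = n2),
            class = "roc_result")
}

#' Sensitivity, specificity and accuracy from a confusion matrix
#'
#' Sensitivity = TP/(TP+FN); Specificity = TN/(TN+FP);
#' Accuracy = (TP+TN)/N with N = TP+TN+FP+FN.
#'
#' @param tp,tn,fp,fn non-negative counts.
#' @return named numeric: `sensitivity`, `specificity`, `accuracy`.
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  v <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(v < 0) || any(v != round(v)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (tp + fn == 0) stop("sensitivity undefined: TP + FN = 0", call. = FALSE)
  if (tn + fp == 0) stop("specificity undefined: TN + FP = 0", call. = FALSE)
  c(sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    accuracy = (tp + tn) / sum(v))
}

stratified_folds <- function(y, k, seed) {
  yy <- code_response(y)
  set.seed(seed)
  fold <- integer(length(yy))
  classes <- sort(unique(yy), decreasing = TRUE)
  for (ci in seq_along(classes)) {
    idx <- sample(which(yy == classes[ci]))
    # rotate the fold cycle per class so remainders land on different folds
    fold[idx] <- ((seq_along(idx) - 1L + (ci - 1L)) %% k) + 1L
  }
  fold
}

#' Stratified k-fold cross-validation of the PLS classifier
#'
#' Folds come from a seeded shuffle stratified by class (the fold cycle is
#' rotated between classes so class remainders spread across folds). Per
#' fold, [pls_fit()] is trained on the remaining samples and accuracy,
#' sensitivity, specificity and AUC are measured on the held-out fold.
#' When a class has fewer members than folds some folds lack that class;
#' metrics undefined on such folds are `NA` and are excluded from the
#' means with a warning.
#'
#' @param X samples x genes matrix (the model panel).
#' @param y response labels aligned with rows of `X`.
#' @param k number of folds (>= 2).
#' @param seed integer seed for the fold shuffle.
#' @return list of class `cv_report`: `folds` (per-fold data.frame),
#'   `mean_accuracy`, `mean_sensitivity`, `mean_specificity`, `mean_auc`,
#'   `fold_assignment`, `k`, `seed`.
#' @export
cross_validate <- function(X, y, k = 5L, seed = 1L) {
  X <- as.matrix(X)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  yy <- code_response(y)
  if (length(yy) != nrow(X)) stop("X and y dimensions disagree", call. = FALSE)
  fold <- stratified_folds(y, k, seed)

  rows <- lapply(seq_len(k), function(f) {
    tr <- fold != f; te <- !tr
    model <- pls_fit(X[tr, , drop = FALSE], if (is.data.frame(y)) y[tr, ] else y[tr])
    pred <- predict(model, X[te, , drop = FALSE])
    truth <- ifelse(yy[te] == 1, "responder", "nonresponder")
    tp <- sum(pred == "responder" & truth == "responder")
    tn <- sum(pred == "nonresponder" & truth == "nonresponder")
    fp <- sum(pred == "responder" & truth == "nonresponder")
    fn <- sum(pred == "nonresponder" & truth == "responder")
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    auc <- if (tp + fn > 0 && tn + fp > 0)
      roc_auc(pls_score(model, X[te, , drop = FALSE]), truth)$auc
    else NA_real_
    data.frame(fold = f, n_test = sum(te),
               accuracy = (tp + tn) / sum(te),
               sensitivity = sens, specificity = spec, auc = auc)
  })
  folds <- do.call(rbind, rows)
  if (anyNA(folds[, c("sensitivity", "specificity", "auc")]))
    warning("fold(s) with a single class: undefined metrics excluded from means")
  structure(list(folds = folds,
                 mean_accuracy = mean(folds$accuracy),
                 mean_sensitivity = mean(folds$sensitivity, na.rm = TRUE),
                 mean_specificity = mean(folds$specificity, na.rm = TRUE),
                 mean_auc = mean(folds$auc, na.rm = TRUE),
                 fold_assignment = fold, k = k, seed = seed),
            class = "cv_report")
}

# placement components of the Mann-Whitney AUC (ties 0.5)
delong_placements <- function(scores, yy) {
  pos <- scores[yy == 1]; neg <- scores[yy == -1]
  v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)), 0)
  v01 <- vapply(neg, function(x) mean((pos > x) + 0.5 * (pos == x)), 0)
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong test comparing two correlated ROC curves
#'
#' Two-sided test of equal AUC for two score vectors on the same samples,
#' using the DeLong variance of the paired AUC difference. When that
#' variance is zero (e.g. identical or rank-identical scores) the p-value
#' is 1 for equal AUCs and 0 otherwise.
#'
#' @param scores_a,scores_b paired numeric score vectors.
#' @param y response labels for the shared samples.
#' @return list: `auc_a`, `auc_b`, `z`, `p_value`.
#' @export
compare_roc <- function(scores_a, scores_b, y) {
  yy <- code_response(y)
  if (length(scores_a) != length(scores_b) || length(scores_a) != length(yy))
    stop("scores and labels must be paired", call. = FALSE)
  if (length(unique(yy)) < 2L) stop("both classes must be present", call. = FALSE)
  pa <- delong_placements(scores_a, yy)
  pb <- delong_placements(scores_b, yy)
  n1 <- sum(yy == 1); n2 <- sum(yy == -1)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n2
  d <- pa$auc - pb$auc
  if (!is.finite(v) || v <= 0) {
    z <- if (d == 0) 0 else sign(d) * Inf
  } else {
    z <- d / sqrt(v)
  }
  list(auc_a = pa$auc, auc_b = pb$auc, z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}
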