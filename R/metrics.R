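#' F1 score for binary predictions
#'
#' Harmonic mean of precision and recall for the positive class (label 1, the
#' minority class in the simulated task; configurable). Zero-division
#' conventions: if there are no positive predictions, no true positives, or
#' precision + recall is zero, the score is 0, never NaN.
#'
#' @param y_true,y_pred Equal-length binary (0/1) vectors.
#' @param positive The label treated as the positive class (default 1).
#' @return F1 in \[0, 1\].
#' @export
#' @examples
#' f1_score(c(1, 1, 0, 0), c(1, 0, 1, 0)) # 0.5
f1_score <- function(y_true, y_pred, positive = 1L) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  tp <- sum(y_true == positive & y_pred == positive)
  fp <- sum(y_true != positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  if (tp == 0) return(0)
  prec <- tp / (tp + fp)
  rec <- tp / (tp + fn)
  2 * prec * rec / (prec + rec)
}

#' Balanced accuracy
#'
#' Mean of the per-class recalls; equals plain accuracy when the classes are
#' exactly balanced, and is robust to imbalance otherwise.
#'
#' @param y_true,y_pred Equal-length binary (0/1) vectors; `y_true` must
#'   contain both classes.
#' @return Balanced accuracy in \[0, 1\].
#' @export
balanced_accuracy <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  classes <- sort(unique(y_true))
  if (length(classes) < 2L)
    stop("y_true contains a single class; balanced accuracy is undefined")
  mean(vapply(classes,
              function(cl) mean(y_pred[y_true == cl] == cl), numeric(1)))
}

#' Weight-separation statistics
#'
#' Compares the meta-learned aggregate weights of correctly labeled and
#' mislabeled training samples: group means, the fraction of mislabeled
#' samples whose weight is exactly zero (weights are exactly zero whenever
#' the raw meta-gradient was non-positive, so no tolerance is used), and a
#' two-sided Wilcoxon rank-sum test. The test is exact for groups of at most
#' 10 without ties, and otherwise uses the tie-corrected normal
#' approximation; two identical constant groups give p = 1.
#'
#' @param weights Per-sample aggregate weights.
#' @param mislabel_mask Logical vector, `TRUE` for mislabeled samples. Both
#'   groups must be non-empty.
#' @return An object of class `weight_separation`: list with
#'   `mean_weight_correct`, `mean_weight_mislabeled`,
#'   `zero_weight_fraction_mislabeled`, `statistic` (rank-sum statistic of
#'   the correctly-labeled group), `p_value`, `n_correct`, `n_mislabeled`.
#' @export
weight_separation <- function(weights, mislabel_mask) {
  mislabel_mask <- as.logical(mislabel_mask)
  stopifnot(length(weights) == length(mislabel_mask))
  correct <- weights[!mislabel_mask]
  mis <- weights[mislabel_mask]
  if (!length(correct) || !length(mis))
    stop("both the correctly-labeled and mislabeled groups must be non-empty")
  n1 <- length(correct); n2 <- length(mis)
  if (length(unique(c(correct, mis))) == 1L) {
    stat <- n1 * n2 / 2; p <- 1
  } else {
    ties <- anyDuplicated(c(correct, mis)) > 0L
    exact <- !ties && n1 <= 10L && n2 <= 10L
    ht <- suppressWarnings(
      stats::wilcox.test(correct, mis, alternative = "two.sided",
                         exact = exact, correct = TRUE))
    stat <- unname(ht$statistic); p <- ht$p.value
    if (!is.finite(p)) p <- 1
  }
  structure(list(mean_weight_correct = mean(correct),
                 mean_weight_mislabeled = mean(mis),
                 zero_weight_fraction_mislabeled = mean(mis == 0),
                 statistic = stat, p_value = p,
                 n_correct = n1, n_mislabeled = n2),
            class = "weight_separation")
}

#' @export
print.weight_separation <- function(x, ...) {
  cat(sprintf(paste0(
    "Weight separation (%d correct vs %d mislabeled)\n",
    "  mean weight: correct %.3g, mislabeled %.3g\n",
    "  mislabeled with weight exactly 0: %.1f%%\n",
    "  Wilcoxon rank-sum W = %g, two-sided p = %.3g\n"),
    x$n_correct, x$n_mislabeled, x$mean_weight_correct,
    x$mean_weight_mislabeled, 100 * x$zero_weight_fraction_mislabeled,
    x$statistic, x$p_value))
  invisible(x)
}

#' Evaluate a fitted decoder on a clean test set
#'
#' @param fit A `reweight_fit`, `mlp_fit` or bare `mlp_model`.
#' @param test A [labeled_dataset()] with clean labels.
#' @param method,condition Optional names recorded in the report.
#' @param weight_stats Optional [weight_separation()] result to attach.
#' @return An object of class `eval_report`: list with `method`, `condition`,
#'   `f1`, `balanced_accuracy`, `n_test` and `weight_stats`.
#' @export
evaluate_model <- function(fit, test, method = NULL, condition = NULL,
                           weight_stats = NULL) {
  stopifnot(inherits(test, "labeled_dataset"))
  model <- if (inherits(fit, "mlp_model")) fit else fit$model
  pred <- forward_predict(model, test$features)$labels
  structure(list(method = method, condition = condition,
                 f1 = f1_score(test$labels, pred),
                 balanced_accuracy = balanced_accuracy(test$labels, pred),
                 n_test = n_samples(test), weight_stats = weight_stats),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation%s%s: F1 = %.3f, balanced accuracy = %.3f (n = %d)\n",
              if (!is.null(x$method)) paste0(" [", x$method, "]") else "",
              if (!is.null(x$condition)) paste0(" @ ", x$condition) else "",
              x$f1, x$balanced_accuracy, x$n_test))
  if (!is.null(x$weight_stats)) print(x$weight_stats)
  invisible(x)
}

#' Long-format weight table for boxplots
#'
#' @param weights Per-sample aggregate weights.
#' @param mislabel_mask Logical mislabel indicator.
#' @return data.frame with columns `sample_id`, `weight`, `mislabeled`.
#' @export
weight_table <- function(weights, mislabel_mask) {
  data.frame(sample_id = seq_along(weights), weight = weights,
             mislabeled = as.logical(mislabel_mask))
}
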