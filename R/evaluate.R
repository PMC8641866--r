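# Evaluation: confusion counting restricted to the field of view, threshold
# metrics (accuracy, sensitivity, specificity, precision, recall, F1),
# Matthews correlation, and ROC / precision-recall curves with trapezoid AUC.

#' Binarise a probability map
#'
#' A pixel is vessel iff its probability strictly exceeds the threshold
#' (default 0.49). Probabilities are kept in floating point until this point;
#' note that the 8-bit quantisation 125/255 = 0.4902 sits just above the
#' default threshold.
#'
#' @param prob Probability map in [0, 1].
#' @param threshold Decision threshold in [0, 1].
#' @return Binary matrix of the same shape.
#' @export
binarize <- function(prob, threshold = 0.49) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      !is.finite(threshold) || threshold < 0 || threshold > 1) {
    abort_param("threshold must be a single value in [0, 1]")
  }
  if (any(prob < 0 | prob > 1)) abort_input("probabilities must lie in [0, 1]")
  (prob > threshold) + 0
}

#' Confusion counts inside the field of view
#'
#' Vessel pixels are the positive class. Only pixels with `fov == 1` are
#' counted, so `tp + fp + tn + fn` equals the FOV area.
#'
#' @param pred Binary prediction mask.
#' @param truth Binary ground-truth mask.
#' @param fov Optional binary field-of-view mask; `NULL` counts every pixel.
#' @return Object of class `rfarn_confusion`: list with `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
confusion <- function(pred, truth, fov = NULL) {
  if (!all(dim(pred) == dim(truth))) abort_input("pred and truth shapes differ")
  if (is.null(fov)) fov <- array(1, dim(pred))
  if (!all(dim(fov) == dim(pred))) abort_input("fov shape differs")
  keep <- fov == 1
  p <- pred[keep]
  t <- truth[keep]
  structure(list(tp = sum(p == 1 & t == 1), fp = sum(p == 1 & t == 0),
                 tn = sum(p == 0 & t == 0), fn = sum(p == 0 & t == 1)),
            class = "rfarn_confusion")
}

#' @export
print.rfarn_confusion <- function(x, ...) {
  cat(sprintf("<confusion tp=%d fp=%d tn=%d fn=%d (n=%d)>\n",
              x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

safe_ratio <- function(num, den) if (den == 0) NaN else num / den

#' Threshold segmentation metrics from confusion counts
#'
#' Accuracy, sensitivity (= recall), specificity, precision, F1 and Matthews
#' correlation. Ratios with a zero denominator are reported as `NaN` and the
#' affected metric names are listed in the `flags` column - they are never
#' silently set to 0.
#'
#' @param counts An [confusion()] result (or list with tp/fp/tn/fn).
#' @param threshold Optional threshold to record alongside the metrics.
#' @return One-row tibble with the metric columns, the raw counts and a
#'   `flags` string naming any undefined ratios.
#' @export
seg_metrics <- function(counts, threshold = NA_real_) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  n <- tp + fp + tn + fn
  if (n == 0) abort_input("all confusion counts are zero")
  acc <- (tp + tn) / n
  se <- safe_ratio(tp, tp + fn)
  sp <- safe_ratio(tn, tn + fp)
  prec <- safe_ratio(tp, tp + fp)
  f1 <- if (is.nan(prec) || is.nan(se) || prec + se == 0) NaN else 2 * prec * se / (prec + se)
  m <- mcc(counts)
  vals <- c(sensitivity = se, specificity = sp, precision = prec, f1 = f1, mcc = m)
  flags <- names(vals)[is.nan(vals)]
  tibble::tibble(accuracy = acc, sensitivity = se, specificity = sp,
                 precision = prec, recall = se, f1 = f1, mcc = m,
                 tp = tp, fp = fp, tn = tn, fn = fn,
                 threshold = threshold,
                 flags = if (length(flags)) paste(flags, collapse = ",") else "")
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, a balanced
#' correlation between predicted and true labels in [-1, 1]; 1 means perfect
#' agreement. If any marginal sum is zero the coefficient is undefined and
#' `NaN` is returned.
#'
#' @param counts An [confusion()] result (or list with tp/fp/tn/fn).
#' @return Value in [-1, 1], or `NaN` when undefined.
#' @export
mcc <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(NaN)
  (tp * tn - fp * fn) / den
}

#' ROC and precision-recall curves with trapezoid AUC
#'
#' Sweeps the decision threshold over every distinct probability value inside
#' the field of view. The ROC curve is (false-positive rate, true-positive
#' rate), the PR curve (recall, precision); both AUCs use the trapezoid rule.
#'
#' @param prob Probability map.
#' @param truth Binary ground-truth mask.
#' @param fov Optional binary field-of-view mask.
#' @return Object of class `rfarn_curves`: list with `roc` and `pr`, each a
#'   list with a `points` tibble and an `auc`.
#' @export
roc_pr_curves <- function(prob, truth, fov = NULL) {
  if (is.null(fov)) fov <- array(1, dim(prob))
  keep <- fov == 1
  s <- as.vector(prob[keep])
  y <- as.vector(truth[keep])
  P <- sum(y == 1)
  Nn <- sum(y == 0)
  if (P == 0 || Nn == 0) abort_input("both classes must be present inside the FOV")
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]; y <- y[ord]
  # cumulative counts at distinct-score boundaries
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  ctp <- cumsum(y)[last_of_tie]
  cfp <- cumsum(1 - y)[last_of_tie]
  tpr <- c(0, ctp / P)
  fpr <- c(0, cfp / Nn)
  roc_auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  rec <- ctp / P
  prec <- ctp / (ctp + cfp)
  rec <- c(0, rec)
  prec <- c(prec[1], prec)
  pr_auc <- sum(diff(rec) * (head(prec, -1) + tail(prec, -1)) / 2)
  structure(list(
    roc = list(points = tibble::tibble(x = fpr, y = tpr), auc = roc_auc),
    pr = list(points = tibble::tibble(x = rec, y = prec), auc = pr_auc)
  ), class = "rfarn_curves")
}

#' @export
print.rfarn_curves <- function(x, ...) {
  cat(sprintf("<rfarn_curves ROC-AUC %.4f, PR-AUC %.4f (%d points)>\n",
              x$roc$auc, x$pr$auc, nrow(x$roc$points)))
  invisible(x)
}

#' Plot ROC and PR curves
#'
#' @param object An `rfarn_curves` object.
#' @param ... Unused.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
autoplot.rfarn_curves <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort_param("ggplot2 is required for plotting")
  }
  df <- rbind(
    cbind(object$roc$points, curve = sprintf("ROC (AUC %.3f)", object$roc$auc)),
    cbind(object$pr$points, curve = sprintf("PR (AUC %.3f)", object$pr$auc))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~curve) +
    ggplot2::labs(x = "FPR / Recall", y = "TPR / Precision") +
    ggplot2::theme_minimal()
}

#' Evaluate predictions for a set of samples
#'
#' Computes per-image threshold metrics and ROC/PR AUCs inside each sample's
#' field of view, plus a micro-average (confusion counts summed over images)
#' and pooled-pixel AUCs as the headline aggregate.
#'
#' @param preds Named list of probability maps (see [predict_samples()]).
#' @param samples List of [fundus_sample()] objects in matching order.
#' @param threshold Decision threshold (default 0.49).
#' @return Object of class `rfarn_eval`: list with `per_image` (tibble),
#'   `micro` (one-row tibble with pooled AUCs) and `counts`.
#' @export
evaluate_predictions <- function(preds, samples, threshold = 0.49) {
  per <- list()
  tot <- list(tp = 0, fp = 0, tn = 0, fn = 0)
  pool_s <- c(); pool_y <- c()
  for (k in seq_along(samples)) {
    s <- samples[[k]]
    pr <- preds[[k]]
    cm <- confusion(binarize(pr, threshold), s$truth, s$fov)
    row <- seg_metrics(cm, threshold)
    cur <- roc_pr_curves(pr, s$truth, s$fov)
    row$roc_auc <- cur$roc$auc
    row$pr_auc <- cur$pr$auc
    row <- cbind(tibble::tibble(id = s$id), row)
    per[[k]] <- row
    for (nm in names(tot)) tot[[nm]] <- tot[[nm]] + cm[[nm]]
    keep <- s$fov == 1
    pool_s <- c(pool_s, as.vector(pr[keep]))
    pool_y <- c(pool_y, as.vector(s$truth[keep]))
  }
  micro <- seg_metrics(structure(tot, class = "rfarn_confusion"), threshold)
  pooled <- roc_pr_curves(matrix(pool_s, ncol = 1), matrix(pool_y, ncol = 1))
  micro$roc_auc <- pooled$roc$auc
  micro$pr_auc <- pooled$pr$auc
  structure(list(per_image = tibble::as_tibble(do.call(rbind, per)), micro = micro,
                 counts = structure(tot, class = "rfarn_confusion")),
            class = "rfarn_eval")
}

#' @export
print.rfarn_eval <- function(x, ...) {
  cat("<rfarn_eval>\n  micro-average over", nrow(x$per_image), "image(s):\n")
  m <- x$micro
  cat(sprintf("  Acc %.4f  Se %.4f  Sp %.4f  F1 %.4f  MCC %.4f  ROC-AUC %.4f\n",
              m$accuracy, m$sensitivity, m$specificity, m$f1, m$mcc, m$roc_auc))
  invisible(x)
}

#' Per-image metric table of an evaluation
#' @param x An `rfarn_eval` object.
#' @param ... Unused.
#' @return Tibble with one row per image.
#' @export
tidy.rfarn_eval <- function(x, ...) x$per_image

#' One-row micro-average summary of an evaluation
#' @param x An `rfarn_eval` object.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.rfarn_eval <- function(x, ...) x$micro

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

#' @export
autoplot <- function(object, ...) UseMethod("autoplot")
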