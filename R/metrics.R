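# Discrimination and agreement statistics for validating the burden score
# against binary high-burden labels: confusion-table metrics, AUROC (rank /
# Mann-Whitney form), AUPRC (average precision), Youden cut-point selection,
# and Cohen's kappa with its large-sample (Fleiss-Cohen-Everitt) variance.

check_scores_labels <- function(scores, labels) {
  if (length(scores) != length(labels) || length(scores) == 0) {
    stop("scores and labels must have equal positive length", call. = FALSE)
  }
  if (any(is.na(scores)) || any(is.na(labels))) {
    stop("scores/labels contain NA", call. = FALSE)
  }
  labels <- as.integer(labels)
  if (!all(labels %in% c(0, 1))) {
    stop("labels must be binary 0/1", call. = FALSE)
  }
  labels
}

#' Confusion-table metrics at a fixed threshold
#'
#' Classification rule: `score > t` predicts the positive (high-burden)
#' class.  When no positive predictions are made, precision and F1 are
#' undefined and returned as `NaN` with a warning — never silently zero.
#'
#' @param scores numeric score vector.
#' @param labels binary 0/1 labels, same length.
#' @param t decision threshold.
#' @return list of class `metric_report`: `accuracy`, `precision`,
#'   `sensitivity`, `specificity`, `f1`, `threshold_used`, and the raw
#'   counts `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_at_threshold <- function(scores, labels, t) {
  labels <- check_scores_labels(scores, labels)
  pred <- as.integer(scores > t)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  precision <- if (tp + fp == 0) {
    warning("no positive predictions at threshold ", t,
            "; precision undefined", call. = FALSE)
    NaN
  } else tp / (tp + fp)
  sensitivity <- if (tp + fn == 0) NaN else tp / (tp + fn)
  specificity <- if (tn + fp == 0) NaN else tn / (tn + fp)
  f1 <- if (is.nan(precision) || is.nan(sensitivity) ||
            precision + sensitivity == 0) {
    NaN
  } else 2 * precision * sensitivity / (precision + sensitivity)
  structure(
    list(accuracy = (tp + tn) / length(labels), precision = precision,
         sensitivity = sensitivity, specificity = specificity, f1 = f1,
         threshold_used = t, tp = tp, fp = fp, tn = tn, fn = fn),
    class = "metric_report"
  )
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) estimator with tie correction:
#' P(score+ > score-) + 0.5 P(tie), identical to the trapezoidal area under
#' the empirical ROC curve.
#'
#' @inheritParams confusion_at_threshold
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- check_scores_labels(scores, labels)
  n1 <- as.numeric(sum(labels == 1)); n0 <- as.numeric(sum(labels == 0))
  if (n1 == 0 || n0 == 0) {
    stop("auroc: both classes must be present", call. = FALSE)
  }
  r <- rank(scores)           # midranks handle ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Average-precision (right-continuous step) estimator over distinct score
#' thresholds, descending: AP = sum over thresholds of
#' (recall_i - recall_(i-1)) * precision_i.  Trapezoidal interpolation in PR
#' space is deliberately avoided (it is optimistically biased), so values
#' may sit slightly below trapezoid-based reports.
#'
#' @inheritParams confusion_at_threshold
#' @return AUPRC in (0, 1\].
#' @export
auprc <- function(scores, labels) {
  labels <- check_scores_labels(scores, labels)
  n1 <- sum(labels == 1)
  if (n1 == 0) stop("auprc: no positive labels", call. = FALSE)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- cumsum(vapply(thr, function(t) sum(labels == 1 & scores == t), 0))
  np <- cumsum(vapply(thr, function(t) sum(scores == t), 0))
  precision <- tp / np
  recall <- tp / n1
  sum(diff(c(0, recall)) * precision)
}

#' Youden-index best cut-off point
#'
#' Scans candidate thresholds — midpoints between consecutive distinct
#' observed score values — and returns the one maximizing Youden's
#' J = sensitivity + specificity - 1 under the `score > t` rule.  Ties are
#' broken toward the lower threshold (favoring sensitivity).
#'
#' @inheritParams confusion_at_threshold
#' @return list of class `threshold_result`: `bcp` (best cut-off point) and
#'   `youden_j`.
#' @export
youden_threshold <- function(scores, labels) {
  labels <- check_scores_labels(scores, labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("youden_threshold: both classes must be present", call. = FALSE)
  }
  v <- sort(unique(scores))
  if (length(v) < 2) {
    stop("youden_threshold: need at least two distinct score values",
         call. = FALSE)
  }
  cand <- (v[-length(v)] + v[-1]) / 2
  # score > t: sensitivity = P(s > t | +), specificity = P(s <= t | -)
  j <- vapply(cand, function(t) {
    sum(scores > t & labels == 1) / n1 + sum(scores <= t & labels == 0) / n0 - 1
  }, 0)
  best <- which.max(j)   # which.max returns the first (lowest) maximizer
  structure(list(bcp = cand[best], youden_j = j[best]),
            class = "threshold_result")
}

#' Cohen's kappa for two binary raters
#'
#' kappa = (po - pe) / (1 - pe) with chance agreement pe from the marginal
#' products.  The 95% CI uses the large-sample standard error of Fleiss,
#' Cohen and Everitt (1969).  In the degenerate case pe = 1 (both raters
#' constant), kappa is defined as 1 when the tables agree perfectly and is
#' otherwise an error.
#'
#' @param labels_a,labels_b equal-length binary 0/1 vectors.
#' @return list of class `kappa_result`: `kappa`, `se`, `ci_low`, `ci_high`,
#'   `po`, `pe`, `n`.
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b) || length(labels_a) == 0) {
    stop("cohens_kappa: vectors must have equal positive length",
         call. = FALSE)
  }
  a <- as.integer(labels_a); b <- as.integer(labels_b)
  if (any(is.na(a)) || any(is.na(b)) ||
      !all(a %in% c(0, 1)) || !all(b %in% c(0, 1))) {
    stop("cohens_kappa: entries must be binary 0/1", call. = FALSE)
  }
  n <- length(a)
  # 2x2 joint proportions, categories ordered (0, 1)
  p <- matrix(0, 2, 2)
  for (i in 0:1) for (j in 0:1) p[i + 1, j + 1] <- sum(a == i & b == j) / n
  prow <- rowSums(p); pcol <- colSums(p)
  po <- sum(diag(p))
  pe <- sum(prow * pcol)
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    if (abs(po - 1) < .Machine$double.eps^0.5) {
      return(structure(list(kappa = 1, se = 0, ci_low = 1, ci_high = 1,
                            po = po, pe = pe, n = n),
                       class = "kappa_result"))
    }
    stop("cohens_kappa: degenerate marginals (pe = 1) without perfect ",
         "agreement", call. = FALSE)
  }
  kappa <- (po - pe) / (1 - pe)
  # Fleiss-Cohen-Everitt (1969) large-sample variance
  A <- sum(diag(p) * (1 - (prow + pcol) * (1 - kappa))^2)
  B <- (1 - kappa)^2 *
    (p[1, 2] * (pcol[1] + prow[2])^2 + p[2, 1] * (pcol[2] + prow[1])^2)
  C <- (kappa - pe * (1 - kappa))^2
  se <- sqrt((A + B - C) / (n * (1 - pe)^2))
  structure(
    list(kappa = kappa, se = se,
         ci_low = kappa - 1.96 * se, ci_high = kappa + 1.96 * se,
         po = po, pe = pe, n = n),
    class = "kappa_result"
  )
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f (95%% CI %.3f to %.3f), n = %d\n",
              x$kappa, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Full metric block for one label definition
#'
#' Computes AUROC, AUPRC and (at the Youden-selected or supplied threshold)
#' the confusion-table metrics for one binary label.
#'
#' @inheritParams confusion_at_threshold
#' @param threshold decision threshold; `NULL` (default) selects it by
#'   [youden_threshold()].
#' @return list: `auroc`, `auprc`, `threshold`, `youden_j` (when selected),
#'   plus the `metric_report` fields.
#' @export
label_metrics <- function(scores, labels, threshold = NULL) {
  yj <- NULL
  if (is.null(threshold)) {
    yt <- youden_threshold(scores, labels)
    threshold <- yt$bcp
    yj <- yt$youden_j
  }
  conf <- confusion_at_threshold(scores, labels, threshold)
  c(list(auroc = auroc(scores, labels), auprc = auprc(scores, labels),
         youden_j = yj),
    unclass(conf))
}
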