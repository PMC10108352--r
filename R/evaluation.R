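## Evaluation metrics: DICE, best-achievable DICE over a global residual
## threshold, AUPRC (step-interpolated), AUROC (rank/trapezoid), and the
## false-positive rate at fixed true-positive rates. Conventions follow the
## segmentation/OOD evaluation protocol: the best-DICE threshold is a single
## global threshold over the pooled test set, and for FPR-at-TPR the
## "positives" are the in-distribution examples.

check_labels <- function(labels) {
  u <- unique(labels)
  if (!all(u %in% c(0, 1))) stop("labels must be binary (0/1)")
  if (length(u) < 2L) {
    stop("degenerate label set: need both positive and negative examples")
  }
  invisible(TRUE)
}

#' DICE overlap of two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; two empty masks score 1 (perfect agreement).
#'
#' @param pred,gt Binary arrays of equal shape.
#' @return Scalar in \[0,1\].
#' @export
dice <- function(pred, gt) {
  stopifnot(length(pred) == length(gt))
  a <- sum(pred > 0)
  b <- sum(gt > 0)
  if (a + b == 0) return(1)
  2 * sum(pred > 0 & gt > 0) / (a + b)
}

#' Best achievable DICE over a global residual threshold
#'
#' Greedy search for the single binarization threshold maximizing DICE over
#' the pooled test set. Candidates are all unique residual values when there
#' are at most `max_exact`, otherwise `n_grid` quantile-spaced values.
#'
#' @param residuals List of residual maps (or one array).
#' @param gt_masks List of matching binary ground-truth masks.
#' @param max_exact Use exact unique-value search up to this many candidates.
#' @param n_grid Number of quantile candidates beyond that.
#' @return List with `best_dice` and `best_threshold`.
#' @export
best_dice <- function(residuals, gt_masks, max_exact = 1e4, n_grid = 1024) {
  if (!is.list(residuals)) residuals <- list(residuals)
  if (!is.list(gt_masks)) gt_masks <- list(gt_masks)
  stopifnot(length(residuals) == length(gt_masks))
  r <- unlist(lapply(residuals, as.vector))
  g <- unlist(lapply(gt_masks, function(m) as.vector(m > 0)))
  stopifnot(length(r) == length(g))
  if (!any(g)) stop("ground truth contains no positive pixels")
  u <- sort(unique(r))
  cand <- if (length(u) <= max_exact) {
    u
  } else {
    sort(unique(stats::quantile(r, probs = seq(0, 1, length.out = n_grid),
                                names = FALSE, type = 1)))
  }
  ## predictions are r > t; sweep thresholds from a sorted pass
  ord <- order(r, decreasing = TRUE)
  rs <- r[ord]
  gs <- g[ord]
  cum_tp <- cumsum(gs)
  P <- sum(g)
  ## number of predictions for threshold t = count of values > t
  n_above <- length(rs) - findInterval(cand, sort(rs))
  ## findInterval over ascending rs gives count of rs <= t
  tp <- ifelse(n_above > 0, cum_tp[pmax(n_above, 1L)] * (n_above > 0), 0)
  dice_vals <- ifelse(n_above + P > 0, 2 * tp / (n_above + P), 1)
  best <- which.max(dice_vals)
  list(best_dice = dice_vals[best], best_threshold = cand[best])
}

#' Area under the precision-recall curve
#'
#' Step-interpolated area over the distinct score thresholds (higher score =
#' predicted positive, as for residual values against anomaly labels).
#'
#' @param scores Numeric vector.
#' @param labels Binary vector (1 = positive).
#' @return Scalar in \[0,1\].
#' @export
auprc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  check_labels(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  cum_tp <- cumsum(y)
  cum_fp <- cumsum(1 - y)
  ## evaluate at the last index of each tie group
  last <- which(!duplicated(s, fromLast = TRUE))
  tp <- cum_tp[last]
  fp <- cum_fp[last]
  P <- sum(y)
  recall <- tp / P
  precision <- tp / (tp + fp)
  dr <- diff(c(0, recall))
  sum(dr * precision)
}

#' Area under the ROC curve
#'
#' Trapezoidal/rank formulation (ties contribute 1/2), so identical scores
#' give 0.5 and the value is invariant under strictly monotone transforms.
#'
#' @inheritParams auprc
#' @return Scalar in \[0,1\].
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  check_labels(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  rk <- rank(scores, ties.method = "average")
  (sum(rk[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' False-positive rate at a fixed true-positive rate
#'
#' Positives are the in-distribution examples (higher score = more normal).
#' With acceptance rule `score >= t`, the threshold is the largest observed
#' score cutoff whose TPR still reaches `tpr_level`; the returned value is
#' the fraction of anomalous examples accepted at that cutoff.
#'
#' @param scores Numeric scores, higher = more in-distribution.
#' @param labels Binary labels, 1 = in-distribution (positive).
#' @param tpr_level Required true-positive rate (e.g. 0.8, 0.95, 0.99).
#' @return Scalar FPR in \[0,1\].
#' @export
fpr_at_tpr <- function(scores, labels, tpr_level = 0.95) {
  stopifnot(length(scores) == length(labels),
            tpr_level > 0, tpr_level <= 1)
  check_labels(labels)
  cand <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  for (t in cand) {
    tpr <- sum(scores >= t & labels == 1) / n_pos
    if (tpr >= tpr_level) {
      return(sum(scores >= t & labels == 0) / n_neg)
    }
  }
  1
}

#' Full evaluation report for pixel-wise segmentation and image-wise scores
#'
#' @param residuals List of residual maps.
#' @param gt_masks List of binary ground-truth masks.
#' @param detection_scores Optional numeric image-wise scores (higher = more
#'   normal) for AUROC/FPR metrics.
#' @param detection_labels Optional binary labels (1 = in-distribution).
#' @return A one-row tibble of class `lh_eval`: `best_dice`,
#'   `best_threshold`, `auprc`, and when detection inputs are given `auroc`,
#'   `fpr80`, `fpr95`, `fpr99`.
#' @export
eval_report <- function(residuals, gt_masks, detection_scores = NULL,
                        detection_labels = NULL) {
  bd <- best_dice(residuals, gt_masks)
  r <- unlist(lapply(residuals, as.vector))
  g <- unlist(lapply(gt_masks, function(m) as.integer(m > 0)))
  out <- tibble::tibble(best_dice = bd$best_dice,
                        best_threshold = bd$best_threshold,
                        auprc = auprc(r, g))
  if (!is.null(detection_scores)) {
    stopifnot(!is.null(detection_labels))
    ## detection AUROC convention: anomalous = detection positive, so score
    ## ordering is flipped (lower logp = more anomalous)
    out$auroc <- auroc(-detection_scores, 1 - detection_labels)
    out$fpr80 <- fpr_at_tpr(detection_scores, detection_labels, 0.80)
    out$fpr95 <- fpr_at_tpr(detection_scores, detection_labels, 0.95)
    out$fpr99 <- fpr_at_tpr(detection_scores, detection_labels, 0.99)
  }
  class(out) <- c("lh_eval", class(out))
  out
}
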