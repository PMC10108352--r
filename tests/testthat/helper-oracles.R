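## Brute-force oracles used to pin the metric implementations.

oracle_best_dice <- function(r, g) {
  best <- c(dice = -1, thr = NA)
  for (t in sort(unique(as.vector(r)))) {
    d <- dice(r > t, g)
    if (d > best["dice"]) best <- c(dice = d, thr = t)
  }
  best
}

oracle_auprc <- function(scores, labels) {
  ts <- sort(unique(scores), decreasing = TRUE)
  prec <- rec <- numeric(0)
  for (t in ts) {
    sel <- scores >= t
    prec <- c(prec, sum(labels[sel]) / sum(sel))
    rec <- c(rec, sum(labels[sel]) / sum(labels))
  }
  sum(diff(c(0, rec)) * prec)
}

oracle_fpr_at_tpr <- function(scores, labels, level) {
  for (t in sort(unique(scores), decreasing = TRUE)) {
    tpr <- mean(scores[labels == 1] >= t)
    if (tpr >= level) return(mean(scores[labels == 0] >= t))
  }
  1
}

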