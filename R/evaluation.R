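# Imbalance-aware evaluation: ROC/AUROC, PR/AUPRC, 50 bp re-windowing for
# cross-method comparison, and fixed-cutoff confusion-matrix metrics.

.check_binary_labels <- function(labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(-1L, 1L))) stop("labels must be -1 or +1")
  labels
}

#' ROC curve and AUROC
#'
#' The area is computed by the rank (Mann-Whitney) formulation with ties
#' counted 1/2 — the probability that a randomly chosen positive outscores
#' a randomly chosen negative — and equals trapezoidal integration of the
#' curve over unique thresholds.
#'
#' @param scores Numeric scores (higher = more NMI-like).
#' @param labels Labels in {-1, +1}; both classes must be present.
#' @return A `curve_result`: list with `kind`, `points` (data.frame of
#'   fpr/tpr, starting at (0,0)), `area`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.2, 0.1), c(1, -1, -1))$area # 1
roc_auc <- function(scores, labels) {
  labels <- .check_binary_labels(labels)
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == -1L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes required for a ROC curve")
  r <- rank(scores, ties.method = "average")
  area <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # curve points at unique thresholds, descending
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  last <- cumsum(rle(s)$lengths) # last index of each tie group
  tp <- cumsum(y == 1L)[last]
  fp <- cumsum(y == -1L)[last]
  points <- data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  structure(list(kind = "ROC", points = points, area = area,
                 n_pos = n_pos, n_neg = n_neg),
            class = "curve_result")
}

#' Precision-recall curve and AUPRC
#'
#' Precision and recall are evaluated at every unique score threshold
#' (descending); the area is the step-wise sum
#' `sum_i (R_i - R_{i-1}) * P_i` with no linear interpolation between
#' points (interpolated PR area is a known-biased estimator). For a random
#' ranker the expected area approaches the positive-class prevalence —
#' the quantity that makes AUPRC the imbalance-sensitive companion to
#' AUROC.
#'
#' @param scores Numeric scores.
#' @param labels Labels in {-1, +1}; at least one positive required.
#' @return A `curve_result` with `points` (recall/precision) and `area`.
#' @export
pr_auc <- function(scores, labels) {
  labels <- .check_binary_labels(labels)
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == -1L)
  if (n_pos == 0L) stop("at least one positive label required for a PR curve")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(y == 1L)[last]
  n_pred <- last
  precision <- tp / n_pred
  recall <- tp / n_pos
  area <- sum(diff(c(0, recall)) * precision)
  structure(list(kind = "PR",
                 points = data.frame(recall = recall, precision = precision),
                 area = area, n_pos = n_pos, n_neg = n_neg),
            class = "curve_result")
}

#' Print a curve_result
#' @param x A `curve_result`.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @exportS3Method base::print
print.curve_result <- function(x, ...) {
  cat(x$kind, "curve: area =", format(x$area, digits = 4),
      sprintf("(%d positives, %d negatives, %d points)\n",
              x$n_pos, x$n_neg, nrow(x$points)))
  invisible(x)
}

#' Write curve points as a tab-separated table
#'
#' @param curve A `curve_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  utils::write.table(curve$points, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Explode scored windows into fixed-width evaluation windows
#'
#' Cross-method comparison happens on short (default 50 bp) windows so
#' that methods emitting short intervals are not penalized. Each parent
#' window yields `width / eval_width` children, every child inheriting the
#' parent's score; child truth labels are re-derived from NMI coverage at
#' the >= `min_frac` rule on the child interval.
#'
#' @param windows Scored window data.frame (columns chrom/start/end and
#'   `score`, or supply `score`).
#' @param nmis Regions data.frame of true NMIs.
#' @param eval_width Child width; must divide the parent width (default 50).
#' @param min_frac Coverage fraction for a positive child label (default 0.5).
#' @param score Optional score vector overriding `windows$score`.
#' @return data.frame of children with chrom/start/end/score/label/parent.
#' @export
explode_to_eval_windows <- function(windows, nmis, eval_width = 50,
                                    min_frac = 0.5, score = NULL) {
  score <- score %||% windows$score
  if (is.null(score)) stop("windows must carry a score")
  stopifnot(length(score) == nrow(windows))
  width <- unique(windows$end - windows$start)
  if (length(width) != 1L) stop("windows must share one width")
  if (width %% eval_width != 0) {
    stop("eval_width must divide the window width")
  }
  m <- width %/% eval_width
  n <- nrow(windows)
  idx <- rep(seq_len(n), each = m)
  off <- rep.int(eval_width * (seq_len(m) - 1), n)
  children <- data.frame(chrom = windows$chrom[idx],
                         start = windows$start[idx] + off,
                         stringsAsFactors = FALSE)
  children$end <- children$start + eval_width
  children$score <- score[idx]
  children$parent <- idx
  label_windows(children, nmis, min_frac)
}

#' Binary scores for interval-only predictions
#'
#' Methods that emit a fixed set of intervals rather than scores (the
#' island callers) are mapped onto evaluation windows with the same
#' coverage rule used for truth labels: a window scores 1 iff >=
#' `min_frac` of its length is covered by a predicted interval, else 0.
#' This yields the single ROC/PR point such methods admit.
#'
#' @param predicted Regions data.frame of predicted islands.
#' @param windows Evaluation window data.frame.
#' @param min_frac Coverage fraction (default 0.5).
#' @return Numeric 0/1 vector parallel to the windows.
#' @export
intervals_to_window_scores <- function(predicted, windows, min_frac = 0.5) {
  if (nrow(windows) == 0L) return(numeric(0))
  if (is.null(predicted) || nrow(predicted) == 0L) {
    return(rep(0, nrow(windows)))
  }
  ov <- region_overlap_length(windows, predicted[, c("chrom", "start", "end")])
  as.numeric(ov / (windows$end - windows$start) >= min_frac)
}

#' Confusion-matrix metrics at a fixed score cutoff
#'
#' Predict positive iff `score >= cutoff` (so the conventional SVM cutoff
#' 0 is the sign rule). Precision is reported as `NA` when no window is
#' predicted positive.
#'
#' @param scores Numeric scores.
#' @param labels Labels in {-1, +1}; both classes required.
#' @param cutoff Score cutoff.
#' @return List with `cutoff`, `TPR`, `FPR`, `precision`.
#' @export
metrics_at_cutoff <- function(scores, labels, cutoff) {
  labels <- .check_binary_labels(labels)
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == -1L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes required")
  pred <- scores >= cutoff
  tp <- sum(pred & labels == 1L)
  fp <- sum(pred & labels == -1L)
  list(cutoff = cutoff,
       TPR = tp / n_pos,
       FPR = fp / n_neg,
       precision = if (tp + fp == 0L) NA_real_ else tp / (tp + fp))
}
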