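# Quantitative evaluation: MSE/PSNR for filter quality, pixel-level
# confusion counts, ROC curves, precision, and IoU against ground truth.

#' MSE and PSNR between two images
#'
#' `MSE = mean((f - g)^2)`, `PSNR = 20 * log10(255 / sqrt(MSE))` dB.
#' Identical images give `mse = 0` and `psnr = Inf`.
#'
#' @param original,filtered numeric matrices of the same size.
#' @return `list(mse, psnr)`.
#' @export
mse_psnr <- function(original, filtered) {
  a <- .as_gray(original, "original"); b <- .as_gray(filtered, "filtered")
  .check_same_shape(a, b, "images")
  mse <- mean((a - b)^2)
  psnr <- if (mse == 0) Inf else 20 * log10(255 / sqrt(mse))
  list(mse = mse, psnr = psnr)
}

#' Pixel-level confusion counts
#'
#' @param pred,truth logical (or 0/1) matrices of the same size; `TRUE` =
#'   foreground.
#' @return object of class `confusion_counts`: `list(tp, fp, tn, fn)`,
#'   summing to the pixel count.
#' @export
confusion_counts <- function(pred, truth) {
  p <- .as_mask(pred, "pred"); t <- .as_mask(truth, "truth")
  .check_same_shape(p, t, "masks")
  structure(list(tp = sum(p & t), fp = sum(p & !t),
                 tn = sum(!p & !t), fn = sum(!p & t)),
            class = "confusion_counts")
}

#' Precision of a detection
#'
#' `TP / (TP + FP)`. With no positive predictions at all the value is
#' defined as 1 (with a warning): nothing was falsely marked.
#'
#' @param counts a [confusion_counts()] object.
#' @return number in `[0, 1]`.
#' @export
precision_score <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$tp + counts$fp == 0) {
    warning("no positive predictions; precision defined as 1")
    return(1)
  }
  counts$tp / (counts$tp + counts$fp)
}

#' ROC curve of a score map against a truth mask
#'
#' For each threshold `t` the prediction is `score > t`;
#' `TPR = TP/(TP+FN)`, `FPR = FP/(FP+TN)`. The endpoints `(0,0)`
#' (threshold `+Inf`) and `(1,1)` (`-Inf`) are always included, and the
#' points are monotone non-decreasing in both coordinates as the threshold
#' decreases.
#'
#' @param score numeric matrix (higher = more foreground-like).
#' @param truth logical matrix.
#' @param thresholds optional increasing threshold vector; by default 99
#'   interior quantiles of `score`.
#' @return `data.frame(threshold, fpr, tpr)` ordered by decreasing
#'   threshold. If the truth is all-foreground or all-background the
#'   undefined rate is reported as `NaN` with a warning.
#' @export
roc_curve <- function(score, truth, thresholds = NULL) {
  s <- .as_gray(score, "score"); t <- .as_mask(truth, "truth")
  .check_same_shape(s, t, "score and truth")
  npos <- sum(t); nneg <- sum(!t)
  if (npos == 0 || nneg == 0)
    warning("degenerate truth mask (all one class); rates contain NaN")
  if (is.null(thresholds))
    thresholds <- unique(stats::quantile(s, probs = seq(0.01, 0.99, by = 0.01),
                                         names = FALSE))
  if (is.unsorted(thresholds)) stop("'thresholds' must be sorted increasing")
  th <- c(Inf, rev(thresholds), -Inf)
  tpr <- fpr <- numeric(length(th))
  for (i in seq_along(th)) {
    p <- s > th[i]
    tpr[i] <- sum(p & t) / npos
    fpr[i] <- sum(p & !t) / nneg
  }
  data.frame(threshold = th, fpr = fpr, tpr = tpr)
}

#' Intersection-over-union of two masks
#'
#' `|A & B| / |A | B|`; both masks empty gives 1 (perfect agreement on
#' "nothing there").
#'
#' @param pred,truth logical matrices.
#' @return number in `[0, 1]`.
#' @export
mask_iou <- function(pred, truth) {
  p <- .as_mask(pred, "pred"); t <- .as_mask(truth, "truth")
  .check_same_shape(p, t, "masks")
  u <- sum(p | t)
  if (u == 0) return(1)
  sum(p & t) / u
}

#' Does one ROC curve dominate another?
#'
#' Compares TPR of `roc_a` and `roc_b` at a common FPR grid (step-function
#' interpolation: the best TPR attained at or below each FPR).
#'
#' @param roc_a,roc_b data frames from [roc_curve()].
#' @param grid FPR evaluation points (default 0.02..0.98 by 0.02).
#' @return fraction of grid points where `roc_a`'s TPR >= `roc_b`'s.
#' @export
roc_dominance <- function(roc_a, roc_b, grid = seq(0.02, 0.98, by = 0.02)) {
  tpr_at <- function(roc, f) {
    o <- order(roc$fpr, roc$tpr)
    vapply(f, function(x) {
      i <- which(roc$fpr[o] <= x)
      if (!length(i)) 0 else max(roc$tpr[o][i])
    }, numeric(1))
  }
  mean(tpr_at(roc_a, grid) >= tpr_at(roc_b, grid))
}
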