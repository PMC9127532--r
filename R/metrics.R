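#' Pixelwise confusion counts
#'
#' Counts true/false positives/negatives of a predicted binary mask against a
#' reference mask. The four counts always sum to the pixel count.
#'
#' @param pred,truth logical matrices of equal dimensions.
#' @return A list of class `"confusion_counts"` with fields `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
confusion <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("`pred` and `truth` must have identical dimensions", call. = FALSE)
  structure(list(
    tp = sum(pred & truth),
    fp = sum(pred & !truth),
    fn = sum(!pred & truth),
    tn = sum(!pred & !truth)
  ), class = "confusion_counts")
}

#' Precision, recall and F-measure
#'
#' `P = tp / (tp + fp)`, `R = tp / (tp + fn)`, and the F-measure is the
#' standard F1 harmonic mean `F = 2PR / (P + R)` (with `F = 0` when
#' `P = R = 0`). Undefined denominators yield `NaN` with a warning rather
#' than a silent 0.
#'
#' @param c a [confusion()] result.
#' @return A list with `precision`, `recall`, `f`.
#' @export
precision_recall_f <- function(c) {
  p <- if (c$tp + c$fp > 0) c$tp / (c$tp + c$fp) else {
    warning("precision undefined: no predicted positives", call. = FALSE)
    NaN
  }
  r <- if (c$tp + c$fn > 0) c$tp / (c$tp + c$fn) else {
    warning("recall undefined: no reference positives", call. = FALSE)
    NaN
  }
  f <- if (is.nan(p) || is.nan(r)) NaN
       else if (p + r == 0) 0
       else 2 * p * r / (p + r)
  list(precision = p, recall = r, f = f)
}

#' F-measure of a predicted mask
#'
#' Convenience wrapper: `f_measure(pred, truth)` is
#' `precision_recall_f(confusion(pred, truth))$f`.
#'
#' @inheritParams confusion
#' @return The F1 value.
#' @export
f_measure <- function(pred, truth) {
  precision_recall_f(confusion(pred, truth))$f
}

#' Boundary pixels of a mask
#'
#' Mask pixels with at least one 4-neighbor outside the mask (pixels on the
#' image border count as boundary).
#'
#' @param mask a logical matrix.
#' @return A two-column matrix of 0-based `(row, col)` boundary coordinates.
#' @export
boundary_pixels <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  inner <- pad[1:h, 2:(w + 1L)] & pad[3:(h + 2L), 2:(w + 1L)] &
           pad[2:(h + 1L), 1:w] & pad[2:(h + 1L), 3:(w + 2L)]
  idx <- which(mask & !inner, arr.ind = TRUE)
  cbind(row = idx[, 1] - 1L, col = idx[, 2] - 1L)
}

directed_hausdorff <- function(a, b) {
  # max over a of the distance to the nearest b, chunked to bound memory
  worst <- 0
  n <- nrow(a)
  for (start in seq(1L, n, by = 256L)) {
    rows <- start:min(start + 255L, n)
    d2 <- outer(a[rows, 1], b[, 1], "-")^2 + outer(a[rows, 2], b[, 2], "-")^2
    worst <- max(worst, sqrt(max(apply(d2, 1L, min))))
  }
  worst
}

#' Hausdorff distance between two masks
#'
#' The symmetric Hausdorff distance between the boundary pixel sets of the
#' two masks under the Euclidean metric: the maximum of the two directed
#' nearest-boundary distances. Smaller values mean better edge agreement.
#'
#' @param pred,truth non-empty logical matrices of equal dimensions.
#' @return Distance in pixels.
#' @export
hausdorff <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("`pred` and `truth` must have identical dimensions", call. = FALSE)
  if (!any(pred) || !any(truth))
    stop("hausdorff distance requires non-empty masks", call. = FALSE)
  a <- boundary_pixels(pred); b <- boundary_pixels(truth)
  max(directed_hausdorff(a, b), directed_hausdorff(b, a))
}

#' ROC curve and AUC over a threshold-indexed prediction family
#'
#' Evaluates a prediction family (typically segmentation re-run with the
#' gray-similarity threshold `th_f` set to each grid value) against a
#' reference mask, producing one (false-positive rate, true-positive rate)
#' point per threshold. The curve is augmented with the anchors (0, 0) and
#' (1, 1), sorted by FPR, and integrated by the trapezoidal rule.
#'
#' @param score_fn a function taking a threshold and returning a logical
#'   prediction mask.
#' @param truth logical reference mask containing both classes.
#' @param grid numeric vector of at least two thresholds.
#' @return A list with `points` (data frame `threshold`, `fpr`, `tpr`,
#'   anchors carrying `NA` thresholds) and `auc`.
#' @export
roc_auc <- function(score_fn, truth, grid) {
  if (length(grid) < 2L) stop("`grid` must contain at least 2 thresholds", call. = FALSE)
  if (!any(truth) || all(truth))
    stop("degenerate truth mask: both classes required", call. = FALSE)
  pts <- lapply(grid, function(th) {
    cc <- confusion(score_fn(th), truth)
    c(fpr = cc$fp / (cc$fp + cc$tn), tpr = cc$tp / (cc$tp + cc$fn))
  })
  pts <- do.call(rbind, pts)
  df <- data.frame(threshold = as.numeric(grid), fpr = pts[, "fpr"], tpr = pts[, "tpr"])
  df <- rbind(data.frame(threshold = NA_real_, fpr = 0, tpr = 0),
              df,
              data.frame(threshold = NA_real_, fpr = 1, tpr = 1))
  df <- df[order(df$fpr, df$tpr), ]
  rownames(df) <- NULL
  auc <- sum(diff(df$fpr) * (utils::head(df$tpr, -1) + utils::tail(df$tpr, -1)) / 2)
  list(points = df, auc = auc)
}
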