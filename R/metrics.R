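# Segmentation evaluation metrics: confusion counts, overlap metrics
# (IoU / Jaccard, Dice), confusion-derived rates (accuracy, sensitivity,
# specificity, precision, F-measure, MCC) and the 95th-percentile symmetric
# Hausdorff distance between mask boundaries.
#
# Conventions (rarely stated explicitly in the segmentation literature):
#  - a boundary pixel is a foreground pixel with at least one background
#    4-neighbor (image border counts as background);
#  - the 95th percentile is the linear-interpolation percentile of the
#    sorted directed distances;
#  - when both masks are empty, overlap metrics are 1 (vacuous agreement)
#    and HD95 is undefined.

#' Confusion counts between two binary masks
#'
#' @param pred,truth Binary 0/1 matrices of identical shape.
#' @return List with integer fields `TP`, `FP`, `TN`, `FN` summing to the
#'   pixel count.
#' @export
confusion <- function(pred, truth) {
  stopifnot_same_dim(pred, truth, "pred and truth")
  assert_binary_mask(pred, "pred"); assert_binary_mask(truth, "truth")
  p <- as.vector(pred) == 1; t <- as.vector(truth) == 1
  list(TP = sum(p & t), FP = sum(p & !t), TN = sum(!p & !t), FN = sum(!p & t))
}

#' Intersection over union (Jaccard index)
#'
#' `|A intersect B| / |A union B|`; defined as 1 when both masks are empty.
#'
#' @param A,B Binary 0/1 matrices of identical shape.
#' @export
iou <- function(A, B) {
  stopifnot_same_dim(A, B, "masks")
  a <- as.vector(A) == 1; b <- as.vector(B) == 1
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Dice similarity coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)`; satisfies the algebraic identity
#' `dice = 2 * iou / (1 + iou)`. Defined as 1 when both masks are empty.
#'
#' @inheritParams iou
#' @export
dice <- function(A, B) {
  stopifnot_same_dim(A, B, "masks")
  a <- as.vector(A) == 1; b <- as.vector(B) == 1
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}

# Foreground pixels with at least one background 4-neighbor (the image
# border counts as background). Returns an n x 2 matrix of (row, col).
boundary_pixels <- function(mask) {
  m <- mask == 1
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  up <- pad[1:nr, 2:(nc + 1)]
  down <- pad[3:(nr + 2), 2:(nc + 1)]
  left <- pad[2:(nr + 1), 1:nc]
  right <- pad[2:(nr + 1), 3:(nc + 2)]
  b <- core & !(up & down & left & right)
  which(b, arr.ind = TRUE)
}

# Linear-interpolation percentile of a sorted sample (same rule as R's
# default type-7 quantile), written out explicitly.
percentile_linear <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  if (n == 1) return(x)
  h <- (n - 1) * p
  lo <- floor(h)
  x[lo + 1] + (h - lo) * (x[min(lo + 2, n)] - x[lo + 1])
}

# Directed 95th-percentile distance from boundary point set a to set b
# (n x 2 coordinate matrices, pixel units).
directed_h95 <- function(a, b, p = 0.95) {
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  dmin <- sqrt(apply(d2, 1, min))
  percentile_linear(dmin, p)
}

#' 95th-percentile Hausdorff distance between mask boundaries
#'
#' Extracts the boundary pixels of each mask, computes the directed 95th
#' percentile of nearest-boundary distances in both directions, and returns
#' the larger of the two, scaled to millimetres by the pixel spacing.
#'
#' @inheritParams iou
#' @param spacing Pixel spacing in mm/px.
#' @return HD95 in mm.
#' @export
hd95 <- function(A, B, spacing = 1) {
  stopifnot_same_dim(A, B, "masks")
  ba <- boundary_pixels(A); bb <- boundary_pixels(B)
  if (nrow(ba) == 0 || nrow(bb) == 0)
    stop("HD95 is undefined for an empty mask", call. = FALSE)
  spacing * max(directed_h95(ba, bb), directed_h95(bb, ba))
}

#' Full segmentation metrics report
#'
#' Computes the complete per-slice metric panel: accuracy, sensitivity,
#' specificity, precision, F-measure, MCC, Dice, IoU and HD95 (mm). Rates
#' with a zero denominator are reported as `NaN` with a warning rather than
#' silently coerced to 0. Note that for binary masks the F-measure equals
#' the Dice coefficient.
#'
#' @param pred,truth Binary 0/1 matrices of identical shape.
#' @param spacing Pixel spacing in mm/px (for HD95).
#' @return A one-row data.frame of class `metrics_report`.
#' @export
seg_report <- function(pred, truth, spacing = 1) {
  cc <- confusion(pred, truth)
  N <- cc$TP + cc$FP + cc$TN + cc$FN
  rate <- function(num, den, name) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator); reported as NaN", name),
              call. = FALSE)
      return(NaN)
    }
    num / den
  }
  sens <- rate(cc$TP, cc$TP + cc$FN, "sensitivity")
  spec <- rate(cc$TN, cc$TN + cc$FP, "specificity")
  prec <- rate(cc$TP, cc$TP + cc$FP, "precision")
  f <- if (is.nan(prec) || is.nan(sens) || prec + sens == 0) {
    warning("F-measure undefined; reported as NaN", call. = FALSE); NaN
  } else 2 * prec * sens / (prec + sens)
  mcc_den <- sqrt(prod(c(cc$TP + cc$FP, cc$TP + cc$FN,
                         cc$TN + cc$FP, cc$TN + cc$FN)))
  mcc <- if (mcc_den == 0) {
    warning("MCC undefined (zero denominator); reported as NaN", call. = FALSE)
    NaN
  } else (cc$TP * cc$TN - cc$FP * cc$FN) / mcc_den
  h <- if (sum(pred == 1) > 0 && sum(truth == 1) > 0)
    hd95(pred, truth, spacing) else NA_real_
  out <- data.frame(accuracy = (cc$TP + cc$TN) / N,
                    sensitivity = sens, specificity = spec,
                    precision = prec, f_measure = f, mcc = mcc,
                    dsc = dice(pred, truth), iou = iou(pred, truth),
                    hd95_mm = h)
  class(out) <- c("metrics_report", class(out))
  out
}

#' Evaluate a set of predicted masks against ground truth
#'
#' Per-slice [seg_report()] rows plus an aggregate summary (mean, sd,
#' median, 5th/95th percentiles per metric).
#'
#' @param preds,truths Lists of binary masks of equal length.
#' @param spacing Pixel spacing in mm/px.
#' @return List with `per_slice` (data.frame) and `summary` (data.frame).
#' @export
evaluate_masks <- function(preds, truths, spacing = 1) {
  stopifnot(length(preds) == length(truths))
  rows <- lapply(seq_along(preds), function(i) {
    r <- seg_report(preds[[i]], truths[[i]], spacing)
    cbind(slice = i, r)
  })
  per <- do.call(rbind, rows)
  metrics <- setdiff(names(per), "slice")
  summ <- do.call(rbind, lapply(metrics, function(mn) {
    v <- per[[mn]]
    v <- v[is.finite(v)]
    data.frame(metric = mn, mean = mean(v), sd = stats::sd(v),
               median = stats::median(v),
               p05 = as.numeric(quantile(v, 0.05)),
               p95 = as.numeric(quantile(v, 0.95)))
  }))
  list(per_slice = per, summary = summ)
}
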