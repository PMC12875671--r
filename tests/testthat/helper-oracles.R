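# Independent oracles: naive per-pixel loops, exhaustive enumerations and
# textbook recursions, kept deliberately separate from the implementation
# paths they check.

bce_loop_oracle <- function(S, Y, eps = 1e-7) {
  total <- 0
  for (i in seq_along(S)) {
    s <- min(max(S[i], eps), 1 - eps)
    total <- total - (Y[i] * log(s) + (1 - Y[i]) * log(1 - s))
  }
  total / length(S)
}

focal_loop_oracle <- function(S, Y, alpha, gamma, eps = 1e-7) {
  total <- 0
  for (i in seq_along(S)) {
    s <- min(max(S[i], eps), 1 - eps)
    pt <- if (Y[i] == 1) s else 1 - s
    total <- total - alpha * (1 - pt)^gamma * log(pt)
  }
  total / length(S)
}

dice_loss_oracle <- function(S, Y, smooth = 1) {
  inter <- 0; ssum <- 0; ysum <- 0
  for (i in seq_along(S)) {
    inter <- inter + S[i] * Y[i]
    ssum <- ssum + S[i]
    ysum <- ysum + Y[i]
  }
  1 - (2 * inter + smooth) / (ssum + ysum + smooth)
}

diversity_loop_oracle <- function(params) {
  total <- 0
  m <- length(params)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (j <= i) next
    d <- 0
    for (k in seq_along(params[[i]]))
      d <- d + (params[[i]][k] - params[[j]][k])^2
    total <- total + d
  }
  total
}

confusion_loop_oracle <- function(pred, truth) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1L
    else if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1L
    else if (pred[i] == 0 && truth[i] == 0) tn <- tn + 1L
    else fn <- fn + 1L
  }
  list(TP = tp, FP = fp, TN = tn, FN = fn)
}

set_count_iou_oracle <- function(A, B) {
  a <- which(A == 1); b <- which(B == 1)
  if (length(union(a, b)) == 0) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

set_count_dice_oracle <- function(A, B) {
  a <- which(A == 1); b <- which(B == 1)
  if (length(a) + length(b) == 0) return(1)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

# 4-neighbor boundary (border counts as background), as explicit loops.
boundary_loop_oracle <- function(mask) {
  out <- NULL
  nr <- nrow(mask); nc <- ncol(mask)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (mask[i, j] != 1) next
    nb <- c(if (i > 1) mask[i - 1, j] else 0,
            if (i < nr) mask[i + 1, j] else 0,
            if (j > 1) mask[i, j - 1] else 0,
            if (j < nc) mask[i, j + 1] else 0)
    if (any(nb == 0)) out <- rbind(out, c(i, j))
  }
  out
}

# Linear-interpolation percentile of sorted values, written out explicitly.
percentile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  if (n == 1) return(x)
  h <- (n - 1) * p
  lo <- floor(h)
  hi <- min(lo + 1, n - 1)
  x[lo + 1] * (1 - (h - lo)) + x[hi + 1] * (h - lo)
}

hd95_bruteforce_oracle <- function(A, B, spacing = 1) {
  ba <- boundary_loop_oracle(A)
  bb <- boundary_loop_oracle(B)
  dmin_ab <- apply(ba, 1, function(p)
    min(sqrt((bb[, 1] - p[1])^2 + (bb[, 2] - p[2])^2)))
  dmin_ba <- apply(bb, 1, function(p)
    min(sqrt((ba[, 1] - p[1])^2 + (ba[, 2] - p[2])^2)))
  spacing * max(percentile_oracle(dmin_ab, 0.95),
                percentile_oracle(dmin_ba, 0.95))
}

# Cox-de Boor recursion for the B-spline basis N_{i,k}(u) on a knot vector.
deboor_basis <- function(i, k, u, knots) {
  if (k == 0)
    return(as.numeric(u >= knots[i + 1] & u < knots[i + 2]))
  a <- 0; b <- 0
  d1 <- knots[i + k + 1] - knots[i + 1]
  if (d1 > 0) a <- (u - knots[i + 1]) / d1 * deboor_basis(i, k - 1, u, knots)
  d2 <- knots[i + k + 2] - knots[i + 2]
  if (d2 > 0) b <- (knots[i + k + 2] - u) / d2 * deboor_basis(i + 1, k - 1, u, knots)
  a + b
}

# Evaluate the uniform periodic B-spline by direct de Boor recursion over
# the wrapped coefficients.
deboor_periodic_eval <- function(coefs, degree, u) {
  n <- nrow(coefs)
  k <- degree
  knots <- seq(-k, n + k) / n
  ext <- rbind(coefs, coefs[seq_len(k), , drop = FALSE])
  out <- matrix(0, length(u), ncol(coefs))
  for (ui in seq_along(u)) {
    uu <- u[ui] %% 1
    for (i in seq_len(n + k) - 1)
      out[ui, ] <- out[ui, ] + deboor_basis(i, k, uu, knots) * ext[i + 1, ]
  }
  out
}

rmse_loop_oracle <- function(a, b) {
  total <- 0
  for (i in seq_along(a)) total <- total + (a[i] - b[i])^2
  sqrt(total / length(a))
}

# Random binary mask with a few rectangular blobs (always non-empty).
random_mask <- function(nr, nc, n_blobs = 2) {
  m <- matrix(0L, nr, nc)
  for (b in seq_len(n_blobs)) {
    r0 <- sample(nr - 2, 1); c0 <- sample(nc - 2, 1)
    r1 <- min(nr, r0 + sample(1:4, 1)); c1 <- min(nc, c0 + sample(1:4, 1))
    m[r0:r1, c0:c1] <- 1L
  }
  m
}
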