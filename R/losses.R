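# Training objectives: pixel-wise binary cross-entropy, Dice loss, Focal
# loss, their BCE+Dice hybrid, the inter-expert diversity penalty and its
# sampled approximation, and the total objective
# L_total = L_seg - lambda_reg * L_div (minimizing it rewards accurate
# segmentation AND large inter-expert parameter distance).

#' Loss configuration
#'
#' Bundles every tunable of the training objectives. Defaults are the
#' community-standard choices: equal BCE/Dice weighting, Focal loss with
#' `alpha = 0.25`, `gamma = 2`, Dice smoothing 1, and probability clipping
#' at `1e-7` before logs.
#'
#' @param bce_weight,dice_weight Nonnegative weights of the BCE+Dice hybrid.
#' @param focal_alpha,focal_gamma Focal loss parameters (`gamma = 0`,
#'   `alpha = 1` reduces to BCE).
#' @param lambda_reg Weight of the diversity term in the total loss.
#' @param dice_smooth Additive smoothing of the Dice ratio.
#' @param clip_eps Probabilities are clipped to `[clip_eps, 1 - clip_eps]`.
#' @param n_sampled_pairs Pairs drawn by the sampled diversity estimator.
#' @param div_cap Cap on the magnitude of the diversity term inside the
#'   total loss (guards against divergence, since the diversity term is
#'   rewarded rather than penalized).
#' @return A list of class `loss_config`.
#' @export
loss_config <- function(bce_weight = 0.5, dice_weight = 0.5,
                        focal_alpha = 0.25, focal_gamma = 2,
                        lambda_reg = 1e-4, dice_smooth = 1.0,
                        clip_eps = 1e-7, n_sampled_pairs = 1L,
                        div_cap = 1e3) {
  vals <- c(bce_weight, dice_weight, focal_alpha, focal_gamma, lambda_reg,
            dice_smooth, clip_eps)
  if (any(vals < 0)) stop("loss parameters must be nonnegative", call. = FALSE)
  if (clip_eps <= 0 || clip_eps >= 0.5)
    stop("'clip_eps' must lie in (0, 0.5)", call. = FALSE)
  structure(list(bce_weight = bce_weight, dice_weight = dice_weight,
                 focal_alpha = focal_alpha, focal_gamma = focal_gamma,
                 lambda_reg = lambda_reg, dice_smooth = dice_smooth,
                 clip_eps = clip_eps, n_sampled_pairs = as.integer(n_sampled_pairs),
                 div_cap = div_cap),
            class = "loss_config")
}

#' Pixel-wise binary cross-entropy segmentation loss
#'
#' Mean over pixels of `-[Y log S + (1 - Y) log(1 - S)]`, with `S` clipped
#' to `[clip_eps, 1 - clip_eps]` before the logs.
#'
#' @param S Predicted probability map.
#' @param Y Binary ground-truth mask of the same shape.
#' @param clip_eps Clipping bound.
#' @return Nonnegative scalar.
#' @export
seg_loss <- function(S, Y, clip_eps = 1e-7) {
  stopifnot_same_dim(S, Y, "prediction and mask")
  s <- clip01(as.vector(S), clip_eps)
  y <- as.vector(Y)
  -mean(y * log(s) + (1 - y) * log(1 - s))
}

#' Dice loss
#'
#' `1 - (2 * sum(S*Y) + smooth) / (sum(S) + sum(Y) + smooth)`.
#'
#' @inheritParams seg_loss
#' @param smooth Additive smoothing term.
#' @export
dice_loss <- function(S, Y, smooth = 1.0) {
  stopifnot_same_dim(S, Y, "prediction and mask")
  s <- as.vector(S); y <- as.vector(Y)
  1 - (2 * sum(s * y) + smooth) / (sum(s) + sum(y) + smooth)
}

#' Focal loss
#'
#' Mean of `-alpha * (1 - p_t)^gamma * log(p_t)` with `p_t = S` on
#' foreground pixels and `1 - S` on background pixels; concentrates the
#' gradient on hard-to-classify pixels.
#'
#' @inheritParams seg_loss
#' @param alpha Balancing weight.
#' @param gamma Focusing exponent (must be nonnegative).
#' @export
focal_loss <- function(S, Y, alpha = 0.25, gamma = 2, clip_eps = 1e-7) {
  if (gamma < 0) stop("'gamma' must be nonnegative", call. = FALSE)
  stopifnot_same_dim(S, Y, "prediction and mask")
  s <- clip01(as.vector(S), clip_eps)
  y <- as.vector(Y)
  pt <- ifelse(y == 1, s, 1 - s)
  mean(-alpha * (1 - pt)^gamma * log(pt))
}

#' BCE + Dice hybrid loss
#'
#' @inheritParams seg_loss
#' @param cfg A [loss_config()] supplying the weights and smoothing.
#' @export
combined_bce_dice <- function(S, Y, cfg = loss_config()) {
  cfg$bce_weight * seg_loss(S, Y, cfg$clip_eps) +
    cfg$dice_weight * dice_loss(S, Y, cfg$dice_smooth)
}

#' Diversity loss over expert parameter vectors
#'
#' Sum over unordered expert pairs of the squared Euclidean distance
#' between their flattened parameter vectors; zero iff all experts share
#' identical parameters.
#'
#' @param params List of `m >= 2` numeric vectors of equal length.
#' @return Nonnegative scalar.
#' @export
diversity_loss <- function(params) {
  m <- length(params)
  if (m < 2) stop("need at least two parameter vectors", call. = FALSE)
  len <- lengths(params)
  if (length(unique(len)) != 1)
    stop("parameter vectors must have equal length", call. = FALSE)
  total <- 0
  for (i in seq_len(m - 1))
    for (j in (i + 1):m)
      total <- total + sum((params[[i]] - params[[j]])^2)
  total
}

#' Sampled diversity loss
#'
#' Monte-Carlo approximation of the diversity penalty: the mean squared
#' parameter distance over `n_pairs` uniformly sampled distinct expert
#' pairs. Its expectation equals the exhaustive pair mean, so it scales to
#' many experts at constant cost.
#'
#' @inheritParams diversity_loss
#' @param n_pairs Number of pairs to draw.
#' @param seed Integer seed for the pair sampling.
#' @param replace If `TRUE` (default) pairs are drawn with replacement
#'   across draws; if `FALSE`, `n_pairs` must not exceed the `choose(m, 2)`
#'   available unordered pairs.
#' @export
diversity_loss_sampled <- function(params, n_pairs = 1L, seed = 1L,
                                   replace = TRUE) {
  m <- length(params)
  if (m < 2) stop("need at least two parameter vectors", call. = FALSE)
  if (n_pairs < 1) stop("'n_pairs' must be >= 1", call. = FALSE)
  all_pairs <- utils::combn(m, 2)
  if (!replace && n_pairs > ncol(all_pairs))
    stop(sprintf("'n_pairs' (%d) exceeds the %d available pairs under the no-replacement policy",
                 n_pairs, ncol(all_pairs)), call. = FALSE)
  with_seed(seed, {
    ks <- sample.int(ncol(all_pairs), n_pairs, replace = replace)
    d <- vapply(ks, function(k) {
      ij <- all_pairs[, k]
      sum((params[[ij[1]]] - params[[ij[2]]])^2)
    }, numeric(1))
    mean(d)
  })
}

#' Total training objective
#'
#' `total = seg - lambda_reg * div`, with the diversity term capped in
#' magnitude at `div_cap` so the reward cannot diverge.
#'
#' @param seg Segmentation loss value.
#' @param div Diversity loss value.
#' @param lambda_reg Diversity weight.
#' @param div_cap Cap on `div`'s magnitude.
#' @export
total_loss <- function(seg, div, lambda_reg, div_cap = Inf) {
  stopifnot(is.finite(seg), is.finite(div))
  seg - lambda_reg * sign(div) * min(abs(div), div_cap)
}

# ---- gradients used by the trainer (internal) -------------------------------

# d(loss)/d(logit) for a sigmoid output, averaged over pixels, for each
# supported expert loss. S is the sigmoid output, Y the mask.
loss_grad_logits <- function(loss_name, S, Y, cfg) {
  N <- length(S)
  s <- clip01(S, cfg$clip_eps)
  if (loss_name == "bce") return((s - Y) / N)
  if (loss_name == "bce_dice") {
    g_bce <- (s - Y) / N
    num <- 2 * sum(s * Y) + cfg$dice_smooth
    den <- sum(s) + sum(Y) + cfg$dice_smooth
    dDice_dS <- -(2 * Y * den - num) / den^2
    return(cfg$bce_weight * g_bce +
             cfg$dice_weight * dDice_dS * s * (1 - s))
  }
  if (loss_name == "focal") {
    a <- cfg$focal_alpha; g <- cfg$focal_gamma
    pt <- ifelse(Y == 1, s, 1 - s)
    # dl/dpt for l = -a (1-pt)^g log(pt)
    dl_dpt <- -a * (-g * (1 - pt)^(g - 1) * log(pt) + (1 - pt)^g / pt)
    if (g == 0) dl_dpt <- -a / pt
    dpt_dS <- ifelse(Y == 1, 1, -1)
    return(dl_dpt * dpt_dS * s * (1 - s) / N)
  }
  stop(sprintf("unknown loss '%s'", loss_name), call. = FALSE)
}

loss_value <- function(loss_name, S, Y, cfg) {
  switch(loss_name,
         bce = seg_loss(S, Y, cfg$clip_eps),
         bce_dice = combined_bce_dice(S, Y, cfg),
         focal = focal_loss(S, Y, cfg$focal_alpha, cfg$focal_gamma,
                            cfg$clip_eps),
         stop(sprintf("unknown loss '%s'", loss_name), call. = FALSE))
}
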