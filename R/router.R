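# Error-map computation, the error-learner router, the robust weight
# router, weighted prediction fusion, and gradient-based attention maps.
#
# At training time each expert's signed error map is E_i = P_i - Y. Ground
# truth does not exist at inference, so the router is fed expert
# disagreement maps D_i = P_i - mean(P) in place of E_i; the two share the
# same scale and channel layout, and the router can be trained on either
# (disagreement is the default, so the router sees the same input
# distribution at training and inference).

#' Per-expert signed error maps
#'
#' `E_i = P_i - Y` elementwise: +1 marks a confident false positive,
#' -1 a confident false negative, 0 a correct prediction.
#'
#' @param preds List of expert probability maps (equal-shape matrices).
#' @param Y Binary ground-truth mask.
#' @return List of signed error matrices in `[-1, 1]`.
#' @export
compute_error_maps <- function(preds, Y) {
  lapply(preds, function(p) {
    stopifnot_same_dim(p, Y, "prediction and mask")
    p - Y
  })
}

#' Expert disagreement maps (inference-time error surrogate)
#'
#' `D_i = P_i - mean_j(P_j)`: signed deviation of each expert from the
#' ensemble mean. Requires no ground truth.
#'
#' @param preds List of expert probability maps.
#' @return List of signed matrices.
#' @export
disagreement_maps <- function(preds) {
  pbar <- Reduce(`+`, preds) / length(preds)
  lapply(preds, function(p) p - pbar)
}

#' Router configuration
#'
#' The error learner is a small CNN mapping the 4-channel concatenation
#' `[image, E1, E2, E3]` to an 8-channel error-feature stack; the robust
#' weight router maps the 9-channel concatenation `[image, features]` to
#' 3 per-pixel expert logits, normalized by a softmax. Channel widths
#' follow the stated I/O shapes with minimal depths (error learner
#' 4->16->16->8, router 9->16->3).
#'
#' @param feature_channels Error-feature channels (default 8).
#' @param hidden_channels Hidden width of both CNNs.
#' @param n_experts Number of experts (3).
#' @param train_input `"disagreement"` (default) trains the router on the
#'   inference-time disagreement maps; `"error"` trains on the true error
#'   maps (teacher forcing).
#' @param logit_decay L2 penalty on the router's per-pixel logits during
#'   training. Mixture-of-experts gates are prone to collapse onto a
#'   single globally good expert (the softmax saturates and gradients
#'   vanish); a small logit decay keeps the gate soft so per-pixel
#'   specialization can emerge.
#' @param init_seed Seed for weight initialization.
#' @return Object of class `router_config`.
#' @export
router_config <- function(feature_channels = 8L, hidden_channels = 16L,
                          n_experts = 3L,
                          train_input = c("disagreement", "error"),
                          logit_decay = 1e-2, init_seed = 100L) {
  structure(list(feature_channels = as.integer(feature_channels),
                 hidden_channels = as.integer(hidden_channels),
                 n_experts = as.integer(n_experts),
                 train_input = match.arg(train_input),
                 logit_decay = logit_decay,
                 init_seed = as.integer(init_seed)),
            class = "router_config")
}

#' Build the error learner and robust weight router
#'
#' @param cfg A [router_config()].
#' @return Object of class `moe_router` with two named layer stacks.
#' @export
build_router <- function(cfg = router_config()) {
  with_seed(cfg$init_seed, {
    el <- list(el_c1 = new_conv_layer(1L + cfg$n_experts, cfg$hidden_channels),
               el_c2 = new_conv_layer(cfg$hidden_channels, cfg$hidden_channels),
               el_c3 = new_conv_layer(cfg$hidden_channels, cfg$feature_channels))
    wr <- list(wr_c1 = new_conv_layer(1L + cfg$feature_channels,
                                      cfg$hidden_channels),
               wr_c2 = new_conv_layer(cfg$hidden_channels, cfg$n_experts,
                                      act = "linear"))
  })
  structure(list(error_learner = el, weight_router = wr, config = cfg),
            class = "moe_router")
}

stack_channels <- function(image, maps) {
  out <- array(0, c(dim(image)[1], dim(image)[2], 1L + length(maps)))
  out[, , 1] <- image
  for (i in seq_along(maps)) out[, , 1 + i] <- maps[[i]]
  out
}

#' Error-learner forward pass
#'
#' @param router A `moe_router`.
#' @param image Preprocessed input image (matrix).
#' @param errors List of 3 error (or disagreement) maps.
#' @param keep_cache Keep activations for backward.
#' @return `[H, W, feature_channels]` feature array (or a list with cache).
#' @export
error_learner_forward <- function(router, image, errors, keep_cache = FALSE) {
  if (length(errors) != router$config$n_experts)
    stop(sprintf("expected %d error maps, got %d",
                 router$config$n_experts, length(errors)), call. = FALSE)
  x <- stack_channels(image, errors)
  r <- seq_forward(router$error_learner, x, keep_cache)
  if (keep_cache) r else r$out
}

softmax_channels <- function(logits) {
  mx <- apply(logits, c(1, 2), max)
  e <- exp(sweep(logits, c(1, 2), mx))
  sweep(e, c(1, 2), apply(e, c(1, 2), sum), "/")
}

#' Robust weight router forward pass
#'
#' Concatenates the input image with the error features, applies the
#' router CNN and a per-pixel softmax over experts. The result satisfies
#' the simplex constraint at every pixel.
#'
#' @param router A `moe_router`.
#' @param image Input image (matrix).
#' @param feats `[H, W, C]` error features from [error_learner_forward()].
#' @param keep_cache Keep activations for backward.
#' @return `[H, W, 3]` weight array (or list with cache).
#' @export
robust_weight_router <- function(router, image, feats, keep_cache = FALSE) {
  x <- stack_channels(image, lapply(seq_len(dim(feats)[3]),
                                    function(c) feats[, , c]))
  r <- seq_forward(router$weight_router, x, keep_cache)
  if (any(!is.finite(r$out)))
    stop("non-finite router activations", call. = FALSE)
  w <- softmax_channels(r$out)
  if (keep_cache) list(weights = w, logits = r$out, caches = r$caches,
                       x = x) else w
}

#' Fuse expert predictions with per-pixel weights
#'
#' `P_final(x, y) = sum_i w_i(x, y) P_i(x, y)`: an exact per-pixel convex
#' combination, so the fused value is bounded by the expert minimum and
#' maximum everywhere.
#'
#' @param preds List of expert probability maps.
#' @param weights `[H, W, n_experts]` weight array (per-pixel simplex).
#' @param tol Tolerance on the simplex constraint.
#' @return Fused probability matrix.
#' @export
fuse_predictions <- function(preds, weights, tol = 1e-6) {
  if (dim(weights)[3] != length(preds))
    stop("weight channels must match the number of experts", call. = FALSE)
  sums <- apply(weights, c(1, 2), sum)
  if (max(abs(sums - 1)) > tol || min(weights) < -tol)
    stop("weights violate the per-pixel simplex constraint", call. = FALSE)
  out <- matrix(0, nrow(preds[[1]]), ncol(preds[[1]]))
  for (i in seq_along(preds)) out <- out + weights[, , i] * preds[[i]]
  out
}

#' End-to-end mixture-of-experts prediction
#'
#' Runs the three experts, derives disagreement maps, routes, fuses, and
#' returns every explainability artifact: per-expert probability maps,
#' disagreement maps, error features, the per-pixel weight map and the
#' fused probability and mask.
#'
#' @param framework A `moe_framework` (see [train_framework()]).
#' @param image Preprocessed input image.
#' @param truth Optional ground-truth mask; when supplied, true error maps
#'   `E_i = P_i - Y` are also returned.
#' @param threshold Binarization threshold.
#' @return List with `expert_probs`, `disagreement`, `features`, `weights`,
#'   `fused_prob`, `fused_mask`, and optionally `error_maps`.
#' @export
moe_predict <- function(framework, image, truth = NULL, threshold = 0.5) {
  preds <- lapply(framework$experts, unet_forward, image = image)
  dmaps <- disagreement_maps(preds)
  feats <- error_learner_forward(framework$router, image, dmaps)
  w <- robust_weight_router(framework$router, image, feats)
  fused <- fuse_predictions(preds, w)
  mask <- (fused >= threshold) * 1L
  storage.mode(mask) <- "integer"
  out <- list(expert_probs = preds, disagreement = dmaps, features = feats,
              weights = w, fused_prob = fused, fused_mask = mask)
  if (!is.null(truth)) out$error_maps <- compute_error_maps(preds, truth)
  out
}

#' Gradient-based attention map
#'
#' `A(x) = Z * (dZ/dX) / ||dZ/dX||_1`, where `Z` is a scalar head on the
#' network output (by default the spatial mean of the fused foreground
#' probability) and the gradient is taken w.r.t. the input image by
#' backpropagation through the experts and both routers. If the gradient
#' vanishes identically the map is defined as all zeros and a warning is
#' raised.
#'
#' @param framework A `moe_framework`.
#' @param image Preprocessed input image.
#' @return List with `attention` (matrix), `Z` (scalar head value) and
#'   `grad` (raw input gradient).
#' @export
attention_map <- function(framework, image) {
  fw <- moe_forward_full(framework, image, keep_cache = TRUE)
  H <- nrow(image); W <- ncol(image)
  Z <- mean(fw$fused)
  dfused <- matrix(1 / (H * W), H, W)
  gx <- moe_backward_input(framework, fw, dfused)
  l1 <- sum(abs(gx))
  if (l1 == 0) {
    warning("zero input gradient; attention map defined as all zeros",
            call. = FALSE)
    return(list(attention = gx, Z = Z, grad = gx))
  }
  list(attention = Z * gx / l1, Z = Z, grad = gx)
}

# Full forward pass with caches for input-gradient backprop.
moe_forward_full <- function(framework, image, keep_cache = FALSE) {
  ef <- lapply(framework$experts, unet_forward, image = image,
               keep_cache = keep_cache)
  preds <- if (keep_cache) lapply(ef, `[[`, "prob") else ef
  dmaps <- disagreement_maps(preds)
  elr <- error_learner_forward(framework$router, image, dmaps,
                               keep_cache = keep_cache)
  feats <- if (keep_cache) elr$out else elr
  wr <- robust_weight_router(framework$router, image, feats,
                             keep_cache = keep_cache)
  w <- if (keep_cache) wr$weights else wr
  fused <- fuse_predictions(preds, w)
  list(expert_fw = ef, preds = preds, dmaps = dmaps, el = elr, feats = feats,
       wr = wr, weights = w, fused = fused)
}

# Gradient of a scalar loss w.r.t. the input image given d(loss)/d(fused).
# Backpropagates through fusion -> (weights path: softmax, router CNNs,
# disagreement maps) and (prediction path: experts), accumulating every
# route into the input.
moe_backward_input <- function(framework, fw, dfused) {
  m <- length(framework$experts)
  H <- nrow(dfused); W <- ncol(dfused)
  # fusion: dL/dw_i = dfused * P_i ; dL/dP_i (direct) = dfused * w_i
  dw <- array(0, c(H, W, m))
  dpred_direct <- vector("list", m)
  for (i in seq_len(m)) {
    dw[, , i] <- dfused * fw$preds[[i]]
    dpred_direct[[i]] <- dfused * fw$weights[, , i]
  }
  # softmax backward (per pixel over channels)
  wsum <- array(0, c(H, W))
  for (i in seq_len(m)) wsum <- wsum + fw$weights[, , i] * dw[, , i]
  dlogits <- array(0, c(H, W, m))
  for (i in seq_len(m))
    dlogits[, , i] <- fw$weights[, , i] * (dw[, , i] - wsum)
  # weight-router CNN backward
  wb <- seq_backward(framework$router$weight_router, fw$wr$caches, dlogits)
  dimg <- wb$dx[, , 1]
  dfeats <- wb$dx[, , -1, drop = FALSE]
  # error-learner backward
  eb <- seq_backward(framework$router$error_learner, fw$el$caches, dfeats)
  dimg <- dimg + eb$dx[, , 1]
  ddmaps <- eb$dx[, , -1, drop = FALSE]
  # disagreement maps: D_i = P_i - mean_j P_j
  dsum <- array(0, c(H, W))
  for (i in seq_len(m)) dsum <- dsum + ddmaps[, , i]
  dpred_from_d <- lapply(seq_len(m),
                         function(i) ddmaps[, , i] - dsum / m)
  # experts backward (chain through their final sigmoid)
  for (i in seq_len(m)) {
    dS <- dpred_direct[[i]] + dpred_from_d[[i]]
    S <- fw$preds[[i]]
    dlogit <- dS * S * (1 - S)
    ub <- unet_backward(framework$experts[[i]], fw$expert_fw[[i]]$cache,
                        dlogit)
    dimg <- dimg + ub$dx[, , 1]
  }
  dimg
}
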