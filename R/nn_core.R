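# Minimal CNN engine used by the U-Net experts and the router networks.
#
# Layers are plain lists; tensors are R arrays [H, W, C] handed to the
# compiled kernels (stride-1 same-padding convolution, 2x2 max pooling,
# 2x nearest upsampling) together with explicit backward passes, so both
# parameter gradients and input gradients (needed for the attention maps)
# are available. Optimization uses Adam.

new_conv_layer <- function(in_ch, out_ch, k = 3, act = c("relu", "linear", "sigmoid")) {
  act <- match.arg(act)
  # He-normal initialization, appropriate for ReLU stacks
  sd <- sqrt(2 / (k * k * in_ch))
  W <- matrix(rnorm(out_ch * in_ch * k * k, 0, sd), nrow = out_ch)
  list(W = W, b = numeric(out_ch), k = as.integer(k),
       in_ch = as.integer(in_ch), out_ch = as.integer(out_ch),
       act = act, pad = as.integer((k - 1) / 2))
}

apply_act <- function(z, act) {
  switch(act,
         relu = { z[z < 0] <- 0; z },
         sigmoid = 1 / (1 + exp(-z)),
         linear = z)
}

act_grad_chain <- function(dout, z_pre, out, act) {
  switch(act,
         relu = dout * (z_pre > 0),
         sigmoid = dout * out * (1 - out),
         linear = dout)
}

conv_fw <- function(layer, x) {
  z <- conv2d_fw_cpp(x, layer$W, layer$b, layer$k, layer$k, layer$pad)
  out <- apply_act(z, layer$act)
  list(out = out, x = x, z = z)
}

conv_bw <- function(layer, cache, dout) {
  dz <- act_grad_chain(dout, cache$z, apply_act(cache$z, layer$act), layer$act)
  g <- conv2d_bw_cpp(cache$x, layer$W, dz, layer$k, layer$k, layer$pad)
  list(dx = g$dx, dW = g$dw, db = as.numeric(g$db))
}

# ---- sequential CNN (router networks) ---------------------------------------

# A plain stack of convolution layers. `layers` is a named list of conv
# layers applied in order.
seq_forward <- function(layers, x, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(layers))
  for (i in seq_along(layers)) {
    c_i <- conv_fw(layers[[i]], x)
    x <- c_i$out
    if (keep_cache) caches[[i]] <- c_i
  }
  list(out = x, caches = caches)
}

seq_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  names(grads) <- names(layers)
  for (i in rev(seq_along(layers))) {
    g <- conv_bw(layers[[i]], caches[[i]], dout)
    grads[[i]] <- list(dW = g$dW, db = g$db)
    dout <- g$dx
  }
  list(grads = grads, dx = dout)
}

# ---- parameter plumbing -----------------------------------------------------

# Flatten every trainable parameter of a named layer list into one vector.
flatten_layer_params <- function(layers) {
  unlist(lapply(layers, function(l) c(as.vector(l$W), l$b)), use.names = FALSE)
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(l)
    list(mW = matrix(0, nrow(l$W), ncol(l$W)), vW = matrix(0, nrow(l$W), ncol(l$W)),
         mb = numeric(length(l$b)), vb = numeric(length(l$b))))
}

adam_step <- function(layers, grads, state, t, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (nm in names(layers)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    s <- state[[nm]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    layers[[nm]]$W <- layers[[nm]]$W - lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    layers[[nm]]$b <- layers[[nm]]$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[nm]] <- s
  }
  list(layers = layers, state = state)
}
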