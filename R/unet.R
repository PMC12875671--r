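# U-Net experts.
#
# Encoder stages halve the spatial resolution via convolution + ReLU + max
# pooling; the bottleneck applies convolutions without further
# downsampling; each decoder stage upsamples, concatenates the matching
# encoder feature map through a skip connection, and convolves; a final
# 1x1 convolution with sigmoid yields the per-pixel foreground
# probability. Each stage uses two 3x3 convolutions (the standard U-Net
# block). Three experts differing in loss function, initialization seed
# and data partition form the mixture ensemble.

#' U-Net architecture configuration
#'
#' @param depth Number of encoder stages (>= 2); input sides must be
#'   divisible by `2^depth`.
#' @param base_channels Feature channels of the first stage; doubled at
#'   each deeper stage. Default 16 keeps CPU training tractable.
#' @param input_size Integer (H, W) of the single-channel input.
#' @return Object of class `unet_config`.
#' @export
unet_config <- function(depth = 4, base_channels = 16,
                        input_size = c(256, 256)) {
  depth <- as.integer(depth)
  input_size <- as.integer(input_size)
  if (depth < 2) stop("'depth' must be >= 2", call. = FALSE)
  if (any(input_size %% 2^depth != 0))
    stop(sprintf("input size (%s) must be divisible by 2^depth = %d",
                 paste(input_size, collapse = "x"), 2^depth), call. = FALSE)
  structure(list(depth = depth, base_channels = as.integer(base_channels),
                 input_size = input_size),
            class = "unet_config")
}

#' Expert configuration
#'
#' One specialized expert is a U-Net plus a training recipe: its loss
#' (`bce_dice` for experts 1 and 3, `focal` for expert 2), its
#' initialization seed and its data-partition seed. Expert 3 shares the
#' loss of expert 1 but must differ in both seeds so that it learns
#' distinct features.
#'
#' @param expert_id Integer in 1..3.
#' @param loss_name One of `"bce_dice"`, `"focal"`, `"bce"`.
#' @param init_seed Seed for weight initialization.
#' @param partition_seed Seed for the expert's data partition.
#' @param unet A [unet_config()].
#' @return Object of class `expert_config`.
#' @export
expert_config <- function(expert_id, loss_name = c("bce_dice", "focal", "bce"),
                          init_seed = expert_id, partition_seed = expert_id,
                          unet = unet_config()) {
  loss_name <- match.arg(loss_name)
  structure(list(expert_id = as.integer(expert_id), loss_name = loss_name,
                 init_seed = as.integer(init_seed),
                 partition_seed = as.integer(partition_seed), unet = unet),
            class = "expert_config")
}

#' Default three-expert ensemble configuration
#'
#' Expert 1: BCE+Dice; expert 2: Focal; expert 3: BCE+Dice with different
#' initialization and data partition.
#'
#' @param unet A [unet_config()] shared by all experts.
#' @param base_seed Base for the per-expert init/partition seeds.
#' @return List of three [expert_config()]s.
#' @export
default_expert_configs <- function(unet = unet_config(), base_seed = 1L) {
  list(expert_config(1L, "bce_dice", init_seed = derive_seed(base_seed, 11),
                     partition_seed = derive_seed(base_seed, 21), unet = unet),
       expert_config(2L, "focal", init_seed = derive_seed(base_seed, 12),
                     partition_seed = derive_seed(base_seed, 22), unet = unet),
       expert_config(3L, "bce_dice", init_seed = derive_seed(base_seed, 13),
                     partition_seed = derive_seed(base_seed, 23), unet = unet))
}

unet_layer_plan <- function(cfg) {
  ch <- cfg$base_channels * 2^(seq_len(cfg$depth) - 1)
  plan <- list()
  in_ch <- 1L
  for (i in seq_len(cfg$depth)) {
    plan[[sprintf("enc%d_c1", i)]] <- c(in_ch, ch[i])
    plan[[sprintf("enc%d_c2", i)]] <- c(ch[i], ch[i])
    in_ch <- ch[i]
  }
  cb <- 2L * ch[cfg$depth]
  plan[["bott_c1"]] <- c(ch[cfg$depth], cb)
  plan[["bott_c2"]] <- c(cb, cb)
  up_ch <- cb
  for (i in rev(seq_len(cfg$depth))) {
    plan[[sprintf("dec%d_c1", i)]] <- c(up_ch + ch[i], ch[i])
    plan[[sprintf("dec%d_c2", i)]] <- c(ch[i], ch[i])
    up_ch <- ch[i]
  }
  plan[["final"]] <- c(ch[1], 1L)
  plan
}

#' Build an expert model
#'
#' Instantiates the U-Net with parameters drawn deterministically from the
#' expert's `init_seed` (He-normal initialization).
#'
#' @param cfg An [expert_config()].
#' @return Object of class `expert_model` with named convolution layers.
#' @export
build_expert <- function(cfg) {
  stopifnot(inherits(cfg, "expert_config"))
  plan <- unet_layer_plan(cfg$unet)
  layers <- with_seed(cfg$init_seed, {
    lapply(seq_along(plan), function(i) {
      nm <- names(plan)[i]
      io <- plan[[i]]
      if (nm == "final") new_conv_layer(io[1], io[2], k = 1, act = "sigmoid")
      else new_conv_layer(io[1], io[2], k = 3, act = "relu")
    })
  })
  names(layers) <- names(plan)
  structure(list(layers = layers, config = cfg), class = "expert_model")
}

#' Number of trainable parameters of an expert
#' @param model An `expert_model`.
#' @export
n_parameters <- function(model) length(flatten_layer_params(model$layers))

as_hwc <- function(image) {
  if (length(dim(image)) == 2) array(image, c(dim(image), 1L)) else image
}

#' Forward pass of a U-Net expert
#'
#' @param model An `expert_model` from [build_expert()].
#' @param image Preprocessed single-channel image: matrix or `[H, W, 1]`
#'   array with values in `[0, 1]`.
#' @param keep_cache Keep layer activations for a subsequent backward pass.
#' @return The probability map as an `[H, W]` matrix in (0, 1); with
#'   `keep_cache = TRUE`, a list `(prob, cache)`.
#' @export
unet_forward <- function(model, image, keep_cache = FALSE) {
  cfg <- model$config$unet
  x <- as_hwc(image)
  if (!all(dim(x)[1:2] %% 2^cfg$depth == 0))
    stop("input size incompatible with network depth", call. = FALSE)
  L <- model$layers
  cache <- list()
  skips <- vector("list", cfg$depth)
  for (i in seq_len(cfg$depth)) {
    c1 <- conv_fw(L[[sprintf("enc%d_c1", i)]], x)
    c2 <- conv_fw(L[[sprintf("enc%d_c2", i)]], c1$out)
    skips[[i]] <- c2$out
    mp <- maxpool2_fw_cpp(c2$out)
    x <- mp$out
    if (keep_cache) cache[[sprintf("enc%d", i)]] <-
        list(c1 = c1, c2 = c2, idx = mp$idx,
             hw = dim(c2$out)[1:2])
  }
  b1 <- conv_fw(L[["bott_c1"]], x)
  b2 <- conv_fw(L[["bott_c2"]], b1$out)
  if (keep_cache) cache[["bott"]] <- list(c1 = b1, c2 = b2)
  d <- b2$out
  for (i in rev(seq_len(cfg$depth))) {
    up <- up2_fw_cpp(d)
    cat_in <- abind3(up, skips[[i]])
    c1 <- conv_fw(L[[sprintf("dec%d_c1", i)]], cat_in)
    c2 <- conv_fw(L[[sprintf("dec%d_c2", i)]], c1$out)
    if (keep_cache) cache[[sprintf("dec%d", i)]] <-
        list(c1 = c1, c2 = c2, up_ch = dim(up)[3])
    d <- c2$out
  }
  fin <- conv_fw(L[["final"]], d)
  prob <- fin$out[, , 1]
  if (!keep_cache) return(prob)
  cache[["final"]] <- fin
  list(prob = prob, cache = cache)
}

abind3 <- function(a, b) {
  out <- array(0, c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
  out[, , seq_len(dim(a)[3])] <- a
  out[, , dim(a)[3] + seq_len(dim(b)[3])] <- b
  out
}

# Backward pass through the whole U-Net. `dlogit` is the gradient of the
# loss w.r.t. the pre-sigmoid logits of the final 1x1 convolution,
# as an [H, W] matrix. Returns per-layer parameter gradients and the
# gradient w.r.t. the input image.
unet_backward <- function(model, cache, dlogit) {
  cfg <- model$config$unet
  L <- model$layers
  grads <- list()
  fin <- cache[["final"]]
  dz <- array(dlogit, c(dim(dlogit), 1L))
  g <- conv2d_bw_cpp(fin$x, L[["final"]]$W, dz, 1L, 1L, 0L)
  grads[["final"]] <- list(dW = g$dw, db = as.numeric(g$db))
  dd <- g$dx
  dskips <- vector("list", cfg$depth)
  for (i in seq_len(cfg$depth)) {
    cc <- cache[[sprintf("dec%d", i)]]
    g2 <- conv_bw(L[[sprintf("dec%d_c2", i)]], cc$c2, dd)
    grads[[sprintf("dec%d_c2", i)]] <- g2[c("dW", "db")]
    g1 <- conv_bw(L[[sprintf("dec%d_c1", i)]], cc$c1, g2$dx)
    grads[[sprintf("dec%d_c1", i)]] <- g1[c("dW", "db")]
    up_ch <- cc$up_ch
    dup <- g1$dx[, , seq_len(up_ch), drop = FALSE]
    dskips[[i]] <- g1$dx[, , up_ch + seq_len(dim(g1$dx)[3] - up_ch),
                         drop = FALSE]
    dd <- up2_bw_cpp(dup)
  }
  # dd now matches the bottleneck output
  bc <- cache[["bott"]]
  g2 <- conv_bw(L[["bott_c2"]], bc$c2, dd)
  grads[["bott_c2"]] <- g2[c("dW", "db")]
  g1 <- conv_bw(L[["bott_c1"]], bc$c1, g2$dx)
  grads[["bott_c1"]] <- g1[c("dW", "db")]
  dd <- g1$dx
  for (i in rev(seq_len(cfg$depth))) {
    ec <- cache[[sprintf("enc%d", i)]]
    dpool <- maxpool2_bw_cpp(dd, ec$idx, ec$hw[1], ec$hw[2])
    dpool <- dpool + dskips[[i]]
    g2 <- conv_bw(L[[sprintf("enc%d_c2", i)]], ec$c2, dpool)
    grads[[sprintf("enc%d_c2", i)]] <- g2[c("dW", "db")]
    g1 <- conv_bw(L[[sprintf("enc%d_c1", i)]], ec$c1, g2$dx)
    grads[[sprintf("enc%d_c1", i)]] <- g1[c("dW", "db")]
    dd <- g1$dx
  }
  list(grads = grads, dx = dd)
}

#' Preprocess a raw image for the experts
#'
#' Converts RGB to luminance, rescales intensities to `[0, 1]` (when they
#' are not already) and resizes bilinearly to the target size. Already
#' conforming inputs are returned unchanged.
#'
#' @param raw 2D grayscale matrix, `[H, W, 3]` RGB array, or `[H, W, 1]`.
#' @param target_size Integer (H, W).
#' @return `[H, W]` matrix with values in `[0, 1]`.
#' @export
preprocess_image <- function(raw, target_size = c(256, 256)) {
  if (length(raw) == 0) stop("empty image", call. = FALSE)
  x <- raw
  if (length(dim(x)) == 3) {
    if (dim(x)[3] == 3)
      x <- 0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
    else if (dim(x)[3] == 1) x <- x[, , 1]
    else stop("expected 1 or 3 channels", call. = FALSE)
  }
  rng <- range(x)
  if (rng[1] < 0 || rng[2] > 1) {
    if (rng[2] > rng[1]) x <- (x - rng[1]) / (rng[2] - rng[1])
    else x <- x * 0
  }
  if (!all(dim(x) == target_size))
    x <- EBImage::resize(x, w = target_size[1], h = target_size[2])
  clip01(x)
}

#' Predict a binary mask with one expert
#'
#' @param model An `expert_model`.
#' @param image Preprocessed image.
#' @param threshold Binarization threshold for the probability map.
#' @return 0/1 integer matrix.
#' @export
predict_mask <- function(model, image, threshold = 0.5) {
  p <- unet_forward(model, image)
  m <- (p >= threshold) * 1L
  storage.mode(m) <- "integer"
  m
}

#' Save / load an expert checkpoint
#'
#' The checkpoint is a single RDS file containing the layer parameters and
#' a config echo.
#'
#' @param model An `expert_model`.
#' @param path File path.
#' @export
save_expert <- function(model, path) {
  saveRDS(list(layers = model$layers, config = model$config), path)
  invisible(path)
}

#' @rdname save_expert
#' @export
load_expert <- function(path) {
  obj <- readRDS(path)
  structure(list(layers = obj$layers, config = obj$config),
            class = "expert_model")
}
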