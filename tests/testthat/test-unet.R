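# U-Net experts: seeded construction, forward contracts, preprocessing.

test_that("parameter count matches an independent layer-by-layer tally", {
  m <- build_expert(expert_config(1, unet = tiny_unet(depth = 2, base = 4)))
  # independent tally for depth 2, base 4: channels 4, 8; bottleneck 16;
  # two 3x3 convs per stage, decoder concatenates skip channels, 1x1 head
  tally <- sum(
    4 * (1 * 9) + 4,    # enc1 conv1
    4 * (4 * 9) + 4,    # enc1 conv2
    8 * (4 * 9) + 8,    # enc2 conv1
    8 * (8 * 9) + 8,    # enc2 conv2
    16 * (8 * 9) + 16,  # bottleneck conv1
    16 * (16 * 9) + 16, # bottleneck conv2
    8 * ((16 + 8) * 9) + 8,  # dec2 conv1 (upsampled 16 + skip 8)
    8 * (8 * 9) + 8,         # dec2 conv2
    4 * ((8 + 4) * 9) + 4,   # dec1 conv1
    4 * (4 * 9) + 4,         # dec1 conv2
    1 * 4 + 1)               # final 1x1
  expect_identical(n_parameters(m), as.integer(tally))
})

test_that("identical configs build identical initial parameters", {
  cfg <- expert_config(2, "focal", init_seed = 31, partition_seed = 3,
                       unet = tiny_unet())
  expect_identical(flatten_params <- moeseg:::flatten_layer_params(
    build_expert(cfg)$layers),
    moeseg:::flatten_layer_params(build_expert(cfg)$layers))
  cfg2 <- expert_config(2, "focal", init_seed = 32, partition_seed = 3,
                        unet = tiny_unet())
  expect_false(identical(moeseg:::flatten_layer_params(build_expert(cfg)$layers),
                         moeseg:::flatten_layer_params(build_expert(cfg2)$layers)))
})

test_that("forward pass yields a probability map of the input size", {
  m <- build_expert(expert_config(1, unet = unet_config(3, 8, c(256, 256))))
  set.seed(1)
  p <- unet_forward(m, matrix(runif(256^2), 256, 256))
  expect_identical(dim(p), c(256L, 256L))
  expect_true(all(p > 0 & p < 1))
})

test_that("encoder feature maps halve the spatial resolution per stage", {
  m <- build_expert(expert_config(1, unet = unet_config(3, 4, c(64, 64))))
  fw <- unet_forward(m, matrix(0.5, 64, 64), keep_cache = TRUE)
  sizes <- vapply(1:3, function(i)
    fw$cache[[sprintf("enc%d", i)]]$hw[1], numeric(1))
  expect_identical(sizes, c(64, 32, 16))
  # bottleneck runs at 8x8 with no further downsampling
  expect_identical(dim(fw$cache$bott$c2$out)[1:2], c(8L, 8L))
})

test_that("zeroed final layer produces the constant sigmoid(bias)", {
  m <- build_expert(expert_config(1, unet = tiny_unet()))
  m$layers$final$W[] <- 0
  m$layers$final$b <- 0.7
  p <- unet_forward(m, matrix(runif(256), 16, 16))
  expect_equal(max(abs(p - 1 / (1 + exp(-0.7)))), 0, tolerance = 1e-12)
})

test_that("forward output is bit-identical across repeated runs", {
  m <- build_expert(expert_config(3, init_seed = 77, partition_seed = 1,
                                  unet = tiny_unet(size = 16)))
  img <- matrix(seq(0, 1, length.out = 256), 16, 16)
  expect_identical(unet_forward(m, img), unet_forward(m, img))
})

test_that("backpropagated gradients match finite differences", {
  m <- build_expert(expert_config(1, unet = tiny_unet()))
  set.seed(4)
  img <- matrix(runif(256), 16, 16)
  fw <- unet_forward(m, img, keep_cache = TRUE)
  S <- fw$prob
  # loss L = sum(S^2) / 2  =>  dL/dS = S, chained through the sigmoid
  bw <- moeseg:::unet_backward(m, fw$cache, S * S * (1 - S))
  eps <- 1e-6
  L0 <- sum(S^2) / 2
  img2 <- img; img2[5, 7] <- img2[5, 7] + eps
  fd_in <- (sum(unet_forward(m, img2)^2) / 2 - L0) / eps
  expect_equal(bw$dx[5, 7, 1], fd_in, tolerance = 1e-4)
  m2 <- m; m2$layers$enc1_c2$W[2, 5] <- m2$layers$enc1_c2$W[2, 5] + eps
  fd_w <- (sum(unet_forward(m2, img)^2) / 2 - L0) / eps
  expect_equal(bw$grads$enc1_c2$dW[2, 5], fd_w, tolerance = 1e-4)
})

test_that("input sizes not divisible by 2^depth are rejected", {
  expect_error(unet_config(3, 4, c(60, 60)), "divisible")
  m <- build_expert(expert_config(1, unet = tiny_unet(size = 16)))
  expect_error(unet_forward(m, matrix(0.5, 15, 15)), "incompatible")
})

test_that("preprocessing converts RGB, rescales and is idempotent", {
  rgb <- array(runif(32 * 32 * 3), c(32, 32, 3))
  g <- preprocess_image(rgb, c(32, 32))
  expect_identical(dim(g), c(32L, 32L))
  expect_equal(g, 0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3],
               tolerance = 1e-12)
  expect_identical(preprocess_image(g, c(32, 32)), g)
  hu <- matrix(seq(-1000, 1000, length.out = 64 * 64), 64, 64)
  expect_equal(range(preprocess_image(hu, c(64, 64))), c(0, 1))
  expect_error(preprocess_image(matrix(numeric(0), 0, 0)), "empty")
})

test_that("downsampling preserves mean intensity against a block oracle", {
  set.seed(8)
  src <- matrix(runif(128 * 128), 128, 128)
  small <- preprocess_image(src, c(64, 64))
  expect_identical(dim(small), c(64L, 64L))
  # block-average oracle: mean of each 2x2 block
  block <- 0.25 * (src[seq(1, 127, 2), seq(1, 127, 2)] +
                   src[seq(2, 128, 2), seq(1, 127, 2)] +
                   src[seq(1, 127, 2), seq(2, 128, 2)] +
                   src[seq(2, 128, 2), seq(2, 128, 2)])
  expect_lt(abs(mean(small) / mean(block) - 1), 0.02)
})

test_that("checkpoints round-trip through disk", {
  m <- build_expert(expert_config(1, unet = tiny_unet()))
  f <- tempfile(fileext = ".rds")
  save_expert(m, f)
  m2 <- load_expert(f)
  expect_identical(m2$layers, m$layers)
  expect_identical(m2$config, m$config)
  img <- matrix(runif(256), 16, 16)
  expect_identical(unet_forward(m, img), unet_forward(m2, img))
})
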