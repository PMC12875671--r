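# Router: error maps, error learner, weight router, fusion, attention.

test_that("error maps are the signed prediction minus ground truth", {
  Y <- matrix(c(0, 1, 1, 0), 2, 2)
  P <- matrix(c(1, 0, 1, 0), 2, 2)
  E <- compute_error_maps(list(P), Y)[[1]]
  expect_identical(E[1, 1], 1)    # confident false positive
  expect_identical(E[2, 1], -1)   # confident false negative
  expect_identical(E[1, 2], 0)
  expect_identical(compute_error_maps(list(Y), Y)[[1]], Y - Y)
  set.seed(1)
  preds <- lapply(1:3, function(i) matrix(runif(16), 4, 4))
  Y4 <- matrix(rbinom(16, 1, 0.5), 4, 4)
  E3 <- compute_error_maps(preds, Y4)
  for (i in 1:3)
    for (r in 1:4) for (c in 1:4)
      expect_identical(E3[[i]][r, c], preds[[i]][r, c] - Y4[r, c])
  expect_true(all(sapply(E3, function(e) all(e >= -1 & e <= 1))))
})

test_that("disagreement maps deviate from the ensemble mean and sum to zero", {
  set.seed(2)
  preds <- lapply(1:3, function(i) matrix(runif(16), 4, 4))
  D <- disagreement_maps(preds)
  expect_equal(Reduce(`+`, D), matrix(0, 4, 4), tolerance = 1e-12)
  pbar <- (preds[[1]] + preds[[2]] + preds[[3]]) / 3
  expect_equal(D[[2]], preds[[2]] - pbar, tolerance = 1e-12)
})

test_that("error learner maps 1+3 channels to the configured feature stack", {
  router <- build_router(router_config(init_seed = 5))
  img <- matrix(runif(32 * 32), 32, 32)
  errs <- lapply(1:3, function(i) matrix(rnorm(32 * 32, 0, 0.1), 32, 32))
  f <- error_learner_forward(router, img, errs)
  expect_identical(dim(f), c(32L, 32L, 8L))
  expect_identical(error_learner_forward(router, img, errs), f) # deterministic
  expect_error(error_learner_forward(router, img, errs[1:2]), "expected 3")
  # zeroed weights with bias -> constant feature maps
  r0 <- router
  for (nm in names(r0$error_learner)) {
    r0$error_learner[[nm]]$W[] <- 0
    r0$error_learner[[nm]]$b[] <- 0.3
  }
  f0 <- error_learner_forward(r0, img, errs)
  expect_identical(length(unique(as.vector(f0))), 1L)
})

test_that("weight maps satisfy the per-pixel simplex constraint", {
  router <- build_router(router_config(init_seed = 6))
  img <- matrix(runif(32 * 32), 32, 32)
  feats <- array(rnorm(32 * 32 * 8), c(32, 32, 8))
  w <- robust_weight_router(router, img, feats)
  expect_identical(dim(w), c(32L, 32L, 3L))
  expect_true(all(w >= 0))
  expect_lt(max(abs(apply(w, c(1, 2), sum) - 1)), 1e-6)
  # zeroed router -> exactly uniform weights
  r0 <- router
  for (nm in names(r0$weight_router)) {
    r0$weight_router[[nm]]$W[] <- 0
    r0$weight_router[[nm]]$b[] <- 0
  }
  w0 <- robust_weight_router(r0, img, feats)
  expect_equal(as.vector(w0), rep(1 / 3, length(w0)), tolerance = 1e-12)
})

test_that("softmax of logits (2, 0, 0) gives the known weights", {
  sm <- moeseg:::softmax_channels(array(c(2, 0, 0), c(1, 1, 3)))
  expect_equal(as.vector(sm), c(exp(2), 1, 1) / (exp(2) + 2),
               tolerance = 1e-12)
  expect_equal(as.vector(sm), c(0.7870, 0.1065, 0.1065), tolerance = 1e-4)
})

test_that("fusion is an exact convex combination", {
  set.seed(3)
  preds <- lapply(1:3, function(i) matrix(runif(16), 4, 4))
  onehot <- array(0, c(4, 4, 3)); onehot[, , 2] <- 1
  expect_identical(fuse_predictions(preds, onehot), preds[[2]])
  unif <- array(1 / 3, c(4, 4, 3))
  expect_equal(fuse_predictions(preds, unif),
               (preds[[1]] + preds[[2]] + preds[[3]]) / 3, tolerance = 1e-12)
  set.seed(4)
  raw <- array(runif(48), c(4, 4, 3))
  w <- sweep(raw, c(1, 2), apply(raw, c(1, 2), sum), "/")
  fused <- fuse_predictions(preds, w)
  for (r in 1:4) for (c in 1:4) {
    acc <- 0
    for (i in 1:3) acc <- acc + w[r, c, i] * preds[[i]][r, c]
    expect_equal(fused[r, c], acc, tolerance = 1e-10)
  }
  lo <- pmin(preds[[1]], preds[[2]], preds[[3]])
  hi <- pmax(preds[[1]], preds[[2]], preds[[3]])
  expect_true(all(fused >= lo - 1e-12 & fused <= hi + 1e-12))
  bad <- w; bad[1, 1, ] <- c(0.9, 0.9, 0.9)
  expect_error(fuse_predictions(preds, bad), "simplex")
})

test_that("attention map matches finite differences and its normalization", {
  fr <- untrained_framework()
  set.seed(5)
  img <- matrix(runif(32 * 32), 32, 32)
  am <- attention_map(fr, img)
  expect_true(all(is.finite(am$attention)))
  # by construction ||A / Z||_1 = 1
  expect_equal(sum(abs(am$attention)) / abs(am$Z), 1, tolerance = 1e-10)
  Zf <- function(im) mean(moe_predict(fr, im)$fused_prob)
  eps <- 1e-5
  for (px in list(c(10, 20), c(3, 30))) {
    img2 <- img
    img2[px[1], px[2]] <- img2[px[1], px[2]] + eps
    fd <- (Zf(img2) - am$Z) / eps
    expect_equal(am$grad[px[1], px[2]], fd, tolerance = 1e-4 * max(1, abs(fd)))
  }
})

test_that("prediction emits every explainability artifact", {
  fr <- untrained_framework()
  img <- matrix(runif(32 * 32), 32, 32)
  truth <- disk_mask(32, 16, 16, 8)
  pr <- moe_predict(fr, img, truth = truth)
  expect_length(pr$expert_probs, 3)
  expect_length(pr$disagreement, 3)
  expect_identical(dim(pr$features), c(32L, 32L, 8L))
  expect_identical(dim(pr$weights), c(32L, 32L, 3L))
  expect_identical(dim(pr$fused_prob), c(32L, 32L))
  expect_true(all(pr$fused_mask %in% c(0L, 1L)))
  expect_equal(pr$error_maps[[1]], pr$expert_probs[[1]] - truth,
               tolerance = 1e-12)
})

test_that("router training leaves frozen expert parameters untouched", {
  sp <- noiseless_spec(size = 32, lumen = c(6, 9), wall = c(2, 3), seed = 2)
  samples <- lapply(1:3, function(i) generate_slice(sp, seed = i))
  fr <- untrained_framework()
  before <- lapply(fr$experts, function(e) moeseg:::flatten_layer_params(e$layers))
  router <- train_router(build_router(router_config(init_seed = 9)),
                         fr$experts, samples, task = "wall",
                         schedule = train_schedule(epochs_router = 1, seed = 1))
  after <- lapply(fr$experts, function(e) moeseg:::flatten_layer_params(e$layers))
  expect_identical(before, after)
  expect_s3_class(router, "moe_router")
})
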