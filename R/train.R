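# Training of the mixture-of-experts framework.
#
# Stage 1 trains each U-Net expert independently on its own data partition
# with its own loss. Stage 2 freezes the experts and trains the error
# learner and robust weight router end-to-end by minimizing the BCE of the
# fused prediction. An optional stage 3 jointly fine-tunes everything with
# the total objective (segmentation minus the weighted diversity reward).

#' Training schedule
#'
#' @param epochs_experts Epochs of per-expert training (stage 1).
#' @param epochs_router Epochs of router training (stage 2).
#' @param epochs_joint Epochs of joint fine-tuning with the total loss
#'   (stage 3); 0 disables it.
#' @param lr Adam learning rate.
#' @param seed Seed for sample shuffling.
#' @return Object of class `train_schedule`.
#' @export
train_schedule <- function(epochs_experts = 4, epochs_router = 4,
                           epochs_joint = 0, lr = 1e-3, seed = 1L) {
  structure(list(epochs_experts = as.integer(epochs_experts),
                 epochs_router = as.integer(epochs_router),
                 epochs_joint = as.integer(epochs_joint),
                 lr = lr, seed = as.integer(seed)),
            class = "train_schedule")
}

# One named task ("lumen" or "wall") selects which ground-truth mask an
# expert learns.
task_mask <- function(sample, task) {
  switch(task, lumen = sample$lumen_mask, wall = sample$wall_mask,
         stop(sprintf("unknown task '%s'", task), call. = FALSE))
}

#' Train a single expert
#'
#' Per-sample Adam updates under the expert's configured loss. Shuffling is
#' seeded; training is deterministic on a fixed machine.
#'
#' @param model An `expert_model`.
#' @param samples List of `phantom_sample` training slices.
#' @param task `"lumen"` or `"wall"`.
#' @param schedule A [train_schedule()].
#' @param loss_cfg A [loss_config()].
#' @param log A [training_logger()] or `NULL`.
#' @return The trained `expert_model`.
#' @export
train_expert <- function(model, samples, task = "wall",
                         schedule = train_schedule(),
                         loss_cfg = loss_config(), log = NULL) {
  loss_name <- model$config$loss_name
  state <- adam_init(model$layers)
  t <- 0
  for (ep in seq_len(schedule$epochs_experts)) {
    ord <- with_seed(derive_seed(schedule$seed,
                                 1000 * model$config$expert_id + ep),
                     sample.int(length(samples)))
    for (ix in ord) {
      smp <- samples[[ix]]
      Y <- task_mask(smp, task)
      fw <- unet_forward(model, smp$image, keep_cache = TRUE)
      S <- fw$prob
      if (!all(is.finite(S))) stop("NaN in expert forward pass", call. = FALSE)
      lv <- loss_value(loss_name, S, Y, loss_cfg)
      if (!is.finite(lv))
        stop(sprintf("non-finite loss (%s) during expert %d training",
                     loss_name, model$config$expert_id), call. = FALSE)
      dlogit <- matrix(loss_grad_logits(loss_name, as.vector(S), as.vector(Y),
                                        loss_cfg), nrow(S), ncol(S))
      bw <- unet_backward(model, fw$cache, dlogit)
      t <- t + 1
      upd <- adam_step(model$layers, bw$grads, state, t, schedule$lr)
      model$layers <- upd$layers
      state <- upd$state
      log_step(log, stage = "expert", expert = model$config$expert_id,
               epoch = ep, step = t, loss = lv)
    }
  }
  model
}

router_input_maps <- function(router_cfg, preds, Y) {
  if (router_cfg$train_input == "error") compute_error_maps(preds, Y)
  else disagreement_maps(preds)
}

#' Train the routers on frozen experts
#'
#' Expert predictions on the router-training set are computed once; the
#' error learner and weight router are then optimized jointly to minimize
#' the BCE of the fused prediction. Depending on
#' `router$config$train_input`, the router consumes either the true error
#' maps (teacher forcing) or the inference-time disagreement maps
#' (default).
#'
#' @param router A `moe_router`.
#' @param experts List of trained (frozen) `expert_model`s.
#' @param samples Training slices.
#' @param task `"lumen"` or `"wall"`.
#' @param schedule A [train_schedule()].
#' @param loss_cfg A [loss_config()].
#' @param log A [training_logger()] or `NULL`.
#' @return The trained `moe_router`.
#' @export
train_router <- function(router, experts, samples, task = "wall",
                         schedule = train_schedule(),
                         loss_cfg = loss_config(), log = NULL) {
  pred_list <- lapply(samples, function(smp)
    lapply(experts, unet_forward, image = smp$image))
  el_state <- adam_init(router$error_learner)
  wr_state <- adam_init(router$weight_router)
  t <- 0
  m <- router$config$n_experts
  for (ep in seq_len(schedule$epochs_router)) {
    ord <- with_seed(derive_seed(schedule$seed, 5000 + ep),
                     sample.int(length(samples)))
    for (ix in ord) {
      smp <- samples[[ix]]
      Y <- task_mask(smp, task)
      preds <- pred_list[[ix]]
      maps <- router_input_maps(router$config, preds, Y)
      elr <- error_learner_forward(router, smp$image, maps, keep_cache = TRUE)
      wr <- robust_weight_router(router, smp$image, elr$out, keep_cache = TRUE)
      fused <- fuse_predictions(preds, wr$weights)
      lv <- seg_loss(fused, Y, loss_cfg$clip_eps)
      if (!is.finite(lv)) stop("non-finite router loss", call. = FALSE)
      # d(BCE)/d(fused)
      f <- clip01(fused, loss_cfg$clip_eps)
      dfused <- (-(Y / f) + (1 - Y) / (1 - f)) / length(f)
      H <- nrow(Y); W <- ncol(Y)
      dw <- array(0, c(H, W, m))
      for (i in seq_len(m)) dw[, , i] <- dfused * preds[[i]]
      wsum <- array(0, c(H, W))
      for (i in seq_len(m)) wsum <- wsum + wr$weights[, , i] * dw[, , i]
      dlogits <- array(0, c(H, W, m))
      for (i in seq_len(m))
        dlogits[, , i] <- wr$weights[, , i] * (dw[, , i] - wsum)
      # anti-collapse regularization: L2 decay on the gate logits
      if (router$config$logit_decay > 0)
        dlogits <- dlogits +
          router$config$logit_decay * wr$logits / length(wr$logits)
      wb <- seq_backward(router$weight_router, wr$caches, dlogits)
      dfeats <- wb$dx[, , -1, drop = FALSE]
      eb <- seq_backward(router$error_learner, elr$caches, dfeats)
      t <- t + 1
      upd <- adam_step(router$weight_router, wb$grads, wr_state, t, schedule$lr)
      router$weight_router <- upd$layers; wr_state <- upd$state
      upd <- adam_step(router$error_learner, eb$grads, el_state, t, schedule$lr)
      router$error_learner <- upd$layers; el_state <- upd$state
      log_step(log, stage = "router", expert = NA, epoch = ep, step = t,
               loss = lv)
    }
  }
  router
}

#' Train the full mixture-of-experts framework
#'
#' Stage 1: each expert is trained independently on its own partition (its
#' `partition_seed` selects a subset of `samples` unless explicit
#' `partitions` are given) with its own loss. Stage 2: experts are frozen
#' and the routers are trained on `samples`. Stage 3 (optional,
#' `schedule$epochs_joint > 0`): everything is fine-tuned jointly with
#' `L_total = L_seg - lambda_reg * L_div`.
#'
#' @param samples Training slices (list of `phantom_sample`).
#' @param expert_cfgs List of three [expert_config()]s.
#' @param router_cfg A [router_config()].
#' @param task `"lumen"` or `"wall"`.
#' @param schedule A [train_schedule()].
#' @param loss_cfg A [loss_config()].
#' @param partitions Optional list of index vectors, one per expert,
#'   overriding the seed-derived partitions (used e.g. to specialize
#'   experts on thick- vs thin-wall slices).
#' @param partition_fraction Fraction of `samples` each seed-derived
#'   partition draws.
#' @param log A [training_logger()] or `NULL`.
#' @return Object of class `moe_framework`: `experts`, `router`, `task`,
#'   `configs`.
#' @export
train_framework <- function(samples, expert_cfgs = default_expert_configs(),
                            router_cfg = router_config(), task = "wall",
                            schedule = train_schedule(),
                            loss_cfg = loss_config(),
                            partitions = NULL, partition_fraction = 0.8,
                            log = NULL) {
  n <- length(samples)
  if (is.null(partitions)) {
    partitions <- lapply(expert_cfgs, function(cfg)
      with_seed(cfg$partition_seed,
                sort(sample.int(n, max(1, round(partition_fraction * n))))))
  }
  experts <- vector("list", length(expert_cfgs))
  for (i in seq_along(expert_cfgs)) {
    model <- build_expert(expert_cfgs[[i]])
    experts[[i]] <- train_expert(model, samples[partitions[[i]]], task,
                                 schedule, loss_cfg, log)
  }
  router <- build_router(router_cfg)
  router <- train_router(router, experts, samples, task, schedule, loss_cfg,
                         log)
  fr <- structure(list(experts = experts, router = router, task = task,
                       configs = list(experts = expert_cfgs,
                                      router = router_cfg,
                                      schedule = schedule,
                                      loss = loss_cfg,
                                      partitions = partitions)),
                  class = "moe_framework")
  if (schedule$epochs_joint > 0)
    fr <- joint_finetune(fr, samples, schedule, loss_cfg, log)
  fr
}

# Stage 3: joint fine-tuning with the total objective. The segmentation
# gradient flows through fusion into routers and experts; the diversity
# reward adds dL_div/dtheta_i = sum_j 2 (theta_i - theta_j) per expert,
# with the diversity term capped as in total_loss().
joint_finetune <- function(framework, samples, schedule, loss_cfg, log) {
  m <- length(framework$experts)
  ex_states <- lapply(framework$experts, function(e) adam_init(e$layers))
  el_state <- adam_init(framework$router$error_learner)
  wr_state <- adam_init(framework$router$weight_router)
  t <- 0
  for (ep in seq_len(schedule$epochs_joint)) {
    ord <- with_seed(derive_seed(schedule$seed, 9000 + ep),
                     sample.int(length(samples)))
    for (ix in ord) {
      smp <- samples[[ix]]
      Y <- task_mask(smp, framework$task)
      fw <- moe_forward_full(framework, smp$image, keep_cache = TRUE)
      seg <- seg_loss(fw$fused, Y, loss_cfg$clip_eps)
      pvecs <- lapply(framework$experts,
                      function(e) flatten_layer_params(e$layers))
      div <- diversity_loss(pvecs)
      lv <- total_loss(seg, div, loss_cfg$lambda_reg, loss_cfg$div_cap)
      if (!is.finite(lv)) stop("non-finite joint loss", call. = FALSE)
      f <- clip01(fw$fused, loss_cfg$clip_eps)
      dfused <- (-(Y / f) + (1 - Y) / (1 - f)) / length(f)
      H <- nrow(Y); W <- ncol(Y)
      dw <- array(0, c(H, W, m))
      dpred_direct <- vector("list", m)
      for (i in seq_len(m)) {
        dw[, , i] <- dfused * fw$preds[[i]]
        dpred_direct[[i]] <- dfused * fw$weights[, , i]
      }
      wsum <- array(0, c(H, W))
      for (i in seq_len(m)) wsum <- wsum + fw$weights[, , i] * dw[, , i]
      dlogits <- array(0, c(H, W, m))
      for (i in seq_len(m))
        dlogits[, , i] <- fw$weights[, , i] * (dw[, , i] - wsum)
      wb <- seq_backward(framework$router$weight_router, fw$wr$caches, dlogits)
      dfeats <- wb$dx[, , -1, drop = FALSE]
      eb <- seq_backward(framework$router$error_learner, fw$el$caches, dfeats)
      ddmaps <- eb$dx[, , -1, drop = FALSE]
      dsum <- array(0, c(H, W))
      for (i in seq_len(m)) dsum <- dsum + ddmaps[, , i]
      t <- t + 1
      cap_active <- abs(div) > loss_cfg$div_cap
      for (i in seq_len(m)) {
        dS <- dpred_direct[[i]] + (ddmaps[, , i] - dsum / m)
        S <- fw$preds[[i]]
        dlogit <- dS * S * (1 - S)
        ub <- unet_backward(framework$experts[[i]], fw$expert_fw[[i]]$cache,
                            dlogit)
        # diversity reward: subtract lambda * dDiv/dtheta_i (unless capped)
        if (!cap_active) {
          others <- setdiff(seq_len(m), i)
          for (nm in names(ub$grads)) {
            Wi <- framework$experts[[i]]$layers[[nm]]$W
            bi <- framework$experts[[i]]$layers[[nm]]$b
            Wo <- Reduce(`+`, lapply(others, function(j)
              framework$experts[[j]]$layers[[nm]]$W))
            bo <- Reduce(`+`, lapply(others, function(j)
              framework$experts[[j]]$layers[[nm]]$b))
            ub$grads[[nm]]$dW <- ub$grads[[nm]]$dW -
              loss_cfg$lambda_reg * 2 * (length(others) * Wi - Wo)
            ub$grads[[nm]]$db <- ub$grads[[nm]]$db -
              loss_cfg$lambda_reg * 2 * (length(others) * bi - bo)
          }
        }
        upd <- adam_step(framework$experts[[i]]$layers, ub$grads,
                         ex_states[[i]], t, schedule$lr)
        framework$experts[[i]]$layers <- upd$layers
        ex_states[[i]] <- upd$state
      }
      upd <- adam_step(framework$router$weight_router, wb$grads, wr_state, t,
                       schedule$lr)
      framework$router$weight_router <- upd$layers; wr_state <- upd$state
      upd <- adam_step(framework$router$error_learner, eb$grads, el_state, t,
                       schedule$lr)
      framework$router$error_learner <- upd$layers; el_state <- upd$state
      log_step(log, stage = "joint", expert = NA, epoch = ep, step = t,
               loss = lv)
    }
  }
  framework
}

#' Mean Dice of a model or framework over a sample set
#'
#' @param object An `expert_model` or `moe_framework`.
#' @param samples Slices to evaluate.
#' @param task `"lumen"` or `"wall"`.
#' @param threshold Binarization threshold.
#' @export
mean_dice <- function(object, samples, task = "wall", threshold = 0.5) {
  ds <- vapply(samples, function(smp) {
    Y <- task_mask(smp, task)
    mask <- if (inherits(object, "moe_framework"))
      moe_predict(object, smp$image, threshold = threshold)$fused_mask
    else predict_mask(object, smp$image, threshold)
    dice(mask, Y)
  }, numeric(1))
  mean(ds)
}

# ---- training log -----------------------------------------------------------

#' Step-wise CSV training logger
#'
#' Appends one row per optimization step (stage, expert, epoch, step,
#' loss) to a CSV file.
#'
#' @param path CSV file path.
#' @return Object of class `training_logger`.
#' @export
training_logger <- function(path) {
  if (!file.exists(path))
    write.csv(data.frame(stage = character(), expert = integer(),
                         epoch = integer(), step = integer(),
                         loss = numeric()),
              path, row.names = FALSE)
  structure(list(path = path), class = "training_logger")
}

log_step <- function(log, stage, expert, epoch, step, loss) {
  if (is.null(log)) return(invisible(NULL))
  row <- data.frame(stage = stage, expert = expert, epoch = epoch,
                    step = step, loss = loss)
  utils::write.table(row, log$path, append = TRUE, sep = ",",
                     col.names = FALSE, row.names = FALSE)
  invisible(NULL)
}
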