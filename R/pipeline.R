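# End-to-end orchestration: dataset generation, expert/router training,
# prediction with explainability artifacts, correction, evaluation and
# measurement. Every command is a pure function of (config, seed, inputs)
# and writes a JSON manifest next to its outputs, so a rerun with the same
# seed reproduces identical artifacts.

#' Experiment configuration
#'
#' Gathers every tunable of a full experiment. The object round-trips
#' losslessly through YAML ([save_config()] / [load_config()]).
#'
#' @param image_size Square image side in px (divisible by `2^depth`).
#' @param depth,base_channels U-Net architecture.
#' @param n_samples Phantom pool size.
#' @param split Train/val/test fractions.
#' @param tasks Character subset of `c("lumen", "wall")`.
#' @param epochs_experts,epochs_router,epochs_joint,lr Training schedule.
#' @param router_train_input `"disagreement"` or `"error"`.
#' @param noise_sigma,thrombus_probability,low_contrast_fraction,artifact_probability,pixel_spacing
#'   Phantom generator settings.
#' @param seed Master seed; all stage seeds derive from it.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(image_size = 128, depth = 4, base_channels = 8,
                              n_samples = 60, split = c(0.7, 0.15, 0.15),
                              tasks = c("lumen", "wall"),
                              epochs_experts = 3, epochs_router = 3,
                              epochs_joint = 0, lr = 1e-3,
                              router_train_input = "disagreement",
                              noise_sigma = 0.05,
                              thrombus_probability = 0.3,
                              low_contrast_fraction = 0.1,
                              artifact_probability = 0.1,
                              pixel_spacing = 0.7, seed = 1L) {
  structure(list(image_size = as.integer(image_size),
                 depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 n_samples = as.integer(n_samples),
                 split = as.numeric(split), tasks = tasks,
                 epochs_experts = as.integer(epochs_experts),
                 epochs_router = as.integer(epochs_router),
                 epochs_joint = as.integer(epochs_joint), lr = lr,
                 router_train_input = router_train_input,
                 noise_sigma = noise_sigma,
                 thrombus_probability = thrombus_probability,
                 low_contrast_fraction = low_contrast_fraction,
                 artifact_probability = artifact_probability,
                 pixel_spacing = pixel_spacing, seed = as.integer(seed)),
            class = "experiment_config")
}

#' @rdname experiment_config
#' @param config An `experiment_config`.
#' @param path YAML file path.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname experiment_config
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(experiment_config, raw[names(raw) %in%
                                          names(formals(experiment_config))])
  cfg
}

config_phantom_spec <- function(config) {
  max_r <- floor(config$image_size / 2 * 0.55)
  phantom_spec(image_size = config$image_size,
               lumen_radius_range = c(max(6, round(max_r * 0.3)), max_r),
               wall_thickness_range = c(1, max(2, round(max_r * 0.2))),
               thrombus_probability = config$thrombus_probability,
               noise_sigma = config$noise_sigma,
               low_contrast_fraction = config$low_contrast_fraction,
               artifact_probability = config$artifact_probability,
               pixel_spacing = config$pixel_spacing,
               seed = derive_seed(config$seed, 1))
}

config_expert_cfgs <- function(config) {
  default_expert_configs(unet = unet_config(config$depth,
                                            config$base_channels,
                                            c(config$image_size,
                                              config$image_size)),
                         base_seed = config$seed)
}

#' Generate a dataset on disk
#'
#' @param config An [experiment_config()].
#' @param out_dir Output directory; `train/`, `val/`, `test/` subfolders
#'   are created with one sample per basename plus a manifest.
#' @return Invisibly, the dataset (also usable in memory).
#' @export
run_generate <- function(config, out_dir) {
  spec <- config_phantom_spec(config)
  ds <- make_dataset(config$n_samples, spec, config$split,
                     partition_seed = derive_seed(config$seed, 2))
  for (part in c("train", "val", "test")) {
    sub <- file.path(out_dir, part)
    for (i in seq_along(ds[[part]]))
      write_sample(ds[[part]][[i]], sub, sprintf("sample_%03d", i))
  }
  write_manifest(file.path(out_dir, "manifest.json"), "generate",
                 inputs = list(seed = config$seed,
                               n_samples = config$n_samples),
                 outputs = list(dir = out_dir,
                                sizes = lapply(ds[c("train", "val", "test")],
                                               length)),
                 config = config)
  invisible(ds)
}

read_dataset_dir <- function(dir) {
  parts <- lapply(c(train = "train", val = "val", test = "test"),
                  function(p) {
    files <- sort(list.files(file.path(dir, p), pattern = "\\.rds$",
                             full.names = TRUE))
    lapply(files, readRDS)
  })
  parts
}

#' Train the framework for each configured task
#'
#' @param config An [experiment_config()].
#' @param dataset A dataset list from [run_generate()] / [make_dataset()],
#'   or a directory written by [run_generate()].
#' @param out_dir Checkpoint/log directory.
#' @return Invisibly, a named list of `moe_framework`s (one per task).
#' @export
run_train <- function(config, dataset, out_dir) {
  if (is.character(dataset)) dataset <- read_dataset_dir(dataset)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sched <- train_schedule(config$epochs_experts, config$epochs_router,
                          config$epochs_joint, config$lr,
                          seed = derive_seed(config$seed, 3))
  frameworks <- list()
  for (task in config$tasks) {
    log <- training_logger(file.path(out_dir,
                                     sprintf("train_log_%s.csv", task)))
    fr <- train_framework(dataset$train,
                          expert_cfgs = config_expert_cfgs(config),
                          router_cfg = router_config(
                            train_input = config$router_train_input,
                            init_seed = derive_seed(config$seed, 4)),
                          task = task, schedule = sched, log = log)
    saveRDS(fr, file.path(out_dir, sprintf("framework_%s.rds", task)))
    frameworks[[task]] <- fr
  }
  write_manifest(file.path(out_dir, "manifest.json"), "train",
                 inputs = list(n_train = length(dataset$train),
                               tasks = config$tasks),
                 outputs = list(checkpoints = sprintf("framework_%s.rds",
                                                      config$tasks)),
                 config = config)
  invisible(frameworks)
}

#' Predict with explainability artifacts
#'
#' For each input image and task, emits the fused mask (PNG), the fused
#' probability, the three expert probability maps, the per-pixel weight
#' map and the disagreement maps (all lossless RDS), a color-mapped
#' weight PNG, and a JSON manifest echoing every path.
#'
#' @param config An [experiment_config()].
#' @param frameworks Named list of `moe_framework`s (or directory written
#'   by [run_train()]).
#' @param images List of image matrices (or samples).
#' @param out_dir Output directory.
#' @return Invisibly, the per-image prediction lists.
#' @export
run_predict <- function(config, frameworks, images, out_dir) {
  if (is.character(frameworks)) {
    dirn <- frameworks
    frameworks <- lapply(setNames(config$tasks, config$tasks), function(task) {
      f <- file.path(dirn, sprintf("framework_%s.rds", task))
      if (!file.exists(f))
        stop(sprintf("missing checkpoint '%s'; run run_train() first", f),
             call. = FALSE)
      readRDS(f)
    })
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- vector("list", length(images))
  files <- list()
  for (i in seq_along(images)) {
    img <- images[[i]]
    if (inherits(img, "phantom_sample")) img <- img$image
    per_task <- list()
    for (task in names(frameworks)) {
      pr <- moe_predict(frameworks[[task]], img)
      base <- sprintf("img%03d_%s", i, task)
      p <- list(mask = file.path(out_dir, paste0(base, "_mask.png")),
                arrays = file.path(out_dir, paste0(base, "_arrays.rds")),
                weights_png = file.path(out_dir, paste0(base, "_weights.png")))
      write_mask_png(pr$fused_mask, p$mask)
      saveRDS(pr[c("expert_probs", "disagreement", "weights", "fused_prob")],
              p$arrays)
      png::writePNG(pr$weights, p$weights_png)  # 3 experts -> RGB channels
      files[[base]] <- p
      per_task[[task]] <- pr
    }
    out[[i]] <- per_task
  }
  write_manifest(file.path(out_dir, "manifest.json"), "predict",
                 inputs = list(n_images = length(images),
                               tasks = names(frameworks)),
                 outputs = files, config = config)
  invisible(out)
}

#' Evaluate predictions against ground truth
#'
#' @param config An [experiment_config()].
#' @param preds,truths Lists of binary masks.
#' @param out_dir Output directory for `metrics_per_slice.csv`,
#'   `metrics_summary.csv` and a JSON summary.
#' @return Invisibly, the [evaluate_masks()] result.
#' @export
run_evaluate <- function(config, preds, truths, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ev <- evaluate_masks(preds, truths, spacing = config$pixel_spacing)
  write.csv(ev$per_slice, file.path(out_dir, "metrics_per_slice.csv"),
            row.names = FALSE)
  write.csv(ev$summary, file.path(out_dir, "metrics_summary.csv"),
            row.names = FALSE)
  jsonlite::write_json(ev$summary, file.path(out_dir, "metrics_summary.json"),
                       digits = NA, dataframe = "rows")
  write_manifest(file.path(out_dir, "manifest.json"), "evaluate",
                 inputs = list(n = length(preds)),
                 outputs = list(per_slice = "metrics_per_slice.csv",
                                summary = "metrics_summary.csv"),
                 config = config)
  invisible(ev)
}

#' Measure exam geometry from masks
#'
#' @param config An [experiment_config()].
#' @param lumen_masks,wall_masks Per-slice mask lists.
#' @param labels List with `neck_slice` and `iliac_slices`.
#' @param out_dir Output directory for the geometry JSON and per-slice CSV.
#' @return Invisibly, the `geometry_report`.
#' @export
run_measure <- function(config, lumen_masks, wall_masks, labels, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rep <- exam_geometry(lumen_masks, wall_masks, labels,
                       spacing = config$pixel_spacing)
  jsonlite::write_json(rep[setdiff(names(rep), "per_slice")],
                       file.path(out_dir, "geometry.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  write.csv(rep$per_slice, file.path(out_dir, "geometry_per_slice.csv"),
            row.names = FALSE)
  write_manifest(file.path(out_dir, "manifest.json"), "measure",
                 inputs = labels,
                 outputs = list(report = "geometry.json"), config = config)
  invisible(rep)
}

#' Correct a mask from a recorded edit session
#'
#' @param mask_path Input mask PNG.
#' @param edits_path JSON edit session (fields: `edits`, `n_points`,
#'   `degree`, `n_samples`).
#' @param out_path Corrected mask PNG.
#' @return Invisibly, the corrected mask.
#' @export
run_correct <- function(mask_path, edits_path, out_path) {
  mask <- read_mask_png(mask_path)
  sess <- jsonlite::read_json(edits_path, simplifyVector = FALSE)
  corrected <- correct_mask(mask, edits = sess$edits %||% list(),
                            n_points = sess$n_points %||% 32L,
                            degree = sess$degree %||% 3L,
                            n_samples = sess$n_samples %||% 400L)
  write_mask_png(corrected, out_path)
  invisible(corrected)
}
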