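# Shared fixtures, all generated in code at test time.

tiny_unet <- function(depth = 2, base = 4, size = 16)
  unet_config(depth, base, c(size, size))

noiseless_spec <- function(size = 64, lumen = c(10, 10), wall = c(3, 3),
                           seed = 1L)
  phantom_spec(image_size = size, lumen_radius_range = lumen,
               wall_thickness_range = wall, axis_ratio_range = c(1, 1),
               thrombus_probability = 0, noise_sigma = 0,
               low_contrast_fraction = 0, artifact_probability = 0,
               seed = seed)

# An untrained mixture framework on small images, for algebraic and
# shape contracts that do not depend on training.
untrained_framework <- function(size = 32, depth = 2, base = 4) {
  ucfg <- unet_config(depth, base, c(size, size))
  experts <- list(
    build_expert(expert_config(1, "bce_dice", init_seed = 11,
                               partition_seed = 21, unet = ucfg)),
    build_expert(expert_config(2, "focal", init_seed = 12,
                               partition_seed = 22, unet = ucfg)),
    build_expert(expert_config(3, "bce_dice", init_seed = 13,
                               partition_seed = 23, unet = ucfg)))
  structure(list(experts = experts, router = build_router(router_config()),
                 task = "wall", configs = list()),
            class = "moe_framework")
}

# Rasterize a filled disk/ellipse directly from the inequality.
disk_mask <- function(n, cx, cy, r) moeseg:::ellipse_mask(n, cx, cy, r, r)
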