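# Seeded vascular phantom generator.
#
# Phantoms emulate contrast-enhanced axial slices of an abdominal aortic
# aneurysm: a bright elliptical lumen inside a soft-tissue wall annulus on a
# darker background, optionally with an intraluminal thrombus band of
# intermediate intensity, additive Gaussian noise, low-contrast variants and
# streak artifacts. Every sample carries paired ground-truth masks: the lumen
# ellipse and the filled outer-wall region (which contains the lumen).

#' Phantom slice specification
#'
#' Describes the distribution from which single axial phantom slices are
#' drawn. All geometric quantities are in pixels, intensities in `[0, 1]`,
#' and `pixel_spacing` in mm per pixel. The same spec with the same seed
#' always produces bit-identical samples.
#'
#' @param image_size Side length of the square image in pixels.
#' @param lumen_radius_range Range (min, max) of the lumen semi-major axis;
#'   defaults to 5--16% of the image side, so the same anatomy scales with
#'   resolution.
#' @param wall_thickness_range Range of the wall thickness in pixels; the
#'   default lower end of 1 px admits thin-wall cases.
#' @param axis_ratio_range Range of the lumen minor/major axis ratio
#'   (1 = circle).
#' @param thrombus_probability Probability that a slice carries an
#'   intraluminal thrombus band.
#' @param intensity_levels Named vector with `background`, `wall`,
#'   `thrombus` and `lumen` mean intensities; must be pairwise distinct.
#' @param noise_sigma Standard deviation of additive Gaussian noise.
#' @param low_contrast_fraction Fraction of slices rendered with the
#'   wall/background gap shrunk to at most `2 * noise_sigma`.
#' @param artifact_probability Probability of overlaying bright streak
#'   artifacts.
#' @param pixel_spacing Physical pixel size in mm/px.
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 256,
                         lumen_radius_range = round(c(0.05, 0.16) * image_size),
                         wall_thickness_range = c(1, max(2, round(0.03 * image_size))),
                         axis_ratio_range = c(0.75, 1),
                         thrombus_probability = 0.3,
                         intensity_levels = c(background = 0.15, wall = 0.45,
                                              thrombus = 0.60, lumen = 0.85),
                         noise_sigma = 0.05,
                         low_contrast_fraction = 0.1,
                         artifact_probability = 0.1,
                         pixel_spacing = 0.7,
                         seed = 1L) {
  spec <- list(image_size = as.integer(image_size),
               lumen_radius_range = as.numeric(lumen_radius_range),
               wall_thickness_range = as.numeric(wall_thickness_range),
               axis_ratio_range = as.numeric(axis_ratio_range),
               thrombus_probability = thrombus_probability,
               intensity_levels = intensity_levels,
               noise_sigma = noise_sigma,
               low_contrast_fraction = low_contrast_fraction,
               artifact_probability = artifact_probability,
               pixel_spacing = pixel_spacing,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  rng <- function(x) length(x) == 2 && all(is.finite(x)) && x[1] <= x[2] && x[1] > 0
  if (!rng(spec$lumen_radius_range))
    stop("'lumen_radius_range' must be an increasing positive pair", call. = FALSE)
  if (!rng(spec$wall_thickness_range))
    stop("'wall_thickness_range' must be an increasing positive pair", call. = FALSE)
  if (!rng(spec$axis_ratio_range) || spec$axis_ratio_range[2] > 1)
    stop("'axis_ratio_range' must lie in (0, 1]", call. = FALSE)
  lv <- spec$intensity_levels
  need <- c("background", "wall", "thrombus", "lumen")
  if (!all(need %in% names(lv)))
    stop("'intensity_levels' must name background, wall, thrombus, lumen",
         call. = FALSE)
  if (anyDuplicated(lv[need]))
    stop("'intensity_levels' must be pairwise distinct", call. = FALSE)
  # the largest admissible annulus (plus center jitter) must fit in the image
  max_outer <- spec$lumen_radius_range[2] + spec$wall_thickness_range[2]
  jitter <- 0.05 * spec$image_size
  if (max_outer + jitter + 2 > spec$image_size / 2)
    stop(paste0("wall annulus cannot fit inside the image: decrease ",
                "'lumen_radius_range'/'wall_thickness_range' or increase ",
                "'image_size'"), call. = FALSE)
  invisible(spec)
}

# Filled rotated ellipse as an integer 0/1 matrix (rows = y, cols = x).
ellipse_mask <- function(n, cx, cy, a, b, theta = 0) {
  x <- matrix(seq_len(n), n, n, byrow = TRUE) - cx
  y <- matrix(seq_len(n), n, n) - cy
  u <- x * cos(theta) + y * sin(theta)
  v <- -x * sin(theta) + y * cos(theta)
  m <- (u / a)^2 + (v / b)^2 <= 1
  storage.mode(m) <- "integer"
  m
}

draw_slice_params <- function(spec) {
  n <- spec$image_size
  a <- runif(1, spec$lumen_radius_range[1], spec$lumen_radius_range[2])
  ratio <- runif(1, spec$axis_ratio_range[1], spec$axis_ratio_range[2])
  b <- a * ratio
  t <- runif(1, spec$wall_thickness_range[1], spec$wall_thickness_range[2])
  jitter <- 0.05 * n
  cx <- n / 2 + runif(1, -jitter, jitter)
  cy <- n / 2 + runif(1, -jitter, jitter)
  theta <- runif(1, 0, pi)
  list(a = a, b = b, t = t, cx = cx, cy = cy, theta = theta,
       thrombus = runif(1) < spec$thrombus_probability,
       low_contrast = runif(1) < spec$low_contrast_fraction,
       artifact = runif(1) < spec$artifact_probability)
}

render_vessel <- function(spec, p) {
  n <- spec$image_size
  lv <- spec$intensity_levels
  lumen <- ellipse_mask(n, p$cx, p$cy, p$a, p$b, p$theta)
  wall <- ellipse_mask(n, p$cx, p$cy, p$a + p$t, p$b + p$t, p$theta)
  wall_level <- if (isTRUE(p$low_contrast))
    lv[["background"]] + min(lv[["wall"]] - lv[["background"]],
                             2 * spec$noise_sigma)
  else lv[["wall"]]
  img <- matrix(lv[["background"]], n, n)
  img[wall == 1L] <- wall_level
  if (isTRUE(p$thrombus)) {
    band <- ellipse_mask(n, p$cx, p$cy, p$a + 0.6 * p$t, p$b + 0.6 * p$t,
                         p$theta)
    ring <- band == 1L & lumen == 0L
    ang <- atan2(matrix(seq_len(n), n, n) - p$cy,
                 matrix(seq_len(n), n, n, byrow = TRUE) - p$cx)
    a0 <- runif(1, -pi, pi)
    width <- runif(1, pi / 2, 1.5 * pi)
    sector <- ((ang - a0) %% (2 * pi)) <= width
    img[ring & sector] <- lv[["thrombus"]]
  }
  img[lumen == 1L] <- lv[["lumen"]]
  if (isTRUE(p$artifact)) {
    for (k in seq_len(sample(1:3, 1))) {
      r0 <- sample(n, 1)
      slope <- runif(1, -0.3, 0.3)
      cols <- seq_len(n)
      rows <- round(r0 + slope * cols)
      ok <- rows >= 1 & rows <= n
      img[cbind(rows[ok], cols[ok])] <- pmin(img[cbind(rows[ok], cols[ok])] + 0.2, 1)
    }
  }
  list(image = img, lumen_mask = lumen, wall_mask = wall)
}

#' Generate one phantom slice
#'
#' Draws slice geometry from the spec, rasterizes the lumen and outer-wall
#' ground-truth masks, renders the intensity image and applies noise and
#' artifacts. Output is deterministic given `(spec, spec$seed)`.
#'
#' @param spec A [phantom_spec()].
#' @param seed Optional seed overriding `spec$seed` (used when drawing many
#'   slices from one spec).
#' @return A `phantom_sample`: list with `image` (numeric matrix in `[0,1]`),
#'   `lumen_mask` and `wall_mask` (0/1 integer matrices, lumen contained in
#'   wall), and `metadata` (drawn geometry, flags, analytic areas in px^2,
#'   pixel spacing).
#' @export
generate_slice <- function(spec, seed = spec$seed) {
  validate_phantom_spec(spec)
  with_seed(seed, {
    p <- draw_slice_params(spec)
    out <- render_vessel(spec, p)
    img <- out$image
    if (spec$noise_sigma > 0)
      img <- img + matrix(rnorm(length(img), 0, spec$noise_sigma),
                          nrow(img), ncol(img))
    img <- clip01(img)
    meta <- list(a = p$a, b = p$b, wall_thickness = p$t,
                 center = c(x = p$cx, y = p$cy), theta = p$theta,
                 thin_wall = p$t <= 2,
                 has_thrombus = p$thrombus, low_contrast = p$low_contrast,
                 has_artifact = p$artifact,
                 lumen_area_px = pi * p$a * p$b,
                 wall_area_px = pi * (p$a + p$t) * (p$b + p$t),
                 pixel_spacing = spec$pixel_spacing,
                 section = NA_character_, seed = seed)
    structure(list(image = img, lumen_mask = out$lumen_mask,
                   wall_mask = out$wall_mask, metadata = meta),
              class = "phantom_sample")
  })
}

#' Exam series specification
#'
#' Describes a multi-slice phantom exam running proximal to distal: a
#' normal-caliber neck, a single fusiform bulge whose lumen radius peaks at
#' `peak_slice`, and a distal bifurcation below which two common iliac
#' lumens replace the single aortic lumen. Exam slices use circular cross
#' sections so that the analytic geometry (areas, hydraulic diameters) is
#' known exactly.
#'
#' @param n_slices Number of axial slices.
#' @param slice_thickness Slice spacing in mm.
#' @param neck_slice,peak_slice,bifurcation_slice 1-based slice indices with
#'   `neck_slice < peak_slice < bifurcation_slice <= n_slices`.
#' @param neck_radius,max_radius Lumen radius (px) at the neck and at the
#'   bulge peak.
#' @param iliac_radius Lumen radius (px) of each common iliac artery.
#' @param wall_thickness Wall thickness (px), constant along the exam.
#' @param bulge_width Gaussian width (in slices) of the fusiform bulge.
#' @param phantom Base [phantom_spec()] providing image size, intensities,
#'   noise and spacing.
#' @param seed Integer seed.
#' @return An object of class `exam_spec`.
#' @export
exam_spec <- function(n_slices = 20, slice_thickness = 2,
                      neck_slice = 3, peak_slice = 10,
                      bifurcation_slice = 16,
                      neck_radius = 12, max_radius = 30, iliac_radius = 8,
                      wall_thickness = 3, bulge_width = 3,
                      phantom = phantom_spec(), seed = 1L) {
  if (!(neck_slice < peak_slice && peak_slice < bifurcation_slice))
    stop("slice ordering must satisfy neck < peak < bifurcation", call. = FALSE)
  if (bifurcation_slice > n_slices)
    stop("'bifurcation_slice' exceeds 'n_slices'", call. = FALSE)
  structure(list(n_slices = as.integer(n_slices),
                 slice_thickness = slice_thickness,
                 neck_slice = as.integer(neck_slice),
                 peak_slice = as.integer(peak_slice),
                 bifurcation_slice = as.integer(bifurcation_slice),
                 neck_radius = neck_radius, max_radius = max_radius,
                 iliac_radius = iliac_radius,
                 wall_thickness = wall_thickness,
                 bulge_width = bulge_width,
                 phantom = phantom, seed = as.integer(seed)),
            class = "exam_spec")
}

# Unimodal (Gaussian bump) lumen radius profile for aortic slices.
exam_radius_profile <- function(spec) {
  s <- seq_len(spec$n_slices)
  spec$neck_radius + (spec$max_radius - spec$neck_radius) *
    exp(-((s - spec$peak_slice) / spec$bulge_width)^2)
}

render_exam_slice <- function(pspec, centers, radius, t, seed) {
  n <- pspec$image_size
  lv <- pspec$intensity_levels
  lumen <- matrix(0L, n, n)
  wall <- matrix(0L, n, n)
  for (ct in centers) {
    lumen <- pmax(lumen, ellipse_mask(n, ct[1], ct[2], radius, radius))
    wall <- pmax(wall, ellipse_mask(n, ct[1], ct[2], radius + t, radius + t))
  }
  storage.mode(lumen) <- "integer"
  storage.mode(wall) <- "integer"
  img <- matrix(lv[["background"]], n, n)
  img[wall == 1L] <- lv[["wall"]]
  img[lumen == 1L] <- lv[["lumen"]]
  with_seed(seed, {
    if (pspec$noise_sigma > 0)
      img <- img + matrix(rnorm(length(img), 0, pspec$noise_sigma), n, n)
  })
  list(image = clip01(img), lumen_mask = lumen, wall_mask = wall)
}

#' Generate a multi-slice phantom exam
#'
#' Produces ordered slices with section labels (`neck`, `body`,
#' `max_diameter`, `iliac`) and an analytic per-slice geometry table
#' (lumen areas, outer-wall hydraulic diameter) derived from the circular
#' construction, against which mask-based measurements can be checked.
#'
#' @param spec An [exam_spec()].
#' @return An `exam_series`: list with `slices` (list of `phantom_sample`),
#'   `spec`, `pixel_spacing`, `slice_thickness` and `geometry`
#'   (data.frame: slice, section, analytic lumen/iliac areas in px^2 and
#'   outer-wall hydraulic diameter in px).
#' @export
generate_exam <- function(spec) {
  stopifnot(inherits(spec, "exam_spec"))
  pspec <- spec$phantom
  n <- pspec$image_size
  radii <- exam_radius_profile(spec)
  t <- spec$wall_thickness
  if (max(radii) + t + 2 > n / 2 ||
      3.5 * spec$iliac_radius + t + 2 > n / 2)
    stop("exam vessel does not fit inside the image: reduce 'max_radius' or increase image size",
         call. = FALSE)
  slices <- vector("list", spec$n_slices)
  geom <- data.frame(slice = seq_len(spec$n_slices),
                     section = NA_character_,
                     lumen_area_px = NA_real_, outer_dh_px = NA_real_,
                     left_iliac_area_px = NA_real_,
                     right_iliac_area_px = NA_real_)
  for (s in seq_len(spec$n_slices)) {
    bifurcated <- s >= spec$bifurcation_slice
    label <- if (s == spec$neck_slice) "neck"
      else if (s == spec$peak_slice) "max_diameter"
      else if (bifurcated) "iliac" else "body"
    seed_s <- derive_seed(spec$seed, s)
    if (bifurcated) {
      r <- spec$iliac_radius
      sep <- 2.5 * r
      centers <- list(c(n / 2 - sep, n / 2), c(n / 2 + sep, n / 2))
      out <- render_exam_slice(pspec, centers, r, t, seed_s)
      geom$lumen_area_px[s] <- 2 * pi * r^2
      geom$left_iliac_area_px[s] <- geom$right_iliac_area_px[s] <- pi * r^2
      geom$outer_dh_px[s] <- 2 * (r + t)
    } else {
      r <- radii[s]
      out <- render_exam_slice(pspec, list(c(n / 2, n / 2)), r, t, seed_s)
      geom$lumen_area_px[s] <- pi * r^2
      geom$outer_dh_px[s] <- 2 * (r + t)
    }
    geom$section[s] <- label
    meta <- list(section = label, slice = s, radius = if (bifurcated)
      spec$iliac_radius else radii[s], wall_thickness = t,
      pixel_spacing = pspec$pixel_spacing, seed = seed_s)
    slices[[s]] <- structure(list(image = out$image,
                                  lumen_mask = out$lumen_mask,
                                  wall_mask = out$wall_mask,
                                  metadata = meta),
                             class = "phantom_sample")
  }
  structure(list(slices = slices, spec = spec,
                 pixel_spacing = pspec$pixel_spacing,
                 slice_thickness = spec$slice_thickness,
                 geometry = geom),
            class = "exam_series")
}

#' Build a train/validation/test phantom dataset
#'
#' Generates `n` slices from `spec` (sample `i` uses a seed derived from
#' `spec$seed` and `i`, so the pool is independent of the partition) and
#' splits them into disjoint subsets whose membership is a pure function of
#' `partition_seed`. Distinct partition seeds give each expert its own data
#' partition over the same pool.
#'
#' @param n Number of samples.
#' @param spec A [phantom_spec()].
#' @param split Fractions (train, val, test) summing to 1.
#' @param partition_seed Integer seed controlling membership only.
#' @return List with `train`, `val`, `test` (lists of `phantom_sample`) and
#'   `indices` (the pool indices of each subset).
#' @export
make_dataset <- function(n, spec, split = c(0.8, 0.1, 0.1),
                         partition_seed = 1L) {
  if (abs(sum(split) - 1) > 1e-8)
    stop("'split' fractions must sum to 1", call. = FALSE)
  sizes <- floor(split * n)
  sizes[1] <- n - sum(sizes[-1])
  if (any(sizes < 1))
    stop(sprintf("n = %d is too small for split %s", n,
                 paste(split, collapse = "/")), call. = FALSE)
  pool <- lapply(seq_len(n), function(i)
    generate_slice(spec, seed = derive_seed(spec$seed, i)))
  idx <- with_seed(partition_seed, sample.int(n))
  tr <- idx[seq_len(sizes[1])]
  va <- idx[sizes[1] + seq_len(sizes[2])]
  te <- idx[sizes[1] + sizes[2] + seq_len(sizes[3])]
  list(train = pool[tr], val = pool[va], test = pool[te],
       indices = list(train = sort(tr), val = sort(va), test = sort(te)))
}
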