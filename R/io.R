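# On-disk artifact formats.
#
# Each phantom sample is written as a grayscale PNG (image, 8-bit, for
# inspection), 0/255 PNG masks, a JSON metadata sidecar, and a lossless
# RDS copy of the full-precision arrays. Exam series can additionally be
# exported as single-file NIfTI volumes with correct voxel spacing. Every
# pipeline command writes a JSON manifest listing its inputs, outputs and
# configuration.

#' Write a phantom sample to a directory
#'
#' @param sample A `phantom_sample`.
#' @param dir Output directory (created if missing).
#' @param name Basename for the files.
#' @return Invisibly, the paths written.
#' @export
write_sample <- function(sample, dir, name) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(image = file.path(dir, paste0(name, "_image.png")),
                lumen = file.path(dir, paste0(name, "_lumen.png")),
                wall = file.path(dir, paste0(name, "_wall.png")),
                meta = file.path(dir, paste0(name, "_meta.json")),
                rds = file.path(dir, paste0(name, ".rds")))
  png::writePNG(sample$image, paths$image)
  png::writePNG(sample$lumen_mask * 1.0, paths$lumen)
  png::writePNG(sample$wall_mask * 1.0, paths$wall)
  jsonlite::write_json(sample$metadata, paths$meta, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  saveRDS(sample, paths$rds)
  invisible(paths)
}

#' Read a phantom sample written by [write_sample()]
#'
#' @param dir Directory.
#' @param name Basename.
#' @return The `phantom_sample` (full precision, from the RDS copy).
#' @export
read_sample <- function(dir, name) {
  readRDS(file.path(dir, paste0(name, ".rds")))
}

#' Export an exam series as NIfTI volumes
#'
#' Writes three volumes (image, lumen mask, wall mask) with voxel
#' dimensions (spacing, spacing, slice thickness) in mm.
#'
#' @param exam An `exam_series`.
#' @param dir Output directory.
#' @param name Basename.
#' @return Invisibly, the paths written.
#' @export
write_exam_nifti <- function(exam, dir, name = "exam") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ns <- length(exam$slices)
  d <- dim(exam$slices[[1]]$image)
  vol <- function(field) {
    a <- array(0, c(d, ns))
    for (s in seq_len(ns)) a[, , s] <- exam$slices[[s]][[field]]
    nim <- RNifti::asNifti(a)
    RNifti::pixdim(nim) <- c(exam$pixel_spacing, exam$pixel_spacing,
                             exam$slice_thickness)
    nim
  }
  paths <- list(image = file.path(dir, paste0(name, "_image.nii.gz")),
                lumen = file.path(dir, paste0(name, "_lumen.nii.gz")),
                wall = file.path(dir, paste0(name, "_wall.nii.gz")))
  RNifti::writeNifti(vol("image"), paths$image)
  RNifti::writeNifti(vol("lumen_mask"), paths$lumen)
  RNifti::writeNifti(vol("wall_mask"), paths$wall)
  invisible(paths)
}

#' Write a binary mask as a 0/255 PNG
#' @param mask 0/1 matrix.
#' @param path Output file.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' Read a 0/255 PNG mask back to a 0/1 integer matrix
#' @param path PNG file.
#' @param threshold Values above this (in `[0,1]`) are foreground.
#' @export
read_mask_png <- function(path, threshold = 0.5) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  out <- (m > threshold) * 1L
  storage.mode(out) <- "integer"
  out
}

# Manifest written next to every pipeline artifact.
write_manifest <- function(path, command, inputs, outputs, config = NULL) {
  jsonlite::write_json(list(command = command,
                            created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                            inputs = inputs, outputs = outputs,
                            config_hash = config_hash(config)),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

config_hash <- function(config) {
  if (is.null(config)) return(NA_character_)
  raw <- serialize(config, NULL)
  # small order-sensitive rolling hash; stable across sessions
  as.character(sum(as.integer(raw) * (seq_along(raw) %% 977)) %% 2147483647)
}
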