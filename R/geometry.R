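# Clinical cross-sectional measurements: lumen areas at the aneurysm neck
# and the common iliac arteries, the maximum hydraulic diameter of the
# outer wall across an exam, and RMSE between measurement series.
#
# The hydraulic diameter of a cross-section is D_h = 4 * Area / Perimeter
# (equal to the diameter for a circle). The perimeter is measured on the
# sub-pixel iso-contour of the mask (marching squares at level 0.5) rather
# than on raw pixel edges, which would overestimate smooth boundaries;
# the area entering D_h is the shoelace area of the same contour, so both
# quantities refer to one consistent boundary.

#' Cross-sectional mask area
#'
#' Foreground pixel count times the pixel area, in cm^2.
#'
#' @param mask Binary 0/1 matrix.
#' @param spacing Pixel spacing in mm/px.
#' @return Area in cm^2 (0 for an empty mask).
#' @export
mask_area <- function(mask, spacing) {
  if (spacing <= 0) stop("'spacing' must be positive", call. = FALSE)
  sum(mask == 1) * spacing^2 / 100
}

# Sub-pixel boundary of the largest component: marching-squares iso-contour
# at level 0.5, returned as an m x 2 matrix of (x = col, y = row).
subpixel_contour <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  sizes <- table(lab[lab > 0])
  biggest <- as.integer(names(sizes)[which.max(sizes)])
  comp <- (lab == biggest) * 1
  # pad so the contour closes even when the component touches the border
  nr <- nrow(comp); nc <- ncol(comp)
  z <- matrix(0, nr + 2, nc + 2)
  z[2:(nr + 1), 2:(nc + 1)] <- comp
  cl <- grDevices::contourLines(x = 0:(nr + 1), y = 0:(nc + 1), z = z,
                                levels = 0.5)
  if (!length(cl)) stop("could not trace mask contour", call. = FALSE)
  lens <- vapply(cl, function(c) length(c$x), numeric(1))
  ct <- cl[[which.max(lens)]]
  cbind(x = ct$y, y = ct$x)   # contourLines x follows rows of z
}

# Smooth sub-pixel boundary: the marching-squares contour still zigzags at
# pixel scale, which inflates perimeter estimates of smooth anatomy; a
# periodic cubic B-spline through a subsample of the contour removes the
# zigzag while following the true boundary.
smooth_contour <- function(mask, n_ctrl = 48L, n_samples = 512L) {
  ct <- subpixel_contour(mask)
  m <- nrow(ct)
  n_ctrl <- max(8L, min(as.integer(n_ctrl), floor(m / 3)))
  if (n_ctrl < 8L) return(ct)
  keep <- unique(round(seq(1, m, length.out = n_ctrl + 1)[-(n_ctrl + 1)]))
  pts <- ct[keep, , drop = FALSE]
  d <- rowSums((pts - pts[c(2:nrow(pts), 1), , drop = FALSE])^2)
  pts <- pts[d > 0, , drop = FALSE]
  if (nrow(pts) < 5) return(ct)
  coefs <- tryCatch(periodic_interp_coefs(pts, 3L), error = function(e) NULL)
  if (is.null(coefs)) return(ct)
  eval_periodic_bspline(coefs, 3L, (seq_len(n_samples) - 1) / n_samples)
}

#' Hydraulic diameter of a mask cross-section
#'
#' `D_h = 4 A / P` of the largest connected component, with area and
#' perimeter both measured on a smooth periodic-spline fit of the
#' sub-pixel traced contour (raw pixel-edge perimeters overestimate smooth
#' boundaries), converted to cm via the pixel spacing. For a disk this
#' equals its diameter.
#'
#' @param mask Binary 0/1 matrix with non-empty foreground.
#' @param spacing Pixel spacing in mm/px.
#' @return Hydraulic diameter in cm.
#' @export
hydraulic_diameter <- function(mask, spacing) {
  if (sum(mask == 1) == 0)
    stop("hydraulic diameter is undefined for an empty mask", call. = FALSE)
  ct <- smooth_contour(mask)
  a_px <- shoelace_area(ct)
  p_px <- polyline_length(ct, closed = TRUE)
  (4 * a_px / p_px) * spacing / 10
}

#' Geometric report of an exam series
#'
#' From per-slice masks and section labels: the lumen area at the labeled
#' neck slice, the per-vessel lumen areas at the bifurcated (iliac) slices
#' (left/right assigned by centroid x-order, averaged over iliac slices),
#' and the maximum over all slices of the outer-wall hydraulic diameter.
#'
#' @param lumen_masks,wall_masks Lists of per-slice 0/1 masks, proximal to
#'   distal.
#' @param labels List with `neck_slice` (index) and `iliac_slices`
#'   (indices); e.g. from the exam generator's geometry table.
#' @param spacing Pixel spacing in mm/px.
#' @return List of class `geometry_report`: `neck_lumen_area_cm2`,
#'   `max_hydraulic_diameter_cm`, `max_diameter_slice`,
#'   `left_iliac_area_cm2`, `right_iliac_area_cm2`, `per_slice`
#'   (data.frame of per-slice lumen area and wall D_h).
#' @export
exam_geometry <- function(lumen_masks, wall_masks, labels, spacing) {
  if (is.null(labels$neck_slice) || is.null(labels$iliac_slices))
    stop("labels must supply 'neck_slice' and 'iliac_slices' indices",
         call. = FALSE)
  stopifnot(length(lumen_masks) == length(wall_masks))
  ns <- length(lumen_masks)
  per <- data.frame(slice = seq_len(ns), lumen_area_cm2 = NA_real_,
                    wall_dh_cm = NA_real_)
  for (s in seq_len(ns)) {
    per$lumen_area_cm2[s] <- mask_area(lumen_masks[[s]], spacing)
    if (sum(wall_masks[[s]] == 1) > 0)
      per$wall_dh_cm[s] <- hydraulic_diameter(wall_masks[[s]], spacing)
  }
  imax <- which.max(per$wall_dh_cm)
  left <- right <- numeric(0)
  for (s in labels$iliac_slices) {
    lab <- EBImage::bwlabel(lumen_masks[[s]])
    ncomp <- max(lab)
    if (ncomp < 2) next
    sizes <- sort(table(lab[lab > 0]), decreasing = TRUE)
    ids <- as.integer(names(sizes)[1:2])
    cx <- vapply(ids, function(id)
      mean(which(lab == id, arr.ind = TRUE)[, 2]), numeric(1))
    areas <- vapply(ids, function(id)
      sum(lab == id) * spacing^2 / 100, numeric(1))
    ord <- order(cx)
    left <- c(left, areas[ord[1]])
    right <- c(right, areas[ord[2]])
  }
  structure(list(neck_lumen_area_cm2 = per$lumen_area_cm2[labels$neck_slice],
                 max_hydraulic_diameter_cm = per$wall_dh_cm[imax],
                 max_diameter_slice = imax,
                 left_iliac_area_cm2 = if (length(left)) mean(left) else NA_real_,
                 right_iliac_area_cm2 = if (length(right)) mean(right) else NA_real_,
                 per_slice = per),
            class = "geometry_report")
}

#' Root mean square error between measurement series
#'
#' @param pred_series,ref_series Equal-length numeric vectors.
#' @return `sqrt(mean((pred - ref)^2))`.
#' @export
measurement_rmse <- function(pred_series, ref_series) {
  if (length(pred_series) != length(ref_series))
    stop("series lengths differ", call. = FALSE)
  if (!length(pred_series)) stop("series must be non-empty", call. = FALSE)
  sqrt(mean((pred_series - ref_series)^2))
}
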