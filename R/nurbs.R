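# Spline-based contour correction.
#
# A segmentation boundary is represented as an ordered set of control
# points; a closed (periodic) B-spline of degree k is fitted through them
# (C(u) = sum_i N_{i,k}(u) P'_i with the spline coefficients P'_i solved so
# the curve interpolates the control points), evaluated densely, and
# rasterized back into a binary mask. Edits are pure, recordable and
# replayable, which makes manual correction scriptable and bit-exactly
# reproducible. Rational weights are not used (all weights 1): the fitted
# curve is a non-rational periodic B-spline.

#' Ordered control points of a closed contour
#'
#' @param xy n x 2 matrix of (x = column, y = row) pixel coordinates.
#' @param closed Closed-contour flag (only closed contours are rasterized).
#' @param degree Spline degree k (default 3, cubic).
#' @return Object of class `control_point_set`.
#' @export
control_point_set <- function(xy, closed = TRUE, degree = 3L) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2) stop("'xy' must be an n x 2 matrix", call. = FALSE)
  degree <- as.integer(degree)
  if (nrow(xy) < degree + 1)
    stop(sprintf("a degree-%d spline needs at least %d control points",
                 degree, degree + 1), call. = FALSE)
  nxt <- if (closed) c(seq_len(nrow(xy))[-1], 1L) else seq_len(nrow(xy))[-1]
  cur <- if (closed) seq_len(nrow(xy)) else seq_len(nrow(xy) - 1)
  if (any(rowSums((xy[cur, , drop = FALSE] - xy[nxt, , drop = FALSE])^2) == 0))
    stop("consecutive duplicate control points are not allowed", call. = FALSE)
  structure(list(xy = unname(xy), closed = isTRUE(closed), degree = degree),
            class = "control_point_set")
}

# Uniform periodic B-spline machinery: n coefficients, degree k, knots
# t_i = i/n for i = -k .. n+k; basis functions wrap modulo n.
periodic_knots <- function(n, k) seq(-k, n + k) / n

#' Evaluate a uniform periodic B-spline
#'
#' Evaluates `C(u) = sum_i N_{i,k}(u) P_i` for coefficient rows `P_i` on
#' the uniform periodic knot vector, at parameters `u` in `[0, 1)`.
#'
#' @param coefs n x d coefficient matrix (rows wrap cyclically).
#' @param degree Spline degree k.
#' @param u Vector of parameter values in `[0, 1)`.
#' @return length(u) x d matrix of curve points.
#' @export
eval_periodic_bspline <- function(coefs, degree, u) {
  n <- nrow(coefs)
  k <- as.integer(degree)
  knots <- periodic_knots(n, k)
  B <- splines::splineDesign(knots, u %% 1, ord = k + 1)
  # wrap the k extra basis columns onto the first k coefficients
  Bw <- B[, seq_len(n), drop = FALSE]
  if (k > 0)
    Bw[, seq_len(k)] <- Bw[, seq_len(k), drop = FALSE] +
      B[, n + seq_len(k), drop = FALSE]
  Bw %*% coefs
}

# Solve for periodic spline coefficients so the curve interpolates the
# data points at uniform parameter sites u_j = (j-1)/n.
periodic_interp_coefs <- function(points, degree) {
  n <- nrow(points)
  u <- (seq_len(n) - 1) / n
  k <- as.integer(degree)
  knots <- periodic_knots(n, k)
  B <- splines::splineDesign(knots, u, ord = k + 1)
  Bw <- B[, seq_len(n), drop = FALSE]
  if (k > 0)
    Bw[, seq_len(k)] <- Bw[, seq_len(k), drop = FALSE] +
      B[, n + seq_len(k), drop = FALSE]
  solve(Bw, points)
}

#' Fit a closed periodic B-spline through control points
#'
#' With zero smoothing (the only mode implemented) the curve passes
#' through every control point; the spline coefficients are obtained by
#' solving the periodic interpolation system on the uniform knot vector.
#'
#' @param cps A [control_point_set()] (must be closed).
#' @param n_samples Number of dense samples along `u` in `[0, 1)`
#'   (minimum 32).
#' @return Object of class `contour_polyline`: `points` (n_samples x 2),
#'   `closed`, `n_samples`, plus the fitted `coefs` and `degree`.
#' @export
fit_closed_spline <- function(cps, n_samples = 200L) {
  stopifnot(inherits(cps, "control_point_set"))
  if (!cps$closed) stop("contour must be closed", call. = FALSE)
  if (n_samples < 32) stop("'n_samples' must be >= 32", call. = FALSE)
  coefs <- periodic_interp_coefs(cps$xy, cps$degree)
  u <- (seq_len(n_samples) - 1) / n_samples
  pts <- eval_periodic_bspline(coefs, cps$degree, u)
  structure(list(points = pts, closed = TRUE,
                 n_samples = as.integer(n_samples),
                 coefs = coefs, degree = cps$degree),
            class = "contour_polyline")
}

#' Apply a recorded edit list to a control point set
#'
#' Pure function: the input set is never mutated, so an edit session can
#' be replayed to a bit-identical result. Supported edits: `move`
#' (`list(op = "move", index, xy)`), `insert` (`list(op = "insert", index,
#' xy)`, the new point taking position `index`), and `delete`
#' (`list(op = "delete", index)`).
#'
#' @param cps A [control_point_set()].
#' @param edits List of edit records.
#' @return The edited `control_point_set`.
#' @export
edit_control_points <- function(cps, edits) {
  stopifnot(inherits(cps, "control_point_set"))
  xy <- cps$xy
  for (e in edits) {
    op <- e$op %||% stop("edit without 'op'", call. = FALSE)
    if (op == "move") {
      if (e$index < 1 || e$index > nrow(xy))
        stop("move index out of range", call. = FALSE)
      xy[e$index, ] <- as.numeric(e$xy)
    } else if (op == "insert") {
      if (e$index < 1 || e$index > nrow(xy) + 1)
        stop("insert index out of range", call. = FALSE)
      xy <- rbind(xy[seq_len(e$index - 1), , drop = FALSE],
                  as.numeric(e$xy),
                  xy[seq(e$index, length.out = nrow(xy) - e$index + 1), ,
                     drop = FALSE])
    } else if (op == "delete") {
      if (e$index < 1 || e$index > nrow(xy))
        stop("delete index out of range", call. = FALSE)
      if (nrow(xy) - 1 < cps$degree + 1)
        stop(sprintf("cannot delete below %d control points (degree %d)",
                     cps$degree + 1, cps$degree), call. = FALSE)
      xy <- xy[-e$index, , drop = FALSE]
    } else stop(sprintf("unknown edit op '%s'", op), call. = FALSE)
  }
  control_point_set(xy, closed = cps$closed, degree = cps$degree)
}

#' Extract an ordered boundary contour from a mask
#'
#' Traces the sub-pixel boundary (marching squares at level 0.5) of the
#' largest connected foreground component and subsamples it to `n_points`
#' control points. When several components are present the largest is used
#' and a message reports the count.
#'
#' @param mask Binary 0/1 matrix with at least one foreground component.
#' @param n_points Number of control points to keep.
#' @param degree Spline degree recorded on the returned set.
#' @return A [control_point_set()] in (x = column, y = row) coordinates.
#' @export
extract_contour <- function(mask, n_points = 32L, degree = 3L) {
  if (sum(mask == 1) == 0) stop("empty mask", call. = FALSE)
  lab <- EBImage::bwlabel(mask)
  sizes <- table(lab[lab > 0])
  if (length(sizes) > 1)
    message(sprintf("mask has %d components; tracing the largest",
                    length(sizes)))
  if (max(sizes) < 4)
    stop("component too small to form a closed contour", call. = FALSE)
  pts <- subpixel_contour(mask)
  if (nrow(pts) < degree + 1)
    stop("component too small to form a closed contour", call. = FALSE)
  keep <- unique(round(seq(1, nrow(pts), length.out = n_points + 1)[-(n_points + 1)]))
  pts <- pts[keep, , drop = FALSE]
  # drop any consecutive duplicates introduced by subsampling
  d <- rowSums((pts - pts[c(2:nrow(pts), 1), ])^2)
  pts <- pts[d > 0, , drop = FALSE]
  control_point_set(pts, closed = TRUE, degree = degree)
}

# Locate a self-intersection of a closed polyline; returns NULL or the
# approximate (x, y) crossing location.
polyline_self_intersection <- function(pts) {
  n <- nrow(pts)
  a <- pts
  b <- pts[c(2:n, 1), , drop = FALSE]
  cross <- function(ox, oy, px, py, qx, qy) (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]   # skip segments adjacent through the wrap
    if (!length(js)) next
    d1 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[js, 1], a[js, 2])
    d2 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[js, 1], b[js, 2])
    d3 <- cross(a[js, 1], a[js, 2], b[js, 1], b[js, 2], a[i, 1], a[i, 2])
    d4 <- cross(a[js, 1], a[js, 2], b[js, 1], b[js, 2], b[i, 1], b[i, 2])
    hit <- which(d1 * d2 < 0 & d3 * d4 < 0)
    if (length(hit)) {
      j <- js[hit[1]]
      return(c(x = mean(c(a[i, 1], b[i, 1], a[j, 1], b[j, 1])),
               y = mean(c(a[i, 2], b[i, 2], a[j, 2], b[j, 2]))))
    }
  }
  NULL
}

#' Rasterize a closed contour into a binary mask
#'
#' Fills the polygon bounded by the sampled curve (even-odd scanline
#' rule). Curves extending beyond the image are clipped with a warning;
#' self-intersecting curves are rejected with the crossing location.
#'
#' @param curve A `contour_polyline` from [fit_closed_spline()] (or any
#'   list with closed `points`).
#' @param image_size Integer (rows, cols) of the output mask.
#' @return 0/1 integer matrix.
#' @export
rasterize_contour <- function(curve, image_size) {
  pts <- curve$points
  if (!isTRUE(curve$closed)) stop("contour must be closed", call. = FALSE)
  si <- polyline_self_intersection(pts)
  if (!is.null(si))
    stop(sprintf("self-intersecting contour near (x = %.1f, y = %.1f)",
                 si["x"], si["y"]), call. = FALSE)
  image_size <- rep(as.integer(image_size), length.out = 2)
  if (min(pts) < 0.5 || max(pts[, 1]) > image_size[2] + 0.5 ||
      max(pts[, 2]) > image_size[1] + 0.5)
    warning("contour extends beyond image bounds; clipping", call. = FALSE)
  fill_polygon_cpp(pts[, 1], pts[, 2], image_size[1], image_size[2])
}

#' Correct a mask by replaying a recorded edit session
#'
#' mask -> traced contour -> edited control points -> periodic spline ->
#' rasterized mask. Identical sessions replay to bit-identical masks.
#'
#' @param mask Binary 0/1 matrix.
#' @param edits Edit list as in [edit_control_points()].
#' @param n_points Control points extracted from the mask boundary.
#' @param degree Spline degree.
#' @param n_samples Dense samples of the corrected curve.
#' @return The corrected 0/1 mask.
#' @export
correct_mask <- function(mask, edits = list(), n_points = 32L, degree = 3L,
                         n_samples = 400L) {
  cps <- extract_contour(mask, n_points, degree)
  cps <- edit_control_points(cps, edits)
  curve <- fit_closed_spline(cps, n_samples)
  rasterize_contour(curve, dim(mask))
}

# Shoelace area of a closed polygon (absolute value).
shoelace_area <- function(pts) {
  n <- nrow(pts)
  j <- c(2:n, 1)
  abs(sum(pts[, 1] * pts[j, 2] - pts[j, 1] * pts[, 2])) / 2
}

polyline_length <- function(pts, closed = TRUE) {
  n <- nrow(pts)
  j <- if (closed) c(2:n, 1) else 2:n
  i <- if (closed) 1:n else 1:(n - 1)
  sum(sqrt(rowSums((pts[j, , drop = FALSE] - pts[i, , drop = FALSE])^2)))
}
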