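# Periodic B-spline contour correction.

test_that("cubic spline through circle points stays on the circle", {
  th <- seq(0, 2 * pi, length.out = 9)[1:8]
  cps <- control_point_set(cbind(40 + 20 * cos(th), 40 + 20 * sin(th)))
  cv <- fit_closed_spline(cps, 256)
  rad <- sqrt(rowSums(sweep(cv$points, 2, c(40, 40))^2))
  expect_lt(max(abs(rad - 20)), 0.5)
  # zero smoothing: the curve interpolates every control point
  at_cp <- eval_periodic_bspline(cv$coefs, 3, (0:7) / 8)
  expect_equal(at_cp, cps$xy, tolerance = 1e-8)
})

test_that("degree-1 spline of a square reproduces its perimeter exactly", {
  sq <- control_point_set(cbind(c(10, 30, 30, 10), c(10, 10, 30, 30)),
                          degree = 1)
  cv <- fit_closed_spline(sq, 64)
  expect_equal(moeseg:::polyline_length(cv$points), 80, tolerance = 1e-9)
  # every sampled point lies on the square's boundary
  on_edge <- apply(cv$points, 1, function(p)
    (abs(p[1] - 10) < 1e-9 || abs(p[1] - 30) < 1e-9) ||
      (abs(p[2] - 10) < 1e-9 || abs(p[2] - 30) < 1e-9))
  expect_true(all(on_edge))
})

test_that("spline evaluation matches the de Boor recursion oracle", {
  set.seed(1)
  for (k in c(2, 3)) {
    n <- 9
    coefs <- cbind(rnorm(n, 50, 10), rnorm(n, 50, 10))
    u <- runif(100)
    expect_equal(eval_periodic_bspline(coefs, k, u),
                 deboor_periodic_eval(coefs, k, u), tolerance = 1e-8)
  }
})

test_that("control point validation rejects degenerate inputs", {
  expect_error(control_point_set(cbind(c(1, 1, 5, 6, 3), c(2, 2, 6, 7, 1))),
               "duplicate")
  expect_error(control_point_set(cbind(c(1, 2, 3), c(1, 2, 3)), degree = 3),
               "at least 4")
  expect_error(fit_closed_spline(control_point_set(cbind(c(0, 5, 5, 0),
                                                         c(0, 0, 5, 5))),
                                 n_samples = 8), ">= 32")
})

test_that("edits are pure, ordered and reversible", {
  xy <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  cps <- control_point_set(xy, degree = 1)
  expect_identical(edit_control_points(cps, list())$xy, cps$xy)
  moved <- edit_control_points(cps, list(list(op = "move", index = 2,
                                              xy = c(15, 0))))
  expect_identical(moved$xy[2, ], c(15, 0))
  expect_identical(moved$xy[-2, ], cps$xy[-2, ])
  expect_identical(cps$xy, xy)   # input untouched
  round_trip <- edit_control_points(cps, list(
    list(op = "insert", index = 3, xy = c(12, 5)),
    list(op = "delete", index = 3)))
  expect_identical(round_trip$xy, cps$xy)
  cps3 <- control_point_set(xy, degree = 3)   # already at the 4-point minimum
  expect_error(edit_control_points(cps3, list(list(op = "delete", index = 1))),
               "cannot delete")
  expect_error(edit_control_points(cps, list(list(op = "move", index = 9,
                                                  xy = c(0, 0)))),
               "out of range")
})

test_that("extracted contour of a disk lies on its boundary circle", {
  m <- disk_mask(64, 32, 33, 15)
  cps <- extract_contour(m, n_points = 32)
  ctr <- colMeans(cps$xy)
  rad <- sqrt(rowSums(sweep(cps$xy, 2, ctr)^2))
  expect_true(all(abs(rad - 15) < 1))
  expect_error(extract_contour(matrix(0L, 8, 8)), "empty")
  single <- matrix(0L, 8, 8); single[4, 4] <- 1L
  expect_error(extract_contour(single), "too small")
  two <- disk_mask(64, 20, 20, 10) + disk_mask(64, 48, 48, 4)
  expect_message(cps2 <- extract_contour(two), "2 components")
  ctr2 <- colMeans(cps2$xy)
  expect_lt(max(abs(ctr2 - 20)), 1.5)  # traced the larger disk
})

test_that("rasterization recovers analytic areas and rejects bad curves", {
  th <- seq(0, 2 * pi, length.out = 9)[1:8]
  circ <- fit_closed_spline(control_point_set(cbind(50 + 20 * cos(th),
                                                    50 + 20 * sin(th))), 256)
  msk <- rasterize_contour(circ, c(100, 100))
  expect_lt(abs(sum(msk) / (pi * 400) - 1), 0.03)
  # shoelace area of the sampled polygon agrees with the filled pixel count
  expect_lt(abs(sum(msk) / moeseg:::shoelace_area(circ$points) - 1), 0.03)
  # self-intersecting figure-eight is rejected with a location
  fig8 <- list(points = cbind(c(10, 30, 10, 30), c(10, 30, 30, 10)),
               closed = TRUE)
  expect_error(rasterize_contour(fig8, c(40, 40)), "self-intersecting")
  # out-of-bounds curve clips with a warning
  out <- fit_closed_spline(control_point_set(cbind(30 + 20 * cos(th),
                                                   8 + 20 * sin(th))), 128)
  expect_warning(clipped <- rasterize_contour(out, c(32, 64)), "clip")
  expect_true(all(dim(clipped) == c(32, 64)))
})

test_that("mask -> contour -> spline -> mask round trip is faithful", {
  shapes <- list(disk_mask(100, 50.3, 48.7, 22),
                 moeseg:::ellipse_mask(100, 50, 50, 28, 18, 0.5),
                 moeseg:::ellipse_mask(80, 42, 39, 20, 16, 1.1))
  for (m in shapes)
    expect_gte(dice(correct_mask(m), m), 0.98)
})

test_that("a recorded edit session replays to a bit-identical mask", {
  m <- disk_mask(80, 40, 40, 18)
  # push one traced control point radially outward (stays simple)
  p4 <- extract_contour(m)$xy[4, ]
  edits <- list(list(op = "move", index = 4,
                     xy = c(40, 40) + 1.3 * (p4 - c(40, 40))))
  out1 <- correct_mask(m, edits)
  out2 <- correct_mask(m, edits)
  expect_identical(out1, out2)
  expect_true(any(out1 != correct_mask(m)))   # the edits changed the mask
})
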