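# Phantom generator: construction invariants, determinism, analytic areas.

test_that("noiseless slice has exactly the three constructed intensities", {
  s <- generate_slice(noiseless_spec(seed = 3))
  expect_identical(length(unique(as.vector(s$image))), 3L)
  expect_setequal(unique(as.vector(s$image)), c(0.15, 0.45, 0.85))
})

test_that("identical spec and seed reproduce bit-identical samples", {
  sp <- phantom_spec(image_size = 64, seed = 9,
                     lumen_radius_range = c(8, 14),
                     wall_thickness_range = c(1, 4))
  expect_identical(generate_slice(sp), generate_slice(sp))
})

test_that("rasterized mask areas match analytic ellipse areas", {
  s <- generate_slice(noiseless_spec(size = 64, lumen = c(10, 10),
                                     wall = c(3, 3), seed = 5))
  expect_lt(abs(sum(s$lumen_mask) / (pi * 100) - 1), 0.05)
  expect_lt(abs(sum(s$wall_mask) / (pi * 169) - 1), 0.05)
})

test_that("lumen is contained in the wall region and masks are non-empty", {
  sp <- phantom_spec(image_size = 64, lumen_radius_range = c(6, 14),
                     wall_thickness_range = c(1, 5), noise_sigma = 0.08,
                     seed = 1)
  for (k in 1:20) {
    s <- generate_slice(sp, seed = k)
    expect_true(all(s$lumen_mask <= s$wall_mask))
    expect_identical(s$lumen_mask & s$wall_mask, s$lumen_mask == 1L)
    expect_gt(sum(s$lumen_mask), 0)
    expect_gt(sum(s$wall_mask), 0)
  }
})

test_that("annulus that cannot fit raises a parameter error", {
  expect_error(phantom_spec(image_size = 32, lumen_radius_range = c(10, 14),
                            wall_thickness_range = c(2, 6)),
               "lumen_radius_range")
})

test_that("exam slices below the bifurcation carry two disjoint lumens", {
  es <- exam_spec(n_slices = 20, neck_slice = 3, peak_slice = 8,
                  bifurcation_slice = 16,
                  phantom = phantom_spec(image_size = 96, noise_sigma = 0,
                                         lumen_radius_range = c(8, 20),
                                         wall_thickness_range = c(1, 4),
                                         seed = 2),
                  max_radius = 22, seed = 2)
  ex <- generate_exam(es)
  ncomp <- vapply(ex$slices, function(s)
    max(EBImage::bwlabel(s$lumen_mask)), numeric(1))
  expect_true(all(ncomp[16:20] == 2))
  expect_true(all(ncomp[1:15] == 1))
  expect_identical(ex$geometry$section[3], "neck")
  expect_identical(ex$geometry$section[8], "max_diameter")
  expect_true(all(ex$geometry$section[16:20] == "iliac"))
})

test_that("lumen area across aortic slices peaks at the bulge slice", {
  es <- exam_spec(n_slices = 16, neck_slice = 2, peak_slice = 8,
                  bifurcation_slice = 13,
                  phantom = phantom_spec(image_size = 96, noise_sigma = 0,
                                         lumen_radius_range = c(8, 20),
                                         wall_thickness_range = c(1, 4),
                                         seed = 4),
                  max_radius = 22, seed = 4)
  ex <- generate_exam(es)
  areas <- vapply(ex$slices[1:12], function(s) sum(s$lumen_mask), numeric(1))
  expect_identical(which.max(areas), 8L)
  # radius profile is unimodal
  r <- moeseg:::exam_radius_profile(es)
  expect_identical(which.max(r), 8L)
  expect_true(all(diff(r[1:8]) >= 0) && all(diff(r[8:16]) <= 0))
})

test_that("seeded exam reproduces its pixel-count geometry bit-exactly", {
  es <- exam_spec(phantom = phantom_spec(image_size = 96, seed = 6,
                                         lumen_radius_range = c(8, 20),
                                         wall_thickness_range = c(1, 4)),
                  max_radius = 22, seed = 6)
  ex1 <- generate_exam(es)
  ex2 <- generate_exam(es)
  tab1 <- vapply(ex1$slices, function(s) sum(s$lumen_mask), numeric(1))
  tab2 <- vapply(ex2$slices, function(s) sum(s$lumen_mask), numeric(1))
  expect_identical(tab1, tab2)
  expect_identical(ex1$geometry, ex2$geometry)
  # analytic areas are close to pixel counts on non-bifurcated slices
  aortic <- which(ex1$geometry$section != "iliac")
  rel <- abs(tab1[aortic] / ex1$geometry$lumen_area_px[aortic] - 1)
  expect_true(all(rel < 0.05))
})

test_that("exam spec validates slice ordering", {
  expect_error(exam_spec(neck_slice = 10, peak_slice = 5,
                         bifurcation_slice = 15), "ordering")
  expect_error(exam_spec(n_slices = 10, neck_slice = 2, peak_slice = 5,
                         bifurcation_slice = 12), "n_slices")
})

test_that("dataset splits are sized, disjoint and partition-seeded", {
  sp <- phantom_spec(image_size = 32, lumen_radius_range = c(4, 8),
                     wall_thickness_range = c(1, 3), seed = 1)
  ds <- make_dataset(100, sp, c(0.8, 0.1, 0.1), partition_seed = 5)
  expect_identical(lengths(ds[c("train", "val", "test")]),
                   c(train = 80L, val = 10L, test = 10L))
  idx <- ds$indices
  expect_length(intersect(idx$train, idx$val), 0)
  expect_length(intersect(idx$train, idx$test), 0)
  expect_length(intersect(idx$val, idx$test), 0)
  ds2 <- make_dataset(100, sp, c(0.8, 0.1, 0.1), partition_seed = 5)
  expect_identical(ds$indices, ds2$indices)
  ds3 <- make_dataset(100, sp, c(0.8, 0.1, 0.1), partition_seed = 6)
  expect_false(identical(ds$indices$train, ds3$indices$train))
  expect_identical(lengths(ds3$indices), lengths(ds$indices))
  expect_error(make_dataset(5, sp, c(0.9, 0.05, 0.05)), "too small")
  expect_error(make_dataset(10, sp, c(0.5, 0.2, 0.2)), "sum to 1")
})
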