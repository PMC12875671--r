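# Overlap and boundary metrics against brute-force oracles.

test_that("confusion counts match the per-pixel loop oracle", {
  p <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_identical(confusion(p, p)[c("FP", "FN")], list(FP = 0L, FN = 0L))
  ones <- matrix(1, 3, 3); zeros <- matrix(0, 3, 3)
  cc <- confusion(ones, zeros)
  expect_identical(cc, list(TP = 0L, FP = 9L, TN = 0L, FN = 0L))
  set.seed(1)
  for (rep in 1:10) {
    a <- matrix(rbinom(36, 1, 0.5), 6, 6)
    b <- matrix(rbinom(36, 1, 0.5), 6, 6)
    cc <- confusion(a, b)
    oc <- confusion_loop_oracle(as.vector(a), as.vector(b))
    expect_identical(cc[order(names(cc))], oc[order(names(oc))])
    expect_identical(sum(unlist(cc)), 36L)
  }
  expect_error(confusion(matrix(2, 2, 2), matrix(0, 2, 2)), "binary")
})

test_that("iou and dice match set-count oracles and their identity", {
  a <- matrix(0L, 4, 4); a[1:2, 1:2] <- 1L          # |A| = 4
  b <- matrix(0L, 4, 4); b[2:3, 1:2] <- 1L          # |B| = 4, overlap 2
  expect_equal(iou(a, b), 2 / 6, tolerance = 1e-12)
  expect_equal(dice(a, b), 0.5, tolerance = 1e-12)
  expect_identical(iou(a, a), 1)
  expect_identical(dice(a, a), 1)
  disjoint <- matrix(0L, 4, 4); disjoint[4, 4] <- 1L
  expect_identical(iou(a, disjoint), 0)
  empty <- matrix(0L, 4, 4)
  expect_identical(iou(empty, empty), 1)   # vacuous agreement convention
  expect_identical(dice(empty, empty), 1)
  set.seed(2)
  for (rep in 1:1000) {
    A <- random_mask(sample(4:10, 1), sample(4:10, 1))
    B <- random_mask(nrow(A), ncol(A))
    i <- iou(A, B)
    expect_equal(i, set_count_iou_oracle(A, B), tolerance = 1e-12)
    expect_equal(dice(A, B), 2 * i / (1 + i), tolerance = 1e-12)
    expect_equal(iou(B, A), i, tolerance = 1e-12)      # symmetry
  }
})

test_that("hd95 handles exact cases and matches the brute-force oracle", {
  m <- disk_mask(20, 10, 10, 6)
  expect_identical(hd95(m, m, 1), 0)
  # two single-pixel boundaries 3-4-5 apart
  p <- matrix(0L, 8, 8); p[1, 1] <- 1L
  q <- matrix(0L, 8, 8); q[4, 5] <- 1L
  expect_identical(hd95(p, q, 1), 5)
  expect_identical(hd95(p, q, 0.7), 3.5)
  set.seed(3)
  for (rep in 1:25) {
    A <- random_mask(sample(8:32, 1), sample(8:32, 1), n_blobs = 3)
    B <- random_mask(nrow(A), ncol(A), n_blobs = 3)
    expect_equal(hd95(A, B, 1), hd95_bruteforce_oracle(A, B), tolerance = 1e-9)
    expect_equal(hd95(A, B, 1), hd95(B, A, 1), tolerance = 1e-12)  # symmetric
  }
  expect_error(hd95(matrix(0L, 4, 4), m[1:4, 1:4]), "empty")
})

test_that("hd95 grows monotonically as a mask translates away", {
  A <- disk_mask(40, 12, 12, 6)
  ds <- vapply(c(0, 4, 8, 14), function(s)
    hd95(A, disk_mask(40, 12 + s, 12, 6), 1), numeric(1))
  expect_true(all(diff(ds) >= 0))
})

test_that("the metric report covers every confusion-derived quantity", {
  truth <- disk_mask(24, 12, 12, 7)
  rep0 <- seg_report(truth, truth, spacing = 0.7)
  for (mname in c("accuracy", "sensitivity", "specificity", "precision",
                  "f_measure", "mcc", "dsc", "iou"))
    expect_equal(rep0[[mname]], 1, tolerance = 1e-12, label = mname)
  expect_identical(rep0$hd95_mm, 0)
  # hand-counted confusion: TP=2, FP=1, FN=1, TN=12 on a 4x4 grid
  truth2 <- matrix(0L, 4, 4); truth2[c(1, 2, 3)] <- 1L
  pred2 <- matrix(0L, 4, 4); pred2[c(1, 2, 4)] <- 1L
  r2 <- seg_report(pred2, truth2, spacing = 1)
  expect_equal(r2$precision, 2 / 3, tolerance = 1e-12)
  expect_equal(r2$sensitivity, 2 / 3, tolerance = 1e-12)
  expect_equal(r2$f_measure, 2 / 3, tolerance = 1e-12)
  expect_equal(r2$dsc, r2$f_measure, tolerance = 1e-12)
  # inverted prediction of a balanced mask anti-correlates perfectly
  bal <- matrix(rep(c(0L, 1L), 8), 4, 4)
  inv <- 1L - bal
  expect_equal(suppressWarnings(seg_report(inv, bal, 1)$mcc), -1,
               tolerance = 1e-12)
  # zero denominators warn and report NaN, never silently 0
  w <- capture_warnings(rnan <- seg_report(matrix(0L, 4, 4), truth2, 1))
  expect_true(any(grepl("precision", w)))
  expect_true(is.nan(rnan$precision))
  expect_true(is.nan(rnan$f_measure))
})

test_that("mask set evaluation aggregates per-slice reports", {
  truths <- list(disk_mask(24, 12, 12, 7), disk_mask(24, 10, 14, 5))
  preds <- list(disk_mask(24, 12, 12, 7), disk_mask(24, 11, 14, 5))
  ev <- evaluate_masks(preds, truths, spacing = 1)
  expect_identical(nrow(ev$per_slice), 2L)
  expect_true(all(c("dsc", "iou", "hd95_mm") %in% ev$summary$metric))
  expect_equal(ev$per_slice$dsc[1], 1, tolerance = 1e-12)
  expect_lt(ev$per_slice$dsc[2], 1)
})
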