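# Evaluation metrics: counts, ratio metrics, HD95.

test_that("confusion counts match an exhaustive voxel loop", {
  p <- array(0L, c(10, 10, 1)); t <- p
  p[1:3, 1, 1] <- 1L; t[1:3, 1, 1] <- 1L
  cc <- confusion(p, t)
  expect_identical(unlist(cc), c(TP = 3L, FP = 0L, FN = 0L, TN = 97L))
  t2 <- array(0L, dim(p)); t2[5:9, 2, 1] <- 1L
  cc2 <- confusion(array(0L, dim(p)), t2)
  expect_identical(c(cc2$TP, cc2$FN), c(0L, 5L))

  set.seed(61)
  a <- array(rbinom(50, 1, 0.4), c(5, 5, 2))
  b <- array(rbinom(50, 1, 0.4), c(5, 5, 2))
  want <- c(TP = 0L, FP = 0L, FN = 0L, TN = 0L)
  for (i in 1:5) for (j in 1:5) for (k in 1:2) {
    key <- if (a[i, j, k] && b[i, j, k]) "TP"
           else if (a[i, j, k]) "FP"
           else if (b[i, j, k]) "FN" else "TN"
    want[key] <- want[key] + 1L
  }
  expect_identical(unlist(confusion(a, b)), want)
  expect_error(confusion(a, array(0, c(5, 5, 3))), "identical shapes")
})

test_that("ratio metrics reproduce the worked confusion example", {
  r <- overlap_metrics(list(TP = 2, FP = 1, FN = 1, TN = 4))
  expect_equal(r$dice, 2 / 3, tolerance = 1e-12)
  expect_equal(r$ji, 1 / 2, tolerance = 1e-12)
  expect_equal(r$sen, 2 / 3, tolerance = 1e-12)
  expect_equal(r$spe, 4 / 5, tolerance = 1e-12)
  expect_equal(r$bacc, 11 / 15, tolerance = 1e-12)
  expect_equal(r$acc, 6 / 8, tolerance = 1e-12)
  expect_equal(r$vs, 1, tolerance = 1e-12)
  expect_equal(r$mcc, 7 / 15, tolerance = 1e-12)
  expect_equal(r$kappa, 7 / 15, tolerance = 1e-12)
})

test_that("perfect, inverted and degenerate cases follow the conventions", {
  m <- array(rbinom(27, 1, 0.5), c(3, 3, 3))
  r <- overlap_metrics(confusion(m, m))
  expect_equal(unlist(r[c("dice", "ji", "sen", "spe", "acc", "vs")]),
               rep(1, 6), ignore_attr = TRUE)
  expect_equal(c(r$kappa, r$mcc), c(1, 1))
  # complement on a 2-voxel grid
  r2 <- overlap_metrics(list(TP = 0, FP = 1, FN = 1, TN = 0))
  expect_equal(r2$dice, 0)
  expect_equal(r2$mcc, -1)
  # both empty / one empty
  r3 <- overlap_metrics(list(TP = 0, FP = 0, FN = 0, TN = 8))
  expect_equal(c(r3$dice, r3$ji, r3$kappa, r3$mcc), c(1, 1, 0, 0))
  r4 <- overlap_metrics(list(TP = 0, FP = 0, FN = 3, TN = 5))
  expect_equal(r4$dice, 0)
  # whole-volume voxel counts: marginal products exceed integer range
  r5 <- overlap_metrics(list(TP = 100L, FP = 50L, FN = 150L, TN = 48000L))
  expect_true(is.finite(r5$kappa) && is.finite(r5$mcc))
})

test_that("Dice and Jaccard satisfy their algebraic identity; Dice is monotone", {
  set.seed(62)
  for (i in 1:50) {
    cc <- as.list(setNames(sample(0:20, 4, replace = TRUE),
                           c("TP", "FP", "FN", "TN")))
    r <- overlap_metrics(cc)
    expect_equal(r$dice, 2 * r$ji / (1 + r$ji), tolerance = 1e-12)
    if (cc$FN > 0) {
      up <- overlap_metrics(list(TP = cc$TP + 1, FP = cc$FP,
                                 FN = cc$FN - 1, TN = cc$TN))
      expect_gte(up$dice, r$dice)
    }
  }
})

test_that("HD95 handles identical, offset and empty masks with mm spacing", {
  m <- array(0L, c(12, 12, 3)); m[4:6, 4:6, 2] <- 1L
  expect_equal(hd95(m, m, c(1, 1, 1)), 0)
  # two single-voxel masks 3 voxels apart along x at the study spacing
  a <- array(0L, c(10, 10, 1)); b <- a
  a[3, 5, 1] <- 1L; b[6, 5, 1] <- 1L
  expect_equal(hd95(a, b, c(0.47, 0.47, 6.5)), 3 * 0.47, tolerance = 1e-12)
  # conventions
  z <- array(0L, c(10, 10, 1))
  expect_equal(hd95(z, z, c(1, 1, 1)), 0)
  expect_true(is.na(hd95(a, z, c(1, 1, 1))))
})

test_that("HD95 agrees with the all-pairs brute-force oracle and is symmetric", {
  set.seed(63)
  sp <- c(0.8, 1.1, 2.5)
  for (i in 1:10) {
    a <- array(0L, c(7, 7, 4)); b <- array(0L, c(7, 7, 4))
    a[sample(length(a), 12)] <- 1L
    b[sample(length(b), 12)] <- 1L
    got <- hd95(a, b, sp)
    expect_equal(got, brute_hd95(a, b, sp), tolerance = 1e-9)
    expect_equal(got, hd95(b, a, sp), tolerance = 1e-12)
  }
})

test_that("directory evaluation writes the ten-metric CSV", {
  td <- withr::local_tempdir()
  dir.create(file.path(td, "pred")); dir.create(file.path(td, "truth"))
  set.seed(64)
  for (i in 1:2) {
    m <- array(0L, c(10, 10, 3)); m[3:5, 3:5, 2] <- 1L
    p <- m; if (i == 2) p[5, 5, 2] <- 0L
    write_volume(msm_volume(m, c(0.5, 0.5, 2)),
                 file.path(td, "truth", sprintf("s%d.nii.gz", i)))
    write_volume(msm_volume(p, c(0.5, 0.5, 2)),
                 file.path(td, "pred", sprintf("s%d.nii.gz", i)))
  }
  csv <- file.path(td, "metrics.csv")
  res <- evaluate_directories(file.path(td, "pred"), file.path(td, "truth"),
                              out = csv)
  expect_true(file.exists(csv))
  got <- read.csv(csv)
  expect_identical(names(got),
                   c("subject", "dice", "sen", "spe", "bacc", "acc", "ji",
                     "kappa", "vs", "mcc", "hd95"))
  expect_equal(got$dice[1], 1)
  expect_lt(got$dice[2], 1)
  expect_false(is.null(attr(res, "summary")))
})
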