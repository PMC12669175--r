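# Geometric standardization and multi-scale intensity harmonization.

test_that("gaussian smoothing preserves identity, constants and mass", {
  v <- msm_volume(array(rnorm(6 * 5 * 4), c(6, 5, 4)), c(1, 1, 2))
  expect_identical(gaussian_smooth(v, 0)$data, v$data)

  cv <- msm_volume(array(3.7, c(5, 5, 3)))
  expect_equal(gaussian_smooth(cv, 2)$data, cv$data, tolerance = 1e-12)

  # interior-supported signal keeps its total intensity (unit-mass kernel)
  set.seed(1)
  arr <- array(0, c(20, 20, 20))
  arr[9:12, 9:12, 9:12] <- abs(rnorm(64)) + 1
  sm <- gaussian_smooth(msm_volume(arr), 1)$data
  expect_equal(sum(sm), sum(arr), tolerance = 1e-8)

  expect_error(gaussian_smooth(v, -1), "non-negative")
})

test_that("gaussian smoothing matches direct-summation convolution", {
  arr <- array(0, c(9, 9, 9))
  arr[5, 5, 5] <- 1
  got <- gaussian_smooth(msm_volume(arr), 2)$data
  want <- brute_gaussian_3d(arr, 2)
  expect_lt(max(abs(got - want)), 1e-10)
})

test_that("harmonization against itself at the identity scale is the identity", {
  set.seed(2)
  v <- msm_volume(array(rnorm(8 * 8 * 4, mean = 10, sd = 3), c(8, 8, 4)))
  spec <- harmonization_spec(v, sigmas = 0)
  expect_equal(harmonize(v, spec)$data, v$data, tolerance = 1e-12)
})

test_that("single-scale harmonization z-scores a toy volume", {
  toy <- msm_volume(array(1:16, c(4, 4, 1)))
  ref_stats <- matrix(c(0, 1), nrow = 1,
                      dimnames = list(NULL, c("mean", "sd")))
  spec <- structure(list(sigmas = 0, reference_stats = ref_stats,
                         stats_scope = "grid"),
                    class = "harmonization_spec")
  got <- harmonize(toy, spec)$data
  # hand evaluation: mean 8.5, sd sqrt(sum((x-8.5)^2)/15)
  want <- (1:16 - 8.5) / sqrt(sum((1:16 - 8.5)^2) / 15)
  expect_equal(as.vector(got), want, tolerance = 1e-12)
})

test_that("harmonized image is the sum of per-scale moment-matched images", {
  set.seed(3)
  v <- msm_volume(array(rnorm(12 * 12 * 6, 5, 2), c(12, 12, 6)))
  sig <- c(0, 2, 4, 6)
  spec <- harmonization_spec(v, sigmas = sig)
  got <- harmonize(v, spec)$data
  want <- Reduce(`+`, lapply(sig, function(s) gaussian_smooth(v, s)$data))
  expect_equal(got, want, tolerance = 1e-10)

  # per-scale moment matching against an independent reference
  set.seed(4)
  ref <- msm_volume(array(rnorm(12 * 12 * 6, 50, 9), c(12, 12, 6)))
  spec2 <- harmonization_spec(ref, sigmas = sig)
  for (k in seq_along(sig)) {
    single <- structure(list(sigmas = sig[k],
                             reference_stats = spec2$reference_stats[k, ,
                                                                     drop = FALSE],
                             stats_scope = "grid"),
                        class = "harmonization_spec")
    single$sigmas[1] <- sig[k]
    out <- harmonize(v, single)$data
    expect_equal(mean(out), unname(spec2$reference_stats[k, "mean"]),
                 tolerance = 1e-6)
    expect_equal(sd(as.vector(out)), unname(spec2$reference_stats[k, "sd"]),
                 tolerance = 1e-6)
  }
})

test_that("constant input at a scale with nonzero reference sd is rejected", {
  ref <- msm_volume(array(rnorm(5 * 5 * 2), c(5, 5, 2)))
  spec <- harmonization_spec(ref, sigmas = 0)
  flat <- msm_volume(array(2, c(5, 5, 2)))
  expect_error(harmonize(flat, spec), "zero intensity variance")
})

test_that("resampling honors the shape formula and label alphabets", {
  set.seed(5)
  v <- msm_volume(array(rnorm(10 * 10 * 10), c(10, 10, 10)), c(1, 1, 1))
  idg <- geometry_spec(target_spacing = c(1, 1, 1))
  expect_identical(resample(v, idg)$data, v$data)

  half <- resample(v, geometry_spec(target_spacing = c(2, 2, 2)))
  expect_identical(dim(half$data), c(5L, 5L, 5L))
  expect_equal(half$spacing, c(2, 2, 2))

  lab <- msm_volume(array(rbinom(8 * 8 * 2, 1, 0.3), c(8, 8, 2)), c(1, 1, 5))
  rs <- resample(lab, geometry_spec(target_spacing = c(0.8, 0.7, 2.5)),
                 method = "nearest")
  expect_true(all(rs$data %in% c(0, 1)))
})

test_that("smooth volumes survive a half-spacing round trip", {
  g <- seq(-1, 1, length.out = 24)
  arr <- outer(outer(cos(pi * g / 2), cos(pi * g / 2)), cos(pi * seq(-1, 1, length.out = 8) / 2))
  v <- msm_volume(arr, c(1, 1, 3))
  down <- resample(v, geometry_spec(target_spacing = c(0.5, 0.5, 1.5)))
  back <- resample(down, geometry_spec(target_spacing = c(1, 1, 3)))
  expect_identical(dim(back$data), dim(arr))
  rms <- sqrt(mean((back$data - arr)^2)) / sqrt(mean(arr^2))
  expect_lt(rms, 0.02)
})

test_that("crop_and_pad centres content with the documented tie-break", {
  # all-zero volume: whole grid is the box, padded with pad_value
  z <- msm_volume(array(0, c(4, 4, 2)))
  out <- crop_and_pad(z, geometry_spec(pad_shape = c(6, 6, 2), pad_value = 0))
  expect_identical(dim(out$data), c(6L, 6L, 2L))
  expect_true(all(out$data == 0))

  # single nonzero voxel at 0-based (3,4,0): lands at 0-based (2,2,0)
  v <- msm_volume(array(0, c(10, 10, 1)))
  v$data[4, 5, 1] <- 7
  out <- crop_and_pad(v, geometry_spec(pad_shape = c(6, 6, 1)))
  expect_identical(which(out$data != 0, arr.ind = TRUE)[1, ],
                   c(dim1 = 3L, dim2 = 3L, dim3 = 1L))

  # already matching with nonzero border: untouched
  set.seed(6)
  w <- msm_volume(array(abs(rnorm(5 * 5 * 3)) + 1, c(5, 5, 3)))
  out <- crop_and_pad(w, geometry_spec(pad_shape = c(5, 5, 3)))
  expect_identical(out$data, w$data)

  # content larger than the target is an error
  expect_error(crop_and_pad(w, geometry_spec(pad_shape = c(4, 4, 3))),
               "exceeds")

  # -1 keeps the axis length
  out <- crop_and_pad(w, geometry_spec(pad_shape = c(7, 7, -1)))
  expect_identical(dim(out$data), c(7L, 7L, 3L))
})
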