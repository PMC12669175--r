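# Multi-scan serialization: parity partition, canonical traversal orders,
# the scan/merge bijection and its inverse.

test_that("the plan realizes the canonical partition arithmetic", {
  plan <- build_scan_plan(4, c(8, 8, 8))
  expect_identical(nrow(plan$element_index), 64L)
  expect_length(plan$subvolumes, 8L)
  expect_true(all(vapply(plan$subvolumes,
                         function(s) length(s$order) == 8L, logical(1))))
  # parity classes and traversal orders match the hard-coded table
  for (s in 1:8) {
    expect_identical(plan$subvolumes[[s]]$parity, TABLE2_PARITY[s, ])
    expect_identical(as.numeric(plan$subvolumes[[s]]$order8),
                     TABLE2_ORDERS[[s]])
    expect_identical(sort(plan$subvolumes[[s]]$order), 1:8)
  }
  # SV1 samples the odd classes {1,3} on every axis
  expect_equal(plan$subvolumes[[1]]$classes,
               list(c(1, 3), c(1, 3), c(1, 3)), ignore_attr = TRUE)

  # N = 2: one element per sub-volume, orders degenerate
  p2 <- build_scan_plan(2, c(4, 4, 4))
  expect_identical(nrow(p2$element_index), 8L)
  expect_true(all(vapply(p2$subvolumes,
                         function(s) identical(s$order, 1L), logical(1))))

  expect_error(build_scan_plan(3, c(8, 8, 8)), "even")
  expect_error(build_scan_plan(4, c(2, 8, 8)), ">= n_segments")
})

test_that("scanning a 4x4x4 grid of unique values follows the element order", {
  plan <- build_scan_plan(4, c(4, 4, 4))
  g <- array(0:63, c(1, 4, 4, 4))
  seqs <- multi_scan(g, plan)
  # SV1 starts with basic element (x1,y1,z1) then (x3,y1,z1):
  # voxels (0-based x-fastest) 0 and 2
  expect_equal(seqs[[1]][1, 1:2], c(0, 2))
  # SV2 is the complementary x/even parity scanned in reverse: its sequence
  # is the reverse of the forward x-fastest enumeration of that parity set
  fwd_sv2 <- as.vector(vapply(c(1, 3), function(z) vapply(c(1, 3), function(y)
    g[1, c(2, 4), y, z], numeric(2)), matrix(0, 2, 2)))
  expect_equal(seqs[[2]][1, ], rev(fwd_sv2))
  # jointly a permutation of all voxel values
  expect_equal(sort(unlist(lapply(seqs, as.vector))), 0:63, ignore_attr = TRUE)
  # the 8 sequences start in 8 distinct basic elements (complementary
  # coverage of the parity octants)
  starts <- vapply(seqs, function(s) s[1, 1], numeric(1))
  blocks <- vapply(starts, function(v) {
    i <- v %% 4; j <- (v %/% 4) %% 4; k <- v %/% 16
    paste(i, j, k)
  }, character(1))
  expect_length(unique(blocks), 8L)
})

test_that("the eight sub-volumes partition every divisible grid", {
  for (N in c(2L, 4L)) {
    for (shape in list(c(4L, 4L, 4L), c(8L, 4L, 4L), c(8L, 8L, 8L))) {
      if (any(shape %% N != 0L)) next
      plan <- build_scan_plan(N, shape)
      idx <- msmseg:::scan_indices(plan, shape)
      all_idx <- unlist(idx)
      expect_identical(sort(all_idx), seq_len(prod(shape)))  # disjoint + complete
      expect_true(all(lengths(idx) == prod(shape) / 8))
    }
  }
})

test_that("multi_merge inverts multi_scan exactly", {
  set.seed(21)
  plan4 <- build_scan_plan(4, c(8, 8, 8))
  for (i in 1:20) {
    shape <- 4L * sample(1:4, 3, replace = TRUE)
    C <- sample(1:8, 1)
    plan <- build_scan_plan(4, shape)
    g <- array(rnorm(C * prod(shape)), c(C, shape))
    seqs <- multi_scan(g, plan)
    expect_identical(multi_merge(seqs, plan, shape), g)
  }
  # all-zero grid
  z <- array(0, c(3, 8, 8, 8))
  expect_identical(multi_merge(multi_scan(z, plan4), plan4, c(8, 8, 8)), z)
  # perturbing one sequence entry changes exactly one voxel
  g <- array(rnorm(2 * 512), c(2, 8, 8, 8))
  seqs <- multi_scan(g, plan4)
  seqs[[3]][1, 17] <- seqs[[3]][1, 17] + 1
  diff <- multi_merge(seqs, plan4, c(8, 8, 8)) - g
  expect_identical(sum(diff != 0), 1L)

  expect_error(multi_scan(array(0, c(1, 6, 8, 8)), plan4), "divisible")
  bad <- multi_scan(array(0, c(1, 8, 8, 8)), plan4)
  bad[[1]] <- bad[[1]][, 1:10, drop = FALSE]
  expect_error(multi_merge(bad, plan4, c(8, 8, 8)), "inconsistent")
})
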