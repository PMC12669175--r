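# State-space engine: bilinear discretization, recurrence, convolutional
# form and the selective (input-dependent) scan.

test_that("bilinear discretization matches hand-derived values", {
  # A = 0: Abar = I, Bbar = delta * B
  p <- ssm_params(matrix(0, 3, 3), B = c(1, -2, 0.5), C = rep(1, 3),
                  delta = 0.3)
  d <- discretize(p)
  expect_equal(d$A_bar, diag(3))
  expect_equal(d$B_bar, 0.3 * c(1, -2, 0.5))

  # scalar system by scalar arithmetic
  d2 <- discretize(ssm_params(-1, 1, 1, 0.1))
  expect_equal(d2$A_bar, 0.95 / 1.05, tolerance = 1e-14)
  expect_equal(d2$B_bar, 0.1 / 1.05, tolerance = 1e-14)

  # delta -> 0: Abar -> I and Bbar -> 0 monotonically
  set.seed(11)
  A <- -diag(runif(4, 0.5, 2))
  B <- rnorm(4)
  errs <- sapply(c(1e-1, 1e-2, 1e-3), function(dt) {
    dd <- discretize(ssm_params(A, B, rnorm(4), dt))
    c(norm(dd$A_bar - diag(4), "F"), sqrt(sum(dd$B_bar^2)))
  })
  expect_true(all(diff(errs[1, ]) < 0) && all(diff(errs[2, ]) < 0))

  # singular (I - delta/2 A) is rejected
  expect_error(discretize(ssm_params(A = 2 / 0.5, B = 1, C = 1, delta = 0.5)),
               "singular")
})

test_that("the recurrence is zero for zero input or zero input map", {
  d <- discretize(random_stable_ssm())
  expect_equal(ssm_recurrence(d, numeric(10)), numeric(10))
  p <- random_stable_ssm()
  p$B[] <- 0
  expect_equal(ssm_recurrence(discretize(p), rnorm(12)), numeric(12))
})

test_that("recurrence and convolutional form agree on random stable systems", {
  set.seed(12)
  for (i in 1:20) {
    d <- discretize(random_stable_ssm(n_state = sample(1:6, 1)))
    L <- sample(1:64, 1)
    x <- rnorm(L)
    expect_lt(max(abs(ssm_recurrence(d, x) - ssm_convolution(d, x))), 1e-8)
  }
})

test_that("impulse response is the kernel; the Abar = 1 system accumulates", {
  set.seed(13)
  d <- discretize(random_stable_ssm())
  x <- c(1, numeric(11))
  expect_equal(ssm_convolution(d, x), ssm_kernel(d, 12), tolerance = 1e-12)

  # A = 0, B = C = delta = 1: kernel is all ones, output is a running sum
  dsum <- discretize(ssm_params(0, 1, 1, 1))
  expect_equal(ssm_kernel(dsum, 5), rep(1, 5))
  x <- rnorm(8)
  expect_equal(ssm_convolution(dsum, x), cumsum(x), tolerance = 1e-12)
})

test_that("the LTI path is causal and linear", {
  set.seed(14)
  d <- discretize(random_stable_ssm())
  x <- rnorm(20)
  y <- ssm_recurrence(d, x)
  xp <- x
  xp[12] <- xp[12] + 5
  yp <- ssm_recurrence(d, xp)
  expect_equal(yp[1:11], y[1:11], tolerance = 1e-12)   # causality
  expect_false(isTRUE(all.equal(yp[12:20], y[12:20])))

  x2 <- rnorm(20)
  lhs <- ssm_recurrence(d, 2 * x - 3 * x2)
  rhs <- 2 * ssm_recurrence(d, x) - 3 * ssm_recurrence(d, x2)
  expect_lt(max(abs(lhs - rhs)), 1e-8)                  # linearity
})

test_that("scalar stable kernels decay monotonically", {
  set.seed(15)
  for (i in 1:10) {
    d <- discretize(ssm_params(-runif(1, 0.2, 3), rnorm(1), rnorm(1),
                               runif(1, 0.01, 0.2)))
    K <- abs(ssm_kernel(d, 32))
    expect_true(all(diff(K[-1]) <= 1e-12))
  }
})

test_that("selective scan matches the naive per-token re-discretization loop", {
  set.seed(16)
  for (i in 1:10) {
    d <- sample(1:4, 1); N <- sample(1:5, 1); L <- sample(1:12, 1)
    sp <- selective_params(d, N,
                           Wc = matrix(rnorm(N * d, sd = 1 / sqrt(d)), N, d),
                           wd = rnorm(d, sd = 0.3), a = -runif(N, 0.2, 3))
    X <- matrix(rnorm(d * L), d, L)
    expect_lt(max(abs(selective_scan(sp, X) - naive_selective_scan(sp, X))),
              1e-6)
  }
})

test_that("selectivity collapses to time-invariance on constant tokens", {
  set.seed(17)
  d <- 3; N <- 4; L <- 10
  sp <- selective_params(d, N,
                         Wc = matrix(rnorm(N * d, sd = 1 / sqrt(d)), N, d),
                         wd = rnorm(d, sd = 0.2), a = -runif(N, 0.2, 2))
  x0 <- rnorm(d)
  X <- matrix(rep(x0, L), d, L)
  Y <- selective_scan(sp, X)
  B0 <- drop(sp$Wb %*% x0)
  C0 <- drop(sp$Wc %*% x0)
  dt0 <- log1p(exp(sum(sp$wd * x0) + sp$bd))
  dlti <- discretize(ssm_params(sp$a, B0, C0, dt0))
  for (c in 1:d) {
    want <- ssm_recurrence(dlti, rep(x0[c], L))
    expect_equal(Y[c, ], want, tolerance = 1e-10)
  }
})

test_that("a length-1 sequence is a single discretized step", {
  set.seed(18)
  d <- 2; N <- 3
  sp <- selective_params(d, N,
                         Wc = matrix(rnorm(N * d), N, d), a = -c(1, 2, 3))
  x <- matrix(rnorm(d), d, 1)
  got <- selective_scan(sp, x)
  B0 <- drop(sp$Wb %*% x[, 1]); C0 <- drop(sp$Wc %*% x[, 1])
  dt0 <- log1p(exp(sum(sp$wd * x[, 1]) + sp$bd))
  dsc <- discretize(ssm_params(sp$a, B0, C0, dt0))
  want <- outer(x[, 1], dsc$B_bar) %*% C0
  expect_equal(got[, 1], drop(want), tolerance = 1e-12)
})

test_that("non-finite projections report the offending token", {
  sp <- selective_params(2, 2)
  X <- matrix(c(0, 0, Inf, 1), 2, 2)
  expect_error(selective_scan(sp, X), "token 2")
})
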