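# Encoder-decoder assembly, shape contracts, backprop correctness.

test_that("conv blocks honor the stride/shape contract", {
  set.seed(41)
  g <- array(rnorm(2 * 12 * 12 * 4), c(2, 12, 12, 4))
  out <- conv_block(g, kernel = c(3, 3, 1), stride = c(1, 1, 1),
                    out_channels = 5)
  expect_identical(dim(out), c(5L, 12L, 12L, 4L))
  g2 <- array(rnorm(2 * 32 * 32 * 8), c(2, 32, 32, 8))
  out2 <- conv_block(g2, kernel = c(3, 3, 1), stride = c(2, 2, 1),
                     out_channels = 4)
  expect_identical(dim(out2), c(4L, 16L, 16L, 8L))
  # ceil division on odd extents
  g3 <- array(rnorm(2 * 9 * 9 * 5), c(2, 9, 9, 5))
  expect_identical(dim(conv_block(g3, stride = c(2, 2, 2)))[2:4],
                   c(5L, 5L, 3L))
})

test_that("instance normalization maps constant channels to the affine offset", {
  x <- array(2, c(1, 4, 4, 2))
  n <- msmseg:::instance_norm_fwd(x, gamma = 1.5, beta = 0.25)
  expect_equal(as.vector(n$y), rep(0.25, 32), tolerance = 1e-8)
})

test_that("the default specification builds the reference channel chain", {
  spec <- network_spec()
  expect_identical(spec$channels, c(32L, 64L, 128L, 256L, 320L, 320L))
  expect_identical(spec$in_channels, 2L)
  expect_identical(c(spec$d_state, spec$d_conv, spec$er), c(16L, 4L, 2L))
  net <- build_network(spec, seed = 42)
  # encoder pointwise convs realize 2->32->64->128->256->320->320
  chain <- vapply(net$params$enc, function(l) dim(l$c1$pw$W), integer(2))
  expect_identical(chain[1, ], c(32L, 64L, 128L, 256L, 320L, 320L))
  expect_identical(chain[2, ], c(2L, 32L, 64L, 128L, 256L, 320L))
  # decoder transposed convs realize 320->320, 320->320, 320->256, ...
  dchain <- vapply(net$params$dec, function(l) dim(l$up$W)[1:2], integer(2))
  expect_identical(dchain[1, ], c(32L, 64L, 128L, 256L, 320L, 320L))
  expect_identical(dchain[2, ], c(64L, 128L, 256L, 320L, 320L, 320L))
  expect_true(param_finite_check <- msmseg:::param_finite(net$params))
})

test_that("a forward pass restores resolution and stacks auxiliary heads", {
  spec <- network_spec()
  net <- build_network(spec, seed = 43)
  x <- array(rnorm(2 * 32 * 32 * 8), c(2, 32, 32, 8))
  out <- network_forward(net, x)
  expect_identical(dim(out$logits), c(2L, 32L, 32L, 8L))
  expect_length(out$aux, 5L)
  # deeper auxiliaries live at the encoder-mirror resolutions
  aux_dims <- lapply(out$aux, function(a) dim(a)[2:4])
  expect_equal(aux_dims[[2]], c(16, 16, 8), ignore_attr = TRUE)
  expect_equal(aux_dims[[3]], c(8, 8, 8), ignore_attr = TRUE)
  expect_equal(aux_dims[[5]], c(2, 2, 2), ignore_attr = TRUE)
  expect_true(all(is.finite(out$logits)))
})

test_that("prediction yields labels of the input shape and forced argmax", {
  spec <- tiny_net_spec()
  net <- build_network(spec, seed = 44)
  ph <- generate_phantom(tiny_phantom_spec(seed = 7))
  lab <- predict(net, ph$image)
  expect_identical(dim(lab$data), dim(ph$image$data))
  expect_true(all(lab$data %in% c(0L, 1L)))
  # head forced to class 0: all-background labels
  net$params$heads$primary$W[] <- 0
  net$params$heads$primary$b <- c(10, -10)
  expect_true(all(predict(net, ph$image)$data == 0L))
  # input smaller than the total down-sampling factor is refused
  tiny <- msm_volume(array(rnorm(2 * 2 * 2), c(2, 2, 2)))
  expect_error(predict(net, tiny), "smaller than")
})

test_that("the conv-only ablation is equivariant to full-period shifts", {
  spec <- tiny_net_spec()
  net <- build_network(spec, seed = 45)
  # support sits deep in the interior so the receptive field (and hence the
  # instance-norm statistics) never touches the zero-padding frontier
  x <- array(0, c(1, 48, 48, 4))
  set.seed(45)
  x[1, 21:24, 21:24, 2:3] <- rnorm(32)
  xs <- array(0, dim(x))
  xs[1, 21:24 + 4, 21:24 + 4, 2:3] <- x[1, 21:24, 21:24, 2:3]
  y <- network_forward(net, x, use_msms = FALSE)$logits
  ys <- network_forward(net, xs, use_msms = FALSE)$logits
  expect_equal(ys[, 25:28, 25:28, 2:3], y[, 21:24, 21:24, 2:3],
               tolerance = 1e-8)
})

test_that("analytic gradients of the full network match finite differences", {
  set.seed(46)
  spec <- network_spec(channels = c(3L, 4L),
                       strides = list(c(2L, 2L, 1L), c(2L, 2L, 1L)),
                       kernels = list(c(3L, 3L, 1L), c(3L, 3L, 1L)),
                       in_channels = 1L, num_classes = 2L, d_state = 2L,
                       n_segments = 2L)
  net <- build_network(spec, seed = 46)
  # perturb the zero-initialized leaves so every path carries signal
  net$params <- msmseg:::param_map(function(v)
    if (all(v == 0)) v + rnorm(length(v), sd = 0.2) else v, net$params)
  x <- array(rnorm(8 * 8 * 4), c(1, 8, 8, 4))
  mask <- array(rbinom(8 * 8 * 4, 1, 0.2), c(8, 8, 4))
  fw <- network_forward(net, x, want_cache = TRUE)
  lg <- msmseg:::total_loss_grad(list(logits = fw$logits, aux = fw$aux), mask)
  bw <- msmseg:::network_backward(net, fw$cache, lg$dlogits, lg$daux)
  theta <- msmseg:::param_unlist(net$params)
  gan <- msmseg:::param_unlist(bw$grads)
  fval <- function(th) {
    nn <- net
    nn$params <- msmseg:::param_relist(net$params, th)
    f <- network_forward(nn, x)
    total_loss(list(logits = f$logits, aux = f$aux), mask)
  }
  idx <- sample(length(theta), 40)
  eps <- 1e-5
  num <- vapply(idx, function(i) {
    t1 <- theta; t2 <- theta
    t1[i] <- t1[i] + eps; t2[i] <- t2[i] - eps
    (fval(t1) - fval(t2)) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(num - gan[idx]) / pmax(abs(num), 1e-6)), 1e-3)
})
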