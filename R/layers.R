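# Differentiable layer primitives.
#
# Feature grids are (C, nx, ny, nz) arrays (channel-first, x-fastest in
# memory after the channel axis).  Every layer exposes a `*_fwd` returning
# list(y, cache) and a `*_bwd(dy, cache)` returning list(dx, grads); batches
# are handled one volume at a time with gradient accumulation, so no batch
# axis appears here.  Convolutions are implemented as sums over kernel
# offsets of shifted copies (zero padding), which keeps everything
# vectorized; depthwise kernels must have odd extents, transposed
# convolutions are restricted to kernel == stride (non-overlapping phases).

shift4 <- function(x, o) {
  d <- dim(x)
  y <- array(0, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    n <- d[ax + 1L]; oo <- o[ax]
    s_from <- max(1L, 1L + oo); s_to <- min(n, n + oo)
    if (s_from > s_to) return(y)
    src[[ax]] <- s_from:s_to
    dst[[ax]] <- (s_from - oo):(s_to - oo)
  }
  y[, dst[[1]], dst[[2]], dst[[3]]] <-
    x[, src[[1]], src[[2]], src[[3]], drop = FALSE]
  y
}

kernel_offsets <- function(k) {
  r <- (k - 1L) %/% 2L
  as.matrix(expand.grid(x = seq_len(k[1]) - r[1] - 1L,
                        y = seq_len(k[2]) - r[2] - 1L,
                        z = seq_len(k[3]) - r[3] - 1L,
                        KEEP.OUT.ATTRS = FALSE))
}

conv_dw_fwd <- function(x, W, stride = c(1L, 1L, 1L)) {
  d <- dim(x); k <- dim(W)[2:4]
  if (any(k %% 2L == 0L)) stop("depthwise kernel extents must be odd")
  y <- conv_dw_full_cpp(x, d, W, k)
  sub <- lapply(1:3, function(ax) seq(1L, d[ax + 1L], by = stride[ax]))
  ys <- y[, sub[[1]], sub[[2]], sub[[3]], drop = FALSE]
  list(y = ys, cache = list(x = x, W = W, full_dim = d, k = k, sub = sub))
}

conv_dw_bwd <- function(dy, cache) {
  d <- cache$full_dim
  dyf <- array(0, d)
  dyf[, cache$sub[[1]], cache$sub[[2]], cache$sub[[3]]] <- dy
  r <- conv_dw_bwd_cpp(cache$x, d, cache$W, cache$k, dyf)
  list(dx = r$dx, grads = list(W = r$dW))
}

conv_pw_fwd <- function(x, W, b) {
  d <- dim(x)
  xm <- matrix(x, nrow = d[1])
  ym <- W %*% xm + b
  list(y = array(ym, dim = c(nrow(W), d[2:4])),
       cache = list(xm = xm, W = W, d = d))
}

conv_pw_bwd <- function(dy, cache) {
  dym <- matrix(dy, nrow = nrow(cache$W))
  list(dx = array(crossprod(cache$W, dym), dim = cache$d),
       grads = list(W = tcrossprod(dym, cache$xm), b = rowSums(dym)))
}

instance_norm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  xm <- matrix(x, nrow = d[1])
  mu <- rowMeans(xm)
  xc <- xm - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  ym <- gamma * xhat + beta
  list(y = array(ym, dim = d),
       cache = list(xhat = xhat, inv = inv, gamma = gamma, d = d))
}

instance_norm_bwd <- function(dy, cache) {
  d <- cache$d
  dym <- matrix(dy, nrow = d[1])
  xhat <- cache$xhat
  V <- ncol(dym)
  dxhat <- dym * cache$gamma
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * cache$inv
  list(dx = array(dx, dim = d),
       grads = list(gamma = rowSums(dym * xhat), beta = rowSums(dym)))
}

# layer normalization across channels at each voxel, per-channel affine
layer_norm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  xm <- matrix(x, nrow = d[1])
  mu <- colMeans(xm)
  xc <- sweep(xm, 2L, mu)
  v <- colMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, inv, "*")
  ym <- gamma * xhat + beta
  list(y = array(ym, dim = d),
       cache = list(xhat = xhat, inv = inv, gamma = gamma, d = d))
}

layer_norm_bwd <- function(dy, cache) {
  d <- cache$d
  C <- d[1]
  dym <- matrix(dy, nrow = C)
  xhat <- cache$xhat
  dxhat <- dym * cache$gamma
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dx <- sweep(dxhat - outer(rep(1, C), m1) - sweep(xhat, 2L, m2, "*"),
              2L, cache$inv, "*")
  list(dx = array(dx, dim = d),
       grads = list(gamma = rowSums(dym * xhat), beta = rowSums(dym)))
}

leaky_relu_fwd <- function(x, slope = 0.01) {
  s <- (x > 0) * (1 - slope) + slope
  list(y = x * s, cache = list(s = s))
}

leaky_relu_bwd <- function(dy, cache) {
  list(dx = dy * cache$s, grads = NULL)
}

# transposed convolution with kernel == stride: every output voxel receives
# exactly one input contribution (per-phase channel mixes)
conv_transpose_fwd <- function(x, W, b, stride) {
  d <- dim(x)
  cin <- d[1]; cout <- dim(W)[1]
  xm <- matrix(x, nrow = cin)
  out_dim <- c(cout, d[2:4] * stride)
  y <- array(0, out_dim)
  for (px in seq_len(stride[1])) for (py in seq_len(stride[2]))
    for (pz in seq_len(stride[3])) {
      Wp <- matrix(W[, , px, py, pz], nrow = cout, ncol = cin)
      y[, seq(px, by = stride[1], length.out = d[2]),
           seq(py, by = stride[2], length.out = d[3]),
           seq(pz, by = stride[3], length.out = d[4])] <-
        array(Wp %*% xm + b, dim = c(cout, d[2:4]))
    }
  list(y = y, cache = list(xm = xm, W = W, stride = stride, d = d,
                           cout = cout))
}

conv_transpose_bwd <- function(dy, cache) {
  d <- cache$d; stride <- cache$stride; cout <- cache$cout
  dW <- array(0, dim(cache$W))
  db <- numeric(cout)
  dxm <- matrix(0, d[1], ncol(cache$xm))
  for (px in seq_len(stride[1])) for (py in seq_len(stride[2]))
    for (pz in seq_len(stride[3])) {
      dyp <- matrix(dy[, seq(px, by = stride[1], length.out = d[2]),
                       seq(py, by = stride[2], length.out = d[3]),
                       seq(pz, by = stride[3], length.out = d[4])],
                    nrow = cout)
      Wp <- matrix(cache$W[, , px, py, pz], nrow = cout, ncol = d[1])
      dW[, , px, py, pz] <- tcrossprod(dyp, cache$xm)
      db <- db + rowSums(dyp)
      dxm <- dxm + crossprod(Wp, dyp)
    }
  list(dx = array(dxm, dim = d), grads = list(W = dW, b = db))
}

pad_spatial_fwd <- function(x, target) {
  d <- dim(x)
  if (all(d[2:4] == target)) return(list(y = x, cache = list(d = d, noop = TRUE)))
  y <- array(0, c(d[1], target))
  y[, seq_len(d[2]), seq_len(d[3]), seq_len(d[4])] <- x
  list(y = y, cache = list(d = d, noop = FALSE))
}

pad_spatial_bwd <- function(dy, cache) {
  if (cache$noop) return(dy)
  d <- cache$d
  dy[, seq_len(d[2]), seq_len(d[3]), seq_len(d[4]), drop = FALSE]
}

crop_spatial <- function(x, target) {
  x[, seq_len(target[1]), seq_len(target[2]), seq_len(target[3]), drop = FALSE]
}

# --- selective scan as a layer ---------------------------------------------

selscan_layer_fwd <- function(X, p, want_cache = TRUE) {
  r <- selscan_forward_cpp(X, p$Wb, p$Wc, p$wd, p$bd, p$a, want_cache)
  list(y = r$Y, cache = if (want_cache) c(r["H"], r["B"], r["C"],
                                          r["delta"], r["u"],
                                          list(X = X, p = p)) else NULL)
}

selscan_layer_bwd <- function(dY, cache) {
  p <- cache$p
  g <- selscan_backward_cpp(cache$X, p$Wb, p$Wc, p$wd, p$a,
                            cache$H, cache$B, cache$C,
                            cache$delta, cache$u, dY)
  list(dx = g$dX,
       grads = list(Wb = g$dWb, Wc = g$dWc, wd = g$dwd, bd = g$dbd,
                    a = g$da))
}
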