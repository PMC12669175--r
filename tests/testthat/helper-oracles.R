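# Independent reference implementations used as oracles.  These are written
# as plain loops against the documented definitions and never call the code
# paths they check.

# reflect an out-of-range 1-based index back into [1, n] (edge repeated)
reflect_idx <- function(i, n) {
  j <- (i - 1) %% (2 * n)
  j <- ifelse(j < 0, j + 2 * n, j)
  ifelse(j < n, j + 1, 2 * n - j)
}

# direct-summation 3-D Gaussian convolution with reflecting boundaries
brute_gaussian_3d <- function(arr, sigma) {
  r <- max(1L, ceiling(4 * sigma))
  w1 <- exp(-((-r:r)^2) / (2 * sigma^2))
  w1 <- w1 / sum(w1)
  d <- dim(arr)
  out <- array(0, d)
  taps <- -r:r
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    acc <- 0
    for (tz in seq_along(taps)) {
      kz <- reflect_idx(k + taps[tz], d[3])
      sl <- arr[reflect_idx(i + taps, d[1]), reflect_idx(j + taps, d[2]), kz]
      acc <- acc + w1[tz] * sum(outer(w1, w1) * sl)
    }
    out[i, j, k] <- acc
  }
  out
}

# naive per-token re-discretization selective scan (builds and applies the
# bilinear step anew at every token through the package's LTI primitives)
naive_selective_scan <- function(sp, X) {
  d <- nrow(X); L <- ncol(X); N <- length(sp$a)
  H <- matrix(0, d, N)
  Y <- matrix(0, d, L)
  for (n in seq_len(L)) {
    x <- X[, n]
    B <- drop(sp$Wb %*% x)
    C <- drop(sp$Wc %*% x)
    dt <- log1p(exp(sum(sp$wd * x) + sp$bd))
    dsc <- discretize(ssm_params(sp$a, B, C, dt))
    H <- sweep(H, 2, dsc$A_bar, "*") + outer(x, dsc$B_bar)
    Y[, n] <- drop(H %*% C)
  }
  Y
}

# random stable diagonal LTI system
random_stable_ssm <- function(n_state = 4L, delta = NULL) {
  if (is.null(delta)) delta <- runif(1, 0.05, 0.5)
  ssm_params(A = -runif(n_state, 0.2, 3), B = rnorm(n_state),
             C = rnorm(n_state), delta = delta)
}

# hard-coded canonical sub-volume traversal orders (octant numbering is
# x-fastest, 1-based)
TABLE2_ORDERS <- list(
  c(1, 2, 3, 4, 5, 6, 7, 8),
  c(8, 7, 6, 5, 4, 3, 2, 1),
  c(1, 3, 2, 4, 5, 7, 6, 8),
  c(8, 6, 7, 5, 4, 2, 3, 1),
  c(1, 5, 2, 6, 3, 7, 4, 8),
  c(8, 4, 7, 3, 6, 2, 5, 1),
  c(1, 2, 4, 3, 5, 6, 8, 7),
  c(7, 8, 6, 5, 3, 4, 2, 1))

# hard-coded parity classes per sub-volume ("odd"/"even" per axis)
TABLE2_PARITY <- matrix(c("odd", "odd", "odd",
                          "even", "odd", "odd",
                          "odd", "even", "odd",
                          "even", "even", "odd",
                          "odd", "odd", "even",
                          "even", "odd", "even",
                          "odd", "even", "even",
                          "even", "even", "even"),
                        ncol = 3, byrow = TRUE)

# brute-force HD95 oracle: boundary via explicit neighbour loop, all-pairs
# distances, manual linear-interpolation percentile
brute_hd95 <- function(a, b, spacing) {
  boundary <- function(m) {
    d <- dim(m)
    out <- NULL
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      if (m[i, j, k] == 0) next
      nb <- c(
        if (i > 1) m[i - 1, j, k] else 0, if (i < d[1]) m[i + 1, j, k] else 0,
        if (j > 1) m[i, j - 1, k] else 0, if (j < d[2]) m[i, j + 1, k] else 0,
        if (k > 1) m[i, j, k - 1] else 0, if (k < d[3]) m[i, j, k + 1] else 0)
      if (any(nb == 0) || i == 1 || i == d[1] || j == 1 || j == d[2] ||
          k == 1 || k == d[3])
        out <- rbind(out, c(i, j, k))
    }
    out
  }
  pct95 <- function(x) {
    x <- sort(x)
    h <- (length(x) - 1) * 0.95 + 1
    lo <- floor(h)
    if (lo == length(x)) x[lo] else x[lo] + (h - lo) * (x[lo + 1] - x[lo])
  }
  ba <- boundary(a); bb <- boundary(b)
  dists <- function(from, to) {
    apply(from, 1, function(p) {
      min(sqrt(colSums((t(to) - p)^2 * spacing^2)))
    })
  }
  max(pct95(dists(ba, bb)), pct95(dists(bb, ba)))
}

# small fast network specification used by training-path tests
tiny_net_spec <- function(channels = c(4L, 8L), in_channels = 1L,
                          d_state = 2L, n_segments = 2L) {
  network_spec(channels = channels,
               strides = list(c(2L, 2L, 1L), c(2L, 2L, 1L)),
               kernels = list(c(3L, 3L, 1L), c(3L, 3L, 1L)),
               in_channels = in_channels, num_classes = 2L,
               d_state = d_state, n_segments = n_segments)
}

# small quick phantom for training-path tests
tiny_phantom_spec <- function(seed) {
  phantom_spec(shape = c(32L, 32L, 6L), n_lesions = 1L,
               lesion_radius_range = c(1.5, 2.5), seed = seed)
}
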