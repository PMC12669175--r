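# The multi-scale multi-scan (MSMS) module and block.
#
# Module (dual branch, shapes preserved):
#   upper:  zero-pad to a multiple of n_segments -> multi-scan into the 8
#           parity sub-volume sequences -> selective scan on each sequence
#           (shared parameters) -> multi-merge -> crop back;
#   lower:  selective scan over the full-resolution grid flattened in a
#           single x-fastest raster order;
#   output: elementwise sum of the two branches.
#
# Block:  LayerNorm -> module -> residual add -> LayerNorm -> convolutional
# feed-forward (two pointwise convolutions with an expansion ratio and a
# LeakyReLU in between) -> residual add.

next_multiple <- function(n, m) as.integer(ceiling(n / m) * m)

msms_module_fwd <- function(x, p, n_segments = 4L, want_cache = TRUE) {
  d <- dim(x)
  sp <- d[2:4]
  padded <- vapply(sp, next_multiple, integer(1), m = n_segments)
  pd <- pad_spatial_fwd(x, padded)
  idx <- scan_indices(build_scan_plan(n_segments, padded), padded)
  Xp <- matrix(pd$y, nrow = d[1])
  Yu <- matrix(0, d[1], ncol(Xp))
  caches_u <- vector("list", 8L)
  for (s in 1:8) {
    r <- selscan_layer_fwd(Xp[, idx[[s]], drop = FALSE], p$upper, want_cache)
    Yu[, idx[[s]]] <- r$y
    caches_u[[s]] <- r$cache
  }
  upper <- crop_spatial(array(Yu, dim = c(d[1], padded)), sp)
  Xl <- matrix(x, nrow = d[1])
  rl <- selscan_layer_fwd(Xl, p$lower, want_cache)
  lower <- array(rl$y, dim = d)
  list(y = upper + lower,
       cache = if (want_cache)
         list(idx = idx, caches_u = caches_u, cache_l = rl$cache,
              pad_cache = pd$cache, padded = padded, d = d) else NULL)
}

msms_module_bwd <- function(dy, cache) {
  d <- cache$d
  # upper branch
  dYu_arr <- array(0, c(d[1], cache$padded))
  dYu_arr[, seq_len(d[2]), seq_len(d[3]), seq_len(d[4])] <- dy
  dYu <- matrix(dYu_arr, nrow = d[1])
  dXp <- matrix(0, d[1], ncol(dYu))
  gU <- NULL
  for (s in 1:8) {
    b <- selscan_layer_bwd(dYu[, cache$idx[[s]], drop = FALSE],
                           cache$caches_u[[s]])
    dXp[, cache$idx[[s]]] <- b$dx
    gU <- if (is.null(gU)) b$grads else param_add(gU, b$grads)
  }
  dx_upper <- pad_spatial_bwd(array(dXp, c(d[1], cache$padded)),
                              cache$pad_cache)
  # lower branch
  bl <- selscan_layer_bwd(matrix(dy, nrow = d[1]), cache$cache_l)
  dx <- dx_upper + array(bl$dx, dim = d)
  list(dx = dx, grads = list(upper = gU, lower = bl$grads))
}

msms_block_fwd <- function(x, p, n_segments = 4L, want_cache = TRUE) {
  l1 <- layer_norm_fwd(x, p$ln1$gamma, p$ln1$beta)
  md <- msms_module_fwd(l1$y, p$mod, n_segments, want_cache)
  r1 <- x + md$y
  l2 <- layer_norm_fwd(r1, p$ln2$gamma, p$ln2$beta)
  f1 <- conv_pw_fwd(l2$y, p$ffn$W1, p$ffn$b1)
  ac <- leaky_relu_fwd(f1$y)
  f2 <- conv_pw_fwd(ac$y, p$ffn$W2, p$ffn$b2)
  y <- r1 + f2$y
  list(y = y,
       cache = if (want_cache)
         list(l1 = l1$cache, md = md$cache, l2 = l2$cache,
              f1 = f1$cache, ac = ac$cache, f2 = f2$cache) else NULL)
}

msms_block_bwd <- function(dy, cache) {
  b2 <- conv_pw_bwd(dy, cache$f2)
  ba <- leaky_relu_bwd(b2$dx, cache$ac)
  b1 <- conv_pw_bwd(ba$dx, cache$f1)
  bl2 <- layer_norm_bwd(b1$dx, cache$l2)
  dr1 <- dy + bl2$dx                      # residual around FFN
  bm <- msms_module_bwd(dr1, cache$md)
  bl1 <- layer_norm_bwd(bm$dx, cache$l1)
  dx <- dr1 + bl1$dx                      # residual around module
  list(dx = dx,
       grads = list(ln1 = bl1$grads, mod = bm$grads, ln2 = bl2$grads,
                    ffn = list(W1 = b1$grads$W, b1 = b1$grads$b,
                               W2 = b2$grads$W, b2 = b2$grads$b)))
}

init_selective <- function(d, n_state, zero_out = TRUE) {
  list(Wb = matrix(stats::rnorm(n_state * d, sd = 1 / sqrt(d)), n_state, d),
       Wc = if (zero_out) matrix(0, n_state, d)
            else matrix(stats::rnorm(n_state * d, sd = 1 / sqrt(d)), n_state, d),
       wd = numeric(d),
       bd = log(expm1(0.1)),
       a = -as.numeric(seq_len(n_state)))
}

init_msms_block <- function(channels, n_state, er = 2L, zero_out = TRUE) {
  hidden <- as.integer(er * channels)
  list(ln1 = list(gamma = rep(1, channels), beta = rep(0, channels)),
       mod = list(upper = init_selective(channels, n_state, zero_out),
                  lower = init_selective(channels, n_state, zero_out)),
       ln2 = list(gamma = rep(1, channels), beta = rep(0, channels)),
       ffn = list(W1 = matrix(stats::rnorm(hidden * channels,
                                           sd = sqrt(2 / channels)),
                              hidden, channels),
                  b1 = numeric(hidden),
                  W2 = matrix(0, channels, hidden),
                  b2 = numeric(channels)))
}

#' Apply the dual-branch MSMS module to a feature grid
#'
#' The upper branch zero-pads the grid to a multiple of `n_segments`,
#' serializes it into the eight parity sub-volume sequences, runs the shared
#' selective scan on each and merges back; the lower branch runs a selective
#' scan over the full-resolution grid in a single x-fastest raster. The
#' output is the elementwise sum of the branches and has the input's shape.
#'
#' @param g feature grid `(channels, nx, ny, nz)` (3-D arrays are treated
#'   as single-channel).
#' @param upper,lower [selective_params] for the two branches (token
#'   dimension must equal the channel count).
#' @param n_segments segments per axis for the upper branch (default 4).
#' @return A feature grid of the same shape.
#' @export
msms_module <- function(g, upper, lower, n_segments = 4L) {
  g <- as_feature_grid(g)
  if (upper$d != dim(g)[1] || lower$d != dim(g)[1])
    stop("selective_params token dimension must equal the channel count",
         call. = FALSE)
  p <- list(upper = upper[c("Wb", "Wc", "wd", "bd", "a")],
            lower = lower[c("Wb", "Wc", "wd", "bd", "a")])
  msms_module_fwd(g, p, n_segments, want_cache = FALSE)$y
}

#' Apply a full MSMS block to a feature grid
#'
#' LayerNorm, MSMS module, residual add, LayerNorm, convolutional
#' feed-forward (pointwise expansion, LeakyReLU, pointwise projection),
#' residual add. With all module and feed-forward weights zero the block is
#' the identity (the residual paths only).
#'
#' @param g feature grid `(channels, nx, ny, nz)`.
#' @param params block parameters as produced by the network constructor; if
#'   `NULL`, freshly initialized parameters are drawn from the current RNG.
#' @param n_segments segments per axis (default 4).
#' @param n_state state dimension of the selective scans (default 16).
#' @param er feed-forward expansion ratio (default 2).
#' @return A feature grid of the same shape.
#' @export
msms_block <- function(g, params = NULL, n_segments = 4L, n_state = 16L,
                       er = 2L) {
  g <- as_feature_grid(g)
  if (is.null(params))
    params <- init_msms_block(dim(g)[1], n_state, er, zero_out = FALSE)
  msms_block_fwd(g, params, n_segments, want_cache = FALSE)$y
}
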