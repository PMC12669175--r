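# Encoder-decoder segmentation network.
#
# Encoder layer l:  conv_block(kernel_l, stride 1, C_{l-1} -> C_l)
#                   -> MSMS block (C_l)
#                   -> conv_block(kernel_l, stride_l, C_l -> C_l)   (down-sampling)
# Decoder layer l:  transposed conv (kernel = stride = encoder stride_l+... )
#                   from the layer below, crop to the skip's extents,
#                   concatenate the skip, conv_block -> C_l.
# A 1x1x1 head maps decoder layer 1 to class logits at full resolution;
# auxiliary heads sit at every deeper decoder layer for deep supervision.
#
# conv_block = depthwise conv -> pointwise conv -> instance norm -> LeakyReLU.

#' Network specification
#'
#' The default reproduces the six-layer reference architecture: encoder
#' channels 2 -> 32 -> 64 -> 128 -> 256 -> 320 -> 320, depthwise kernels
#' (3,3,1) for the first three layers and (3,3,3) below (no z down-sampling
#' in the shallow layers, mirroring thick-slice anisotropy), down-sampling
#' strides (1,1,1), (2,2,1), (2,2,1), (2,2,2), (2,2,2), (2,2,1), state
#' dimension 16, Mamba conv size 4 and expansion ratio 2 at every layer.
#' The decoder's transposed convolutions use kernel = stride = the matching
#' encoder stride, so each decoder layer restores its encoder layer's
#' resolution; decoder channel pairs then follow the encoder chain
#' (e.g. 64 -> 32 at layer 1).
#'
#' @param channels encoder output channels per layer.
#' @param kernels list of depthwise kernel triples per layer.
#' @param strides list of down-sampling stride triples per layer.
#' @param in_channels input channels (default 2).
#' @param num_classes segmentation classes (default 2).
#' @param d_state selective-scan state dimension (default 16).
#' @param d_conv Mamba local-convolution size, recorded for provenance
#'   (default 4; the scan wiring implemented here does not use it).
#' @param er feed-forward expansion ratio (default 2).
#' @param n_segments multi-scan segments per axis (default 4).
#' @param deep_supervision attach auxiliary heads to the deeper decoder
#'   layers (default `TRUE`).
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(channels = c(32L, 64L, 128L, 256L, 320L, 320L),
                         kernels = NULL, strides = NULL,
                         in_channels = 2L, num_classes = 2L,
                         d_state = 16L, d_conv = 4L, er = 2L,
                         n_segments = 4L, deep_supervision = TRUE) {
  L <- length(channels)
  if (L < 2L) stop("need at least two layers", call. = FALSE)
  if (is.null(kernels)) {
    if (L == 6L) kernels <- c(rep(list(c(3L, 3L, 1L)), 3),
                              rep(list(c(3L, 3L, 3L)), 3))
    else kernels <- rep(list(c(3L, 3L, 1L)), L)
  }
  if (is.null(strides)) {
    if (L == 6L) strides <- list(c(1L, 1L, 1L), c(2L, 2L, 1L), c(2L, 2L, 1L),
                                 c(2L, 2L, 2L), c(2L, 2L, 2L), c(2L, 2L, 1L))
    else strides <- c(list(c(1L, 1L, 1L)), rep(list(c(2L, 2L, 1L)), L - 1L))
  }
  stopifnot(length(kernels) == L, length(strides) == L)
  structure(list(channels = as.integer(channels),
                 kernels = lapply(kernels, as.integer),
                 strides = lapply(strides, as.integer),
                 in_channels = as.integer(in_channels),
                 num_classes = as.integer(num_classes),
                 d_state = as.integer(d_state), d_conv = as.integer(d_conv),
                 er = as.integer(er), n_segments = as.integer(n_segments),
                 deep_supervision = isTRUE(deep_supervision),
                 n_layers = L),
            class = "network_spec")
}

init_conv_block <- function(cin, cout, kernel) {
  kv <- prod(kernel)
  list(dw = array(stats::rnorm(cin * kv, sd = sqrt(2 / kv)),
                  dim = c(cin, kernel)),
       pw = list(W = matrix(stats::rnorm(cout * cin, sd = sqrt(2 / cin)),
                            cout, cin),
                 b = numeric(cout)),
       inorm = list(gamma = rep(1, cout), beta = rep(0, cout)))
}

conv_block_fwd <- function(x, p, stride = c(1L, 1L, 1L), want_cache = TRUE) {
  a <- conv_dw_fwd(x, p$dw, stride = c(1L, 1L, 1L))
  b <- conv_pw_fwd(a$y, p$pw$W, p$pw$b)
  # down-sampling happens after the channel mix so the depthwise kernel sees
  # the full-resolution grid
  d <- dim(b$y)
  sub <- lapply(1:3, function(ax) seq(1L, d[ax + 1L], by = stride[ax]))
  ys <- b$y[, sub[[1]], sub[[2]], sub[[3]], drop = FALSE]
  n <- instance_norm_fwd(ys, p$inorm$gamma, p$inorm$beta)
  r <- leaky_relu_fwd(n$y)
  list(y = r$y,
       cache = if (want_cache) list(a = a$cache, b = b$cache, n = n$cache,
                                    r = r$cache, sub = sub, d = d) else NULL)
}

conv_block_bwd <- function(dy, cache) {
  rr <- leaky_relu_bwd(dy, cache$r)
  nn <- instance_norm_bwd(rr$dx, cache$n)
  dyf <- array(0, cache$d)
  dyf[, cache$sub[[1]], cache$sub[[2]], cache$sub[[3]]] <- nn$dx
  bb <- conv_pw_bwd(dyf, cache$b)
  aa <- conv_dw_bwd(bb$dx, cache$a)
  list(dx = aa$dx,
       grads = list(dw = aa$grads$W,
                    pw = list(W = bb$grads$W, b = bb$grads$b),
                    inorm = nn$grads))
}

#' Depthwise-separable convolution block
#'
#' Depthwise 3-D convolution (per-channel, odd same-padded kernel), pointwise
#' 1x1x1 channel mix, instance normalization, LeakyReLU (negative slope
#' 0.01). Spatial extents are divided by `stride` with ceiling division.
#'
#' @param g feature grid `(channels, nx, ny, nz)`.
#' @param kernel odd kernel triple, e.g. `c(3, 3, 1)`.
#' @param stride stride triple.
#' @param out_channels output channel count.
#' @param params optional parameters (from `init_conv_block`); freshly
#'   initialized from the current RNG when `NULL`.
#' @return The transformed feature grid.
#' @export
conv_block <- function(g, kernel = c(3L, 3L, 1L), stride = c(1L, 1L, 1L),
                       out_channels = NULL, params = NULL) {
  g <- as_feature_grid(g)
  cin <- dim(g)[1]
  if (is.null(out_channels)) out_channels <- cin
  if (is.null(params)) params <- init_conv_block(cin, out_channels, as.integer(kernel))
  if (nrow(params$pw$W) != out_channels || ncol(params$pw$W) != cin)
    stop("parameter/channel mismatch", call. = FALSE)
  conv_block_fwd(g, params, as.integer(stride), want_cache = FALSE)$y
}

#' Build a segmentation network
#'
#' Initializes all parameters of the encoder-decoder described by `spec`.
#' Selective-scan output projections and the feed-forward projection back to
#' the channel dimension start at zero, so every MSMS block begins as the
#' identity and the network starts as a pure convolutional encoder-decoder.
#'
#' @param spec a [network_spec].
#' @param seed optional integer seed for the parameter draw.
#' @return An object of class `msm_network`.
#' @export
build_network <- function(spec, seed = NULL) {
  if (!inherits(spec, "network_spec")) stop("expected network_spec", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  L <- spec$n_layers
  ch <- spec$channels
  enc <- vector("list", L)
  dec <- vector("list", L)
  for (l in seq_len(L)) {
    cin <- if (l == 1L) spec$in_channels else ch[l - 1L]
    enc[[l]] <- list(
      c1 = init_conv_block(cin, ch[l], spec$kernels[[l]]),
      block = init_msms_block(ch[l], spec$d_state, spec$er),
      c2 = init_conv_block(ch[l], ch[l], spec$kernels[[l]]))
    up_in <- if (l == L) ch[L] else ch[l + 1L]
    st <- spec$strides[[l]]
    dec[[l]] <- list(
      up = list(W = array(stats::rnorm(ch[l] * up_in * prod(st),
                                       sd = sqrt(2 / up_in)),
                          dim = c(ch[l], up_in, st)),
                b = numeric(ch[l])),
      cb = init_conv_block(2L * ch[l], ch[l], spec$kernels[[l]]))
  }
  # head bias favors the background class at start (class-prior logit
  # initialization): with rare foreground the network then spends no epochs
  # re-learning the trivial background prediction
  head_bias <- c(3, rep(-3, spec$num_classes - 1L))
  heads <- list(primary = list(W = matrix(stats::rnorm(spec$num_classes * ch[1],
                                                       sd = sqrt(2 / ch[1])),
                                          spec$num_classes, ch[1]),
                               b = head_bias))
  if (spec$deep_supervision && L > 1L)
    heads$aux <- lapply(2:L, function(l)
      list(W = matrix(stats::rnorm(spec$num_classes * ch[l],
                                   sd = sqrt(2 / ch[l])),
                      spec$num_classes, ch[l]),
           b = head_bias))
  structure(list(spec = spec, params = list(enc = enc, dec = dec,
                                            heads = heads)),
            class = "msm_network")
}

#' @export
print.msm_network <- function(x, ...) {
  cat(sprintf("<msm_network> %d layers, channels %s, %d classes, %s parameters\n",
              x$spec$n_layers, paste(x$spec$channels, collapse = "-"),
              x$spec$num_classes,
              format(param_count(x$params), big.mark = ",")))
  invisible(x)
}

total_stride <- function(spec) {
  Reduce(function(a, b) a * b, spec$strides, accumulate = FALSE)
}

#' Forward pass of the segmentation network
#'
#' @param net an [build_network()] result.
#' @param x input feature grid `(in_channels, nx, ny, nz)`.
#' @param want_cache keep intermediate activations for a backward pass.
#' @param use_msms run the MSMS blocks (`FALSE` gives the convolution-only
#'   ablation, the blocks are skipped entirely).
#' @return list with `logits` (full-resolution class logits), `aux` (list of
#'   lower-resolution logits, deepest last, when deep supervision is on) and
#'   `cache`.
#' @export
network_forward <- function(net, x, want_cache = FALSE, use_msms = TRUE) {
  spec <- net$spec
  p <- net$params
  L <- spec$n_layers
  x <- as_feature_grid(x)
  if (dim(x)[1] != spec$in_channels)
    stop("input has ", dim(x)[1], " channels, network expects ",
         spec$in_channels, call. = FALSE)
  skips <- vector("list", L)
  ec <- vector("list", L)
  h <- x
  for (l in seq_len(L)) {
    c1 <- conv_block_fwd(h, p$enc[[l]]$c1, c(1L, 1L, 1L), want_cache)
    if (use_msms) {
      bk <- msms_block_fwd(c1$y, p$enc[[l]]$block, spec$n_segments, want_cache)
    } else {
      bk <- list(y = c1$y, cache = NULL)
    }
    c2 <- conv_block_fwd(bk$y, p$enc[[l]]$c2, spec$strides[[l]], want_cache)
    skips[[l]] <- bk$y
    ec[[l]] <- list(c1 = c1$cache, bk = bk$cache, c2 = c2$cache,
                    skip_dim = dim(bk$y))
    h <- c2$y
  }
  dc <- vector("list", L)
  dec_feats <- vector("list", L)
  for (l in rev(seq_len(L))) {
    up <- conv_transpose_fwd(h, p$dec[[l]]$up$W, p$dec[[l]]$up$b,
                             spec$strides[[l]])
    sk_dim <- dim(skips[[l]])
    upc <- crop_spatial(up$y, sk_dim[2:4])
    cat_in <- array(0, c(2L * spec$channels[l], sk_dim[2:4]))
    cat_in[seq_len(spec$channels[l]), , , ] <- upc
    cat_in[spec$channels[l] + seq_len(spec$channels[l]), , , ] <- skips[[l]]
    cb <- conv_block_fwd(cat_in, p$dec[[l]]$cb, c(1L, 1L, 1L), want_cache)
    dc[[l]] <- list(up = up$cache, cb = cb$cache, up_dim = dim(up$y),
                    sk_dim = sk_dim)
    dec_feats[[l]] <- cb$y
    h <- cb$y
  }
  hp <- conv_pw_fwd(dec_feats[[1]], p$heads$primary$W, p$heads$primary$b)
  aux <- NULL
  hc_aux <- NULL
  if (spec$deep_supervision && L > 1L) {
    aux <- vector("list", L - 1L)
    hc_aux <- vector("list", L - 1L)
    for (i in seq_len(L - 1L)) {
      ha <- conv_pw_fwd(dec_feats[[i + 1L]], p$heads$aux[[i]]$W,
                        p$heads$aux[[i]]$b)
      aux[[i]] <- ha$y
      hc_aux[[i]] <- ha$cache
    }
  }
  list(logits = hp$y, aux = aux,
       cache = if (want_cache) list(ec = ec, dc = dc, hp = hp$cache,
                                    hc_aux = hc_aux, use_msms = use_msms)
               else NULL)
}

network_backward <- function(net, cache, dlogits, daux = NULL) {
  spec <- net$spec
  L <- spec$n_layers
  g <- list(enc = vector("list", L), dec = vector("list", L), heads = list())
  hp <- conv_pw_bwd(dlogits, cache$hp)
  g$heads$primary <- list(W = hp$grads$W, b = hp$grads$b)
  ddec <- vector("list", L)        # gradient flowing into each decoder output
  ddec[[1]] <- hp$dx
  if (!is.null(cache$hc_aux)) {
    g$heads$aux <- vector("list", L - 1L)
    for (i in seq_len(L - 1L)) {
      da <- if (!is.null(daux) && !is.null(daux[[i]])) daux[[i]] else NULL
      if (is.null(da)) {
        g$heads$aux[[i]] <- param_zero(list(W = net$params$heads$aux[[i]]$W,
                                            b = net$params$heads$aux[[i]]$b))
      } else {
        ha <- conv_pw_bwd(da, cache$hc_aux[[i]])
        g$heads$aux[[i]] <- list(W = ha$grads$W, b = ha$grads$b)
        ddec[[i + 1L]] <- ha$dx
      }
    }
  }
  dskips <- vector("list", L)
  dh <- NULL                        # gradient flowing into decoder input below
  for (l in seq_len(L)) {
    dout <- ddec[[l]]
    if (!is.null(dh)) dout <- if (is.null(dout)) dh else dout + dh
    if (is.null(dout))
      dout <- array(0, c(spec$channels[l], cache$dc[[l]]$sk_dim[2:4]))
    cb <- conv_block_bwd(dout, cache$dc[[l]]$cb)
    C <- spec$channels[l]
    dupc <- cb$dx[seq_len(C), , , , drop = FALSE]
    dskips[[l]] <- cb$dx[C + seq_len(C), , , , drop = FALSE]
    dup_full <- array(0, cache$dc[[l]]$up_dim)
    sk <- cache$dc[[l]]$sk_dim
    dup_full[, seq_len(sk[2]), seq_len(sk[3]), seq_len(sk[4])] <- dupc
    up <- conv_transpose_bwd(dup_full, cache$dc[[l]]$up)
    g$dec[[l]] <- list(up = list(W = up$grads$W, b = up$grads$b),
                       cb = cb$grads)
    dh <- up$dx
  }
  # dh now flows into the bottleneck = encoder L output
  for (l in rev(seq_len(L))) {
    c2 <- conv_block_bwd(dh, cache$ec[[l]]$c2)
    dblk <- c2$dx + dskips[[l]]
    if (cache$use_msms) {
      bk <- msms_block_bwd(dblk, cache$ec[[l]]$bk)
      gblk <- bk$grads
      dc1 <- bk$dx
    } else {
      gblk <- param_zero(net$params$enc[[l]]$block)
      dc1 <- dblk
    }
    c1 <- conv_block_bwd(dc1, cache$ec[[l]]$c1)
    g$enc[[l]] <- list(c1 = c1$grads, block = gblk, c2 = c2$grads)
    dh <- c1$dx
  }
  list(dx = dh, grads = g)
}

#' Segment a volume with a trained network
#'
#' The volume is z-scored, zero-padded on the right to extents the network's
#' total down-sampling factor divides, passed through the network and
#' arg-maxed into voxel labels; the padding is cropped away, so the label
#' volume has the input's shape.
#'
#' @param object an `msm_network`.
#' @param vol an [msm_volume] (or 3-D array) preprocessed to the training
#'   geometry; for multi-channel networks a `(in_channels, nx, ny, nz)`
#'   array.
#' @param ... unused.
#' @return An [msm_volume] of integer labels in `0 .. num_classes - 1`.
#' @export
predict.msm_network <- function(object, vol, ...) {
  spec <- object$spec
  spacing <- c(1, 1, 1)
  note <- "prediction"
  if (is_volume(vol)) {
    spacing <- vol$spacing
    note <- paste0("prediction of ", vol$origin_note)
    x <- vol$data
  } else x <- vol
  x <- as_feature_grid(x)
  if (dim(x)[1] == 1L && spec$in_channels > 1L)
    x <- array(rep(x, spec$in_channels),
               dim = c(spec$in_channels, dim(x)[2:4]))
  sp <- dim(x)[2:4]
  tsr <- total_stride(spec)
  if (any(sp < tsr))
    stop(sprintf("input extent (%s) smaller than the total down-sampling factor (%s)",
                 paste(sp, collapse = "x"), paste(tsr, collapse = "x")),
         call. = FALSE)
  mu <- mean(x); sdv <- stats::sd(as.vector(x))
  if (is.finite(sdv) && sdv > 0) x <- (x - mu) / sdv
  target <- vapply(seq_len(3), function(ax) next_multiple(sp[ax], tsr[ax]),
                   integer(1))
  xp <- pad_spatial_fwd(x, target)$y
  out <- network_forward(object, xp, want_cache = FALSE)
  lg <- crop_spatial(out$logits, sp)
  lab <- apply(lg, c(2, 3, 4), which.max) - 1L
  msm_volume(array(as.integer(lab), dim = sp), spacing, note)
}

#' Save / load a network checkpoint
#'
#' A checkpoint is a single RDS archive holding the [network_spec] and the
#' parameter values, plus the package version.
#'
#' @param net an `msm_network`.
#' @param path file path (conventionally `.rds`).
#' @return `path` (save) or the restored `msm_network` (load).
#' @export
save_checkpoint <- function(net, path) {
  saveRDS(list(spec = unclass(net$spec), params = net$params,
               package_version = as.character(utils::packageVersion("msmseg"))),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("no such checkpoint: ", path, call. = FALSE)
  obj <- readRDS(path)
  structure(list(spec = structure(obj$spec, class = "network_spec"),
                 params = obj$params),
            class = "msm_network")
}
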