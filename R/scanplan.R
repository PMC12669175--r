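# Multi-scan volume serialization.
#
# A volume is uniformly partitioned into N segments per axis (N even),
# giving N^3 basic elements.  Eight sub-volumes (SVs) are formed by picking
# one parity class (odd or even block index) per axis; each SV is flattened
# into a 1-D sequence by its own traversal order over its elements, and the
# multi-merge operation inverts the serialization exactly.
#
# Element numbering within an SV is x-fastest, then y, then z (1-based), so
# for N = 4 the eight canonical traversal orders read as axis-priority
# scans and their reversals:
#   SV1 [1 2 3 4 5 6 7 8]  x-fastest, forward      SV2 reverse of SV1
#   SV3 [1 3 2 4 5 7 6 8]  y-fastest, forward      SV4 reverse of SV3
#   SV5 [1 5 2 6 3 7 4 8]  z-fastest, forward      SV6 reverse of SV5
#   SV7 [1 2 4 3 5 6 8 7]  in-plane snake, forward SV8 reverse of SV7
# The same axis-priority/snake/reversal rules generalize the traversal to
# any even N (the SV element grid is (N/2)^3).

# parity class per axis for each SV: 1 = odd block indices, 2 = even
SV_PARITY <- matrix(c(1, 1, 1,
                      2, 1, 1,
                      1, 2, 1,
                      2, 2, 1,
                      1, 1, 2,
                      2, 1, 2,
                      1, 2, 2,
                      2, 2, 2), ncol = 3, byrow = TRUE)

# traversal rule per SV: axis priority (fastest first), snake flag, reversal
SV_RULES <- list(
  list(axes = c(1L, 2L, 3L), snake = FALSE, reverse = FALSE),
  list(axes = c(1L, 2L, 3L), snake = FALSE, reverse = TRUE),
  list(axes = c(2L, 1L, 3L), snake = FALSE, reverse = FALSE),
  list(axes = c(2L, 1L, 3L), snake = FALSE, reverse = TRUE),
  list(axes = c(3L, 1L, 2L), snake = FALSE, reverse = FALSE),
  list(axes = c(3L, 1L, 2L), snake = FALSE, reverse = TRUE),
  list(axes = c(1L, 2L, 3L), snake = TRUE,  reverse = FALSE),
  list(axes = c(1L, 2L, 3L), snake = TRUE,  reverse = TRUE))

# Visit order over an m x m x m element grid under one traversal rule;
# returns element numbers in x-fastest numbering (1-based).
sv_element_order <- function(m, rule) {
  pos <- matrix(0L, nrow = m^3, ncol = 3)
  t <- 1L
  for (c3 in seq_len(m)) for (c2 in seq_len(m)) {
    c1s <- seq_len(m)
    if (rule$snake && c2 %% 2L == 0L) c1s <- rev(c1s)
    for (c1 in c1s) {
      p <- integer(3)
      p[rule$axes] <- c(c1, c2, c3)
      pos[t, ] <- p
      t <- t + 1L
    }
  }
  num <- pos[, 1] + m * (pos[, 2] - 1L) + m * m * (pos[, 3] - 1L)
  if (rule$reverse) num <- rev(num)
  num
}

#' Build a multi-scan plan
#'
#' Partitions a grid of the stated spatial shape into `n_segments^3` basic
#' elements and derives the eight parity sub-volumes together with their
#' traversal orders (for `n_segments = 4` these are the eight canonical
#' length-8 permutations; see the package vignette).
#'
#' @param n_segments positive even number of segments per axis (default 4).
#' @param spatial_shape integer triple; every extent must be at least
#'   `n_segments`. Grids handed to [multi_scan()] must be divisible by
#'   `n_segments` along every axis (pad first, e.g. via the network layers,
#'   which pad and crop automatically).
#' @return An object of class `scan_plan` with fields `n_segments`,
#'   `spatial_shape`, `element_index` (element id to block-coordinate map)
#'   and `subvolumes` (parity classes, realized traversal `order`, and the
#'   canonical octant permutation `order8`).
#' @export
build_scan_plan <- function(n_segments = 4L, spatial_shape = c(64L, 64L, 12L)) {
  n_segments <- as.integer(n_segments)
  if (n_segments < 2L || n_segments %% 2L != 0L)
    stop("n_segments must be a positive even integer", call. = FALSE)
  spatial_shape <- as.integer(spatial_shape)
  if (length(spatial_shape) != 3L || any(spatial_shape < n_segments))
    stop("every spatial extent must be >= n_segments", call. = FALSE)
  N <- n_segments
  m <- N %/% 2L
  element_index <- as.matrix(expand.grid(i = seq_len(N), j = seq_len(N),
                                         k = seq_len(N), KEEP.OUT.ATTRS = FALSE))
  subvolumes <- lapply(seq_len(8L), function(s) {
    classes <- lapply(1:3, function(ax)
      seq(SV_PARITY[s, ax], N, by = 2L))     # block indices of this parity
    list(parity = c("odd", "even")[SV_PARITY[s, ]],
         classes = classes,
         order = sv_element_order(m, SV_RULES[[s]]),
         order8 = sv_element_order(2L, SV_RULES[[s]]))
  })
  structure(list(n_segments = N, spatial_shape = spatial_shape,
                 element_index = element_index, subvolumes = subvolumes),
            class = "scan_plan")
}

#' @export
print.scan_plan <- function(x, ...) {
  cat(sprintf("<scan_plan> N = %d: %d basic elements, 8 sub-volumes of %d\n",
              x$n_segments, x$n_segments^3, (x$n_segments %/% 2L)^3))
  for (s in 1:8)
    cat(sprintf("  SV%d (%s): [%s]\n", s,
                paste(x$subvolumes[[s]]$parity, collapse = ","),
                paste(x$subvolumes[[s]]$order8, collapse = ", ")))
  invisible(x)
}

# Voxel linear indices (x-fastest array order over an nx x ny x nz grid)
# visited by each sub-volume's sequence.  Reversed SVs reverse the whole
# voxel sequence, so the within-element raster shares the element order's
# sense.  Cached per (plan, shape) in an environment.
scan_indices <- function(plan, spatial_shape) {
  spatial_shape <- as.integer(spatial_shape)
  N <- plan$n_segments
  if (any(spatial_shape %% N != 0L))
    stop(sprintf("spatial extents (%s) must be divisible by n_segments = %d; pad first",
                 paste(spatial_shape, collapse = "x"), N), call. = FALSE)
  key <- paste(c(N, spatial_shape), collapse = "x")
  cached <- .scan_index_cache[[key]]
  if (!is.null(cached)) return(cached)
  b <- spatial_shape %/% N                       # block extents
  nx <- spatial_shape[1]; ny <- spatial_shape[2]
  m <- N %/% 2L
  # linear voxel indices of one block in x-fastest raster
  block_voxels <- function(i, j, k) {
    xs <- (i - 1L) * b[1] + seq_len(b[1])
    ys <- (j - 1L) * b[2] + seq_len(b[2])
    zs <- (k - 1L) * b[3] + seq_len(b[3])
    idx <- outer(outer(xs, (ys - 1L) * nx, "+"), (zs - 1L) * nx * ny, "+")
    as.integer(idx)
  }
  out <- lapply(seq_len(8L), function(s) {
    sv <- plan$subvolumes[[s]]
    rule <- SV_RULES[[s]]
    fwd <- if (rule$reverse) sv_element_order(m, modifyList(rule, list(reverse = FALSE)))
           else sv$order
    seq_idx <- unlist(lapply(fwd, function(el) {
      p <- c((el - 1L) %% m, ((el - 1L) %/% m) %% m, (el - 1L) %/% (m * m)) + 1L
      block_voxels(sv$classes[[1]][p[1]], sv$classes[[2]][p[2]],
                   sv$classes[[3]][p[3]])
    }), use.names = FALSE)
    if (rule$reverse) rev(seq_idx) else seq_idx
  })
  .scan_index_cache[[key]] <- out
  out
}

.scan_index_cache <- new.env(parent = emptyenv())

as_feature_grid <- function(g) {
  if (is.null(dim(g)) || length(dim(g)) == 3L) {
    g <- array(g, dim = c(1L, dim(as.array(g))))
  }
  if (length(dim(g)) != 4L)
    stop("feature grid must be (channels, nx, ny, nz)", call. = FALSE)
  g
}

#' Flatten a feature grid into the eight sub-volume sequences
#'
#' @param g feature grid, a `(channels, nx, ny, nz)` array (a 3-D array is
#'   treated as single-channel); spatial extents must be divisible by
#'   `plan$n_segments`.
#' @param plan a [build_scan_plan()] result.
#' @return A list of 8 `channels x L` matrices (`L = voxels / 8`); jointly
#'   the sequences visit every voxel exactly once.
#' @export
multi_scan <- function(g, plan) {
  g <- as_feature_grid(g)
  d <- dim(g)
  idx <- scan_indices(plan, d[2:4])
  X <- matrix(g, nrow = d[1])
  lapply(idx, function(ii) X[, ii, drop = FALSE])
}

#' Reconstruct a feature grid from its eight sequences
#'
#' Exact inverse of [multi_scan()].
#'
#' @param seqs list of 8 `channels x L` matrices.
#' @param plan the [build_scan_plan()] used for scanning.
#' @param spatial_shape spatial extents of the grid to reconstruct.
#' @return A `(channels, nx, ny, nz)` array.
#' @export
multi_merge <- function(seqs, plan, spatial_shape) {
  if (length(seqs) != 8L) stop("expected 8 sequences", call. = FALSE)
  spatial_shape <- as.integer(spatial_shape)
  idx <- scan_indices(plan, spatial_shape)
  C <- nrow(seqs[[1]])
  nvox <- prod(spatial_shape)
  lens <- vapply(seqs, ncol, integer(1))
  if (any(lens != nvox / 8L))
    stop("sequence lengths inconsistent with the plan/shape", call. = FALSE)
  X <- matrix(0, nrow = C, ncol = nvox)
  for (s in seq_len(8L)) X[, idx[[s]]] <- seqs[[s]]
  array(X, dim = c(C, spatial_shape))
}
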