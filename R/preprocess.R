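# Geometric standardization and multi-scale Gaussian intensity harmonization.
#
# The harmonization model: an image I is smoothed with Gaussian kernels of
# standard deviations sigma_k (sigma_0 = 0 keeps the original image), each
# smoothed image is z-scored and rescaled to the corresponding moments of the
# smoothed reference scan,
#     I~(k) = (I(k) - mu(k)) / sd(k) * sd_ref(k) + mu_ref(k),
# and the harmonized image is the sum over scales of the I~(k).

gaussian_kernel_1d <- function(sigma) {
  if (sigma == 0) return(1)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w / sum(w)
}

# Fold an out-of-range 1-based index back into [1, n] by reflection with the
# edge sample repeated ( d c b a | a b c d | d c b a ).
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * n)
  j <- ifelse(j < 0L, j + 2L * n, j)
  ifelse(j < n, j + 1L, 2L * n - j)
}

# Convolve along one axis of a 3-D array with a symmetric kernel and
# reflecting boundaries; vectorized as a sum of row-shifted copies.
conv_axis <- function(arr, w, axis) {
  if (length(w) == 1L) return(arr * w)
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = d[axis])
  n <- d[axis]
  r <- (length(w) - 1L) %/% 2L
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (k in seq_along(w)) {
    off <- k - r - 1L
    out <- out + w[k] * m[reflect_index(seq_len(n) + off, n), , drop = FALSE]
  }
  arr2 <- array(out, dim = d[perm])
  aperm(arr2, order(perm))
}

#' Gaussian smoothing of a volume
#'
#' Separable Gaussian filter; `sigma` is expressed in voxels of the current
#' grid (apply after resampling if physically uniform smoothing is wanted).
#' The kernel is normalized to unit mass and boundaries reflect, so constants
#' are preserved and interior-supported signals keep their total intensity.
#'
#' @param vol an [msm_volume].
#' @param sigma non-negative kernel standard deviation in voxels;
#'   `sigma = 0` returns the input unchanged.
#' @return An [msm_volume] of identical shape and spacing.
#' @export
gaussian_smooth <- function(vol, sigma) {
  stopifnot_volume(vol)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma < 0)
    stop("sigma must be a single non-negative real", call. = FALSE)
  if (sigma == 0) return(vol)
  w <- gaussian_kernel_1d(sigma)
  out <- vol$data
  for (ax in 1:3) out <- conv_axis(out, w, ax)
  msm_volume(out, vol$spacing, vol$origin_note)
}

#' Build a harmonization specification from a reference scan
#'
#' Records the Gaussian scales and, for each scale, the mean and standard
#' deviation of the smoothed reference image. Statistics are computed over
#' the whole grid (set `stats_scope = "nonzero"` to restrict them to nonzero
#' voxels, e.g. after background cropping of a skull-stripped scan).
#'
#' @param reference an [msm_volume], the reference scan all images are
#'   harmonized towards.
#' @param sigmas ordered non-negative Gaussian standard deviations in voxels;
#'   the first must be 0 (the original, non-smoothed image). Default
#'   `c(0, 2, 4, 6)`.
#' @param stats_scope `"grid"` (default) or `"nonzero"`.
#' @return An object of class `harmonization_spec` with fields `sigmas` and
#'   `reference_stats` (one `(mean, sd)` row per scale).
#' @export
harmonization_spec <- function(reference, sigmas = c(0, 2, 4, 6),
                               stats_scope = c("grid", "nonzero")) {
  stopifnot_volume(reference)
  stats_scope <- match.arg(stats_scope)
  sigmas <- as.numeric(sigmas)
  if (length(sigmas) < 1L || any(!is.finite(sigmas)) || any(sigmas < 0))
    stop("sigmas must be non-negative reals", call. = FALSE)
  if (sigmas[1] != 0)
    stop("sigmas[1] must be 0: the original image is always included",
         call. = FALSE)
  stats <- t(vapply(sigmas, function(s) {
    sm <- gaussian_smooth(reference, s)$data
    v <- if (stats_scope == "nonzero") sm[sm != 0] else as.vector(sm)
    c(mean = mean(v), sd = stats::sd(v))
  }, numeric(2)))
  if (anyNA(stats) || any(stats[, "sd"] < 0))
    stop("degenerate reference statistics", call. = FALSE)
  structure(list(sigmas = sigmas, reference_stats = stats,
                 stats_scope = stats_scope),
            class = "harmonization_spec")
}

#' Harmonize a volume against reference statistics
#'
#' For every scale k the input is smoothed with `sigmas[k]`, z-scored with
#' its own (whole-grid or nonzero-voxel) moments and mapped onto the
#' reference moments; the harmonized image is the sum of the per-scale
#' images. Each summand therefore has exactly the reference mean and sd at
#' its scale.
#'
#' @param vol an [msm_volume].
#' @param spec a [harmonization_spec].
#' @return The harmonized [msm_volume].
#' @export
harmonize <- function(vol, spec) {
  stopifnot_volume(vol)
  if (!inherits(spec, "harmonization_spec"))
    stop("spec must be a harmonization_spec", call. = FALSE)
  out <- array(0, dim(vol$data))
  for (k in seq_along(spec$sigmas)) {
    sm <- gaussian_smooth(vol, spec$sigmas[k])$data
    v <- if (spec$stats_scope == "nonzero") sm[sm != 0] else as.vector(sm)
    mu <- mean(v); sd_k <- stats::sd(v)
    mu_ref <- spec$reference_stats[k, "mean"]
    sd_ref <- spec$reference_stats[k, "sd"]
    if (sd_k == 0 || !is.finite(sd_k)) {
      if (sd_ref > 0)
        stop(sprintf(
          "degenerate input: zero intensity variance at scale %d (sigma = %g)",
          k, spec$sigmas[k]), call. = FALSE)
      out <- out + mu_ref           # constant scale maps to the reference constant
    } else {
      out <- out + (sm - mu) / sd_k * sd_ref + mu_ref
    }
  }
  msm_volume(out, vol$spacing, vol$origin_note)
}

#' Geometry specification for resampling and crop/pad
#'
#' @param target_spacing positive mm triple; default the study geometry
#'   `c(0.47, 0.47, 6.5)`.
#' @param pad_shape integer triple of output voxel extents; an entry of `-1`
#'   keeps that axis length unchanged.
#' @param pad_value fill value for padded voxels (default 0).
#' @return An object of class `geometry_spec`.
#' @export
geometry_spec <- function(target_spacing = c(0.47, 0.47, 6.5),
                          pad_shape = c(320L, 320L, -1L), pad_value = 0) {
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3L || any(target_spacing <= 0))
    stop("target_spacing must be three positive reals", call. = FALSE)
  pad_shape <- as.integer(pad_shape)
  if (length(pad_shape) != 3L || any(pad_shape == 0L) || any(pad_shape < -1L))
    stop("pad_shape entries must be positive integers or -1", call. = FALSE)
  structure(list(target_spacing = target_spacing, pad_shape = pad_shape,
                 pad_value = as.numeric(pad_value)[1]),
            class = "geometry_spec")
}

#' Resample a volume to a target spacing
#'
#' Output extents are `round(shape * spacing / target_spacing)` (at least 1
#' per axis). Voxel centres are aligned at index 0; intensities are
#' interpolated trilinearly, label volumes with `method = "nearest"` so the
#' label alphabet is preserved.
#'
#' @param vol an [msm_volume].
#' @param geo a [geometry_spec] (only `target_spacing` is used).
#' @param method `"linear"` (intensities) or `"nearest"` (labels).
#' @return The resampled [msm_volume].
#' @export
resample <- function(vol, geo, method = c("linear", "nearest")) {
  stopifnot_volume(vol)
  method <- match.arg(method)
  ts <- geo$target_spacing
  d <- dim(vol$data)
  nd <- pmax(1L, as.integer(round(d * vol$spacing / ts)))
  if (all(nd == d) && all(abs(ts - vol$spacing) < 1e-12)) {
    return(msm_volume(vol$data, ts, vol$origin_note))
  }
  # source coordinate (0-based, voxel centres) for each output index
  src <- lapply(1:3, function(ax) {
    g <- (seq_len(nd[ax]) - 1) * ts[ax] / vol$spacing[ax]
    pmin(pmax(g, 0), d[ax] - 1)
  })
  if (method == "nearest") {
    idx <- lapply(1:3, function(ax) as.integer(round(src[[ax]])) + 1L)
    out <- vol$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  } else {
    i0 <- lapply(1:3, function(ax) pmin(floor(src[[ax]]), d[ax] - 1))
    fr <- lapply(1:3, function(ax) src[[ax]] - i0[[ax]])
    i0 <- lapply(i0, function(v) as.integer(v) + 1L)
    i1 <- lapply(1:3, function(ax) pmin(i0[[ax]] + 1L, d[ax]))
    out <- array(0, nd)
    for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
      wx <- if (a == 0) 1 - fr[[1]] else fr[[1]]
      wy <- if (b == 0) 1 - fr[[2]] else fr[[2]]
      wz <- if (cc == 0) 1 - fr[[3]] else fr[[3]]
      w <- outer(outer(wx, wy), wz)
      ix <- if (a == 0) i0[[1]] else i1[[1]]
      iy <- if (b == 0) i0[[2]] else i1[[2]]
      iz <- if (cc == 0) i0[[3]] else i1[[3]]
      out <- out + w * vol$data[ix, iy, iz, drop = FALSE]
    }
  }
  dim(out) <- nd
  msm_volume(out, ts, vol$origin_note)
}

#' Crop to the in-plane bounding box and zero-pad to a fixed shape
#'
#' The x and y axes are cropped to the tight bounding box of nonzero
#' intensity (an all-zero volume keeps its full extent), then every axis is
#' symmetrically padded with `geo$pad_value` to `geo$pad_shape`; when the
#' total padding on an axis is odd the extra voxel goes to the high-index
#' side. A `pad_shape` entry of `-1` leaves that axis length unchanged.
#'
#' @param vol an [msm_volume].
#' @param geo a [geometry_spec].
#' @return The cropped and padded [msm_volume].
#' @export
crop_and_pad <- function(vol, geo) {
  stopifnot_volume(vol)
  d <- dim(vol$data)
  nz <- which(vol$data != 0, arr.ind = TRUE)
  if (nrow(nz) == 0L) {
    lo <- c(1L, 1L, 1L); hi <- d            # empty box: keep the whole volume
  } else {
    lo <- c(min(nz[, 1]), min(nz[, 2]), 1L)
    hi <- c(max(nz[, 1]), max(nz[, 2]), d[3])
  }
  cropped <- vol$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  cd <- hi - lo + 1L
  target <- ifelse(geo$pad_shape == -1L, cd, geo$pad_shape)
  if (any(cd > target))
    stop(sprintf("bounding box (%s) exceeds pad shape (%s)",
                 paste(cd, collapse = "x"), paste(target, collapse = "x")),
         call. = FALSE)
  pad <- target - cd
  lo_pad <- pad %/% 2L                       # odd remainder goes high
  out <- array(geo$pad_value, dim = target)
  out[lo_pad[1] + seq_len(cd[1]), lo_pad[2] + seq_len(cd[2]),
      lo_pad[3] + seq_len(cd[3])] <- cropped
  msm_volume(out, vol$spacing, vol$origin_note)
}
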