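#' 3-D intensity volume with physical voxel spacing
#'
#' The basic container for a single-channel 3-D image. Axis order is
#' (x, y, z) throughout the package, shapes are written (nx, ny, nz) and all
#' voxel indices are 0-based in documentation (R subsetting is of course
#' 1-based internally). `spacing` is in millimetres per voxel along each axis.
#'
#' @param data 3-D numeric array of intensities.
#' @param spacing numeric triple, mm per voxel along (x, y, z); all > 0.
#' @param origin_note free-text provenance tag.
#' @return An object of class `msm_volume`.
#' @export
msm_volume <- function(data, spacing = c(1, 1, 1), origin_note = "") {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("volume data must have exactly three axes", call. = FALSE)
  if (any(dim(data) < 1L))
    stop("every volume axis must have length >= 1", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive reals", call. = FALSE)
  structure(list(data = data, spacing = spacing,
                 origin_note = as.character(origin_note)[1]),
            class = "msm_volume")
}

#' @export
print.msm_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<msm_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]%s\n",
              min(x$data), max(x$data),
              if (nzchar(x$origin_note)) paste0("  (", x$origin_note, ")") else ""))
  invisible(x)
}

#' @export
dim.msm_volume <- function(x) dim(x$data)

is_volume <- function(x) inherits(x, "msm_volume")

stopifnot_volume <- function(x) {
  if (!is_volume(x)) stop("expected an `msm_volume` object", call. = FALSE)
  invisible(x)
}

#' Read a NIfTI volume
#'
#' Reads a `.nii`/`.nii.gz` file; voxel spacing is taken from the header
#' pixdims. The image is coerced to a plain 3-D array (a trailing singleton
#' fourth dimension is dropped).
#'
#' @param path file path.
#' @return An [msm_volume].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) dim(arr) <- dim(arr)[1:3]
  sp <- RNifti::pixdim(img)[1:3]
  msm_volume(arr, spacing = sp, origin_note = basename(path))
}

#' Write a volume as NIfTI-1
#'
#' @param vol an [msm_volume]. Label volumes (all values non-negative
#'   integers) are stored with an unsigned integer datatype.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot_volume(vol)
  is_label <- all(vol$data == round(vol$data)) && min(vol$data) >= 0 &&
    max(vol$data) < 65536
  dt <- if (is_label) "uint16" else "float"
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}
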