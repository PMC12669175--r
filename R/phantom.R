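# Synthetic 3-D lesion phantoms.
#
# Emulates the imaging regime the package targets: strongly anisotropic
# voxels (thin in-plane, thick slices), an ellipsoidal "brain" support with
# smooth tissue texture, a handful of small bright lesions placed near the
# support boundary (the leptomeningeal pattern), heavy foreground/background
# class imbalance (< 5% lesion voxels), per-"scanner" affine intensity
# shifts and additive Gaussian noise.  Not modelled: MRI physics (bias
# fields, k-space artifacts), skull, partial-volume blur.

#' Phantom specification
#'
#' @param shape voxel extents (default `c(64, 64, 12)`).
#' @param spacing mm voxel spacing (default `c(0.47, 0.47, 6.5)`).
#' @param n_lesions number of lesions (default 2).
#' @param lesion_radius_range mm radius interval lesions are drawn from
#'   (default 2-4 mm); lesion centres snap to slice centres in z so thin
#'   lesions are never lost between thick slices.
#' @param lesion_contrast multiplicative lesion intensity factor > 1
#'   (default 1.8).
#' @param background_texture amplitude of the smooth random tissue texture
#'   relative to the base intensity 1 (default 0.1).
#' @param scanner_shift per-volume affine intensity perturbation,
#'   `c(gain, offset)` applied last (default `c(1, 0)`).
#' @param noise_sd additive Gaussian noise sd (default 0.05).
#' @param boundary_stripe add a bright stripe along the support boundary, a
#'   distractor mimicking bright non-lesion tissue interfaces
#'   (default `FALSE`).
#' @param seed integer seed; identical spec + seed give bit-identical output.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 12L),
                         spacing = c(0.47, 0.47, 6.5),
                         n_lesions = 2L,
                         lesion_radius_range = c(2, 4),
                         lesion_contrast = 1.8,
                         background_texture = 0.1,
                         scanner_shift = c(1, 0),
                         noise_sd = 0.05,
                         boundary_stripe = FALSE,
                         seed = 1L) {
  if (n_lesions < 0L) stop("n_lesions must be >= 0", call. = FALSE)
  if (lesion_contrast <= 1) stop("lesion_contrast must exceed 1", call. = FALSE)
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 n_lesions = as.integer(n_lesions),
                 lesion_radius_range = as.numeric(lesion_radius_range),
                 lesion_contrast = lesion_contrast,
                 background_texture = background_texture,
                 scanner_shift = as.numeric(scanner_shift),
                 noise_sd = noise_sd,
                 boundary_stripe = isTRUE(boundary_stripe),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate one lesion phantom
#'
#' @param spec a [phantom_spec].
#' @return list with `image` (an [msm_volume]) and `mask` (a binary
#'   [msm_volume] of the exact lesion voxels).
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("expected phantom_spec", call. = FALSE)
  with_local_seed(spec$seed, {
    d <- spec$shape; sp <- spec$spacing
    half <- (d - 1) * sp / 2
    ax_mm <- lapply(1:3, function(i) (seq_len(d[i]) - 1) * sp[i] - half[i])
    semi <- 0.45 * (d * sp)                  # ellipsoid "brain" semi-axes, mm
    # squared normalized ellipsoid radius at every voxel
    rx2 <- (ax_mm[[1]] / semi[1])^2
    ry2 <- (ax_mm[[2]] / semi[2])^2
    rz2 <- (ax_mm[[3]] / semi[3])^2
    rho2 <- outer(outer(rx2, ry2, "+"), rz2, "+")
    support <- rho2 <= 1
    # smooth tissue texture on base intensity 1
    tex <- msm_volume(array(stats::rnorm(prod(d)), d), sp)
    tex <- gaussian_smooth(gaussian_smooth(tex, 0), 3)$data
    tex <- tex / max(stats::sd(as.vector(tex)), 1e-12) * spec$background_texture
    img <- (1 + tex) * support
    if (spec$boundary_stripe) {
      stripe <- support & rho2 >= 0.85
      img[stripe] <- img[stripe] * spec$lesion_contrast
    }
    mask <- array(0L, d)
    if (spec$n_lesions > 0L) {
      for (li in seq_len(spec$n_lesions)) {
        placed <- FALSE
        for (try in seq_len(50L)) {
          r <- stats::runif(1, spec$lesion_radius_range[1],
                            spec$lesion_radius_range[2])
          u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
          f <- stats::runif(1, 0.45, 0.75)   # near the support boundary
          ctr <- u * f * semi
          ctr[3] <- ax_mm[[3]][which.min(abs(ax_mm[[3]] - ctr[3]))]
          # lesion must sit fully inside the support
          if (sum(((abs(ctr) + r) / semi)^2) > 0.96) next
          dx2 <- ((ax_mm[[1]] - ctr[1]) / r)^2
          dy2 <- ((ax_mm[[2]] - ctr[2]) / r)^2
          dz2 <- ((ax_mm[[3]] - ctr[3]) / r)^2
          les <- outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
          if (!any(les)) next
          img[les] <- img[les] * spec$lesion_contrast
          mask[les] <- 1L
          placed <- TRUE
          break
        }
        if (!placed)
          stop("could not place lesion ", li, " inside the support",
               call. = FALSE)
      }
    }
    img <- img + stats::rnorm(prod(d), sd = spec$noise_sd)
    img <- spec$scanner_shift[1] * img + spec$scanner_shift[2]
    list(image = msm_volume(img, sp, sprintf("phantom seed %d", spec$seed)),
         mask = msm_volume(mask, sp, sprintf("mask seed %d", spec$seed)))
  })
}

#' Default synthetic scanner profiles
#'
#' Four affine intensity profiles (gain, offset, noise sd) emulating a
#' multi-scanner cohort, so harmonization has real between-"scanner"
#' variation to remove.
#'
#' @return list of profile lists (`name`, `gain`, `offset`, `noise_sd`).
#' @export
default_scanner_profiles <- function() {
  list(list(name = "scannerA_1.5T", gain = 1.00, offset = 0.00, noise_sd = 0.05),
       list(name = "scannerB_3T",   gain = 1.35, offset = 0.25, noise_sd = 0.04),
       list(name = "scannerC_3T",   gain = 0.80, offset = -0.10, noise_sd = 0.05),
       list(name = "scannerD_1.5T", gain = 1.15, offset = 0.10, noise_sd = 0.07))
}

#' Generate a phantom cohort
#'
#' Subjects are assigned to scanner profiles round-robin; subject `i` uses
#' seed `template$seed + i`. With `out_dir` set, image and mask are written
#' as NIfTI with a JSON sidecar per subject (seed, profile, spec snapshot).
#'
#' @param n number of subjects.
#' @param template a [phantom_spec] used for every subject (seed and
#'   scanner shift are overridden per subject).
#' @param scanner_profiles list of profiles
#'   (default [default_scanner_profiles()]).
#' @param out_dir optional output directory.
#' @return list of subjects, each with `image`, `mask`, `profile`, `seed`
#'   (and file paths when written); invisibly when writing.
#' @export
generate_cohort <- function(n, template = phantom_spec(),
                            scanner_profiles = default_scanner_profiles(),
                            out_dir = NULL) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    prof <- scanner_profiles[[(i - 1L) %% length(scanner_profiles) + 1L]]
    spec_i <- template
    spec_i$seed <- template$seed + i
    spec_i$scanner_shift <- c(prof$gain, prof$offset)
    spec_i$noise_sd <- prof$noise_sd
    ph <- generate_phantom(spec_i)
    subj <- list(image = ph$image, mask = ph$mask, profile = prof$name,
                 seed = spec_i$seed)
    if (!is.null(out_dir)) {
      id <- sprintf("subj%03d", i)
      subj$image_path <- file.path(out_dir, paste0(id, "_img.nii.gz"))
      subj$mask_path <- file.path(out_dir, paste0(id, "_mask.nii.gz"))
      write_volume(ph$image, subj$image_path)
      write_volume(ph$mask, subj$mask_path)
      meta <- list(subject = id, seed = spec_i$seed, profile = prof,
                   shape = spec_i$shape, spacing = spec_i$spacing,
                   n_lesions = spec_i$n_lesions)
      jsonlite::write_json(meta, file.path(out_dir, paste0(id, ".json")),
                           auto_unbox = TRUE, digits = NA)
    }
    subjects[[i]] <- subj
  }
  if (is.null(out_dir)) subjects else invisible(subjects)
}
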