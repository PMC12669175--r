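# Segmentation evaluation: confusion counts, nine overlap/agreement ratios
# and the spacing-aware 95th-percentile Hausdorff distance.
#
# Degenerate-input conventions (so batch averaging is always defined):
#   Dice, JI, VS = 1 when both masks are empty, 0 when exactly one is;
#   Sen (Spe) = 1 when there are no positives (negatives) in the truth;
#   Kappa and MCC = 0 when a marginal is degenerate;
#   HD95 = 0 when both masks are empty, NA when exactly one is.

#' Voxel-wise confusion counts
#'
#' @param pred,truth binary label volumes ([msm_volume]s or arrays of
#'   identical shape).
#' @return list with integer fields TP, FP, FN, TN.
#' @export
confusion <- function(pred, truth) {
  if (is_volume(pred)) pred <- pred$data
  if (is_volume(truth)) truth <- truth$data
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth must have identical shapes", call. = FALSE)
  p <- pred != 0
  t <- truth != 0
  list(TP = sum(p & t), FP = sum(p & !t), FN = sum(!p & t), TN = sum(!p & !t))
}

#' Overlap and agreement metrics from confusion counts
#'
#' Dice, sensitivity, specificity, balanced accuracy, accuracy, Jaccard
#' index, Cohen's kappa, volumetric similarity and Matthews correlation
#' coefficient. The distance metric (`hd95`) is left `NA`; fill it with
#' [hd95()].
#'
#' @param c confusion counts from [confusion()].
#' @return list of class `metrics_report` with fields dice, sen, spe, bacc,
#'   acc, ji, kappa, vs, mcc, hd95.
#' @export
overlap_metrics <- function(c) {
  TP <- as.numeric(c$TP); FP <- as.numeric(c$FP)   # doubles: voxel-count
  FN <- as.numeric(c$FN); TN <- as.numeric(c$TN)   # products overflow ints
  n <- TP + FP + FN + TN
  dice <- if (2 * TP + FP + FN == 0) 1 else 2 * TP / (2 * TP + FP + FN)
  ji   <- if (TP + FP + FN == 0) 1 else TP / (TP + FP + FN)
  sen  <- if (TP + FN == 0) 1 else TP / (TP + FN)
  spe  <- if (TN + FP == 0) 1 else TN / (TN + FP)
  acc  <- (TP + TN) / n
  bacc <- (sen + spe) / 2
  vs   <- if (2 * TP + FP + FN == 0) 1 else 1 - abs(FP - FN) / (2 * TP + FP + FN)
  mcc_den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  mcc  <- if (mcc_den == 0) 0 else (TP * TN - FP * FN) / mcc_den
  po <- acc
  pe <- ((TP + FP) * (TP + FN) + (FN + TN) * (FP + TN)) / n^2
  kappa <- if (abs(1 - pe) < .Machine$double.eps) 0 else (po - pe) / (1 - pe)
  structure(list(dice = dice, sen = sen, spe = spe, bacc = bacc, acc = acc,
                 ji = ji, kappa = kappa, vs = vs, mcc = mcc,
                 hd95 = NA_real_),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  v <- unlist(x)
  cat("<metrics_report>\n")
  for (nm in names(v))
    cat(sprintf("  %-5s %s\n", nm,
                ifelse(is.na(v[nm]), "NA", sprintf("%.4f", v[nm]))))
  invisible(x)
}

# boundary voxels: foreground with at least one face-adjacent background
# (or out-of-grid) neighbour
boundary_voxels <- function(mask) {
  d <- dim(mask)
  m <- mask != 0
  b <- array(FALSE, d)
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    nb <- array(FALSE, d)            # neighbour-is-foreground; outside = bg
    n <- d[ax]
    if (n > 1L) {
      dst <- src <- lapply(d, seq_len)
      dst[[ax]] <- if (s == 1L) 1:(n - 1L) else 2:n
      src[[ax]] <- if (s == 1L) 2:n else 1:(n - 1L)
      nb[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    }
    b <- b | (m & !nb)
  }
  which(b, arr.ind = TRUE)
}

directed_distances <- function(from, to, spacing) {
  # for each row of `from`, min Euclidean mm distance to rows of `to`
  A <- sweep(from - 1, 2L, spacing, "*")
  B <- sweep(to - 1, 2L, spacing, "*")
  a2 <- rowSums(A^2)
  out <- numeric(nrow(A))
  chunk <- max(1L, floor(2e7 / nrow(A)))
  i <- 1L
  while (i <= nrow(B)) {
    j <- min(i + chunk - 1L, nrow(B))
    Bc <- B[i:j, , drop = FALSE]
    d2 <- outer(a2, rowSums(Bc^2), "+") - 2 * tcrossprod(A, Bc)
    mins <- apply(d2, 1L, min)
    out <- if (i == 1L) mins else pmin(out, mins)
    i <- j + 1L
  }
  sqrt(pmax(out, 0))
}

pctl_linear <- function(x, q) as.numeric(stats::quantile(x, q, type = 7))

#' 95th-percentile Hausdorff distance
#'
#' Symmetric 95% Hausdorff distance between the boundary voxel sets of two
#' binary masks, in physical millimetres: the maximum over both directions
#' of the linearly interpolated 95th percentile of boundary-to-boundary
#' nearest distances. Boundaries are foreground voxels with at least one
#' face-adjacent background neighbour (grid edges count as boundary).
#'
#' @param pred,truth binary label volumes of identical shape.
#' @param spacing mm voxel spacing triple (taken from `pred` when it is an
#'   [msm_volume] and `spacing` is missing).
#' @return Distance in mm; 0 when both masks are empty, `NA` when exactly
#'   one is.
#' @export
hd95 <- function(pred, truth, spacing = NULL) {
  if (is_volume(pred) && is.null(spacing)) spacing <- pred$spacing
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  if (any(spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  if (is_volume(pred)) pred <- pred$data
  if (is_volume(truth)) truth <- truth$data
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth must have identical shapes", call. = FALSE)
  pe <- !any(pred != 0); te <- !any(truth != 0)
  if (pe && te) return(0)
  if (pe || te) return(NA_real_)
  bp <- boundary_voxels(pred)
  bt <- boundary_voxels(truth)
  d1 <- pctl_linear(directed_distances(bp, bt, spacing), 0.95)
  d2 <- pctl_linear(directed_distances(bt, bp, spacing), 0.95)
  max(d1, d2)
}

#' All ten evaluation metrics for one mask pair
#'
#' @inheritParams hd95
#' @return A `metrics_report` with the distance field filled in.
#' @export
evaluate_masks <- function(pred, truth, spacing = NULL) {
  rep_ <- overlap_metrics(confusion(pred, truth))
  rep_$hd95 <- hd95(pred, truth, spacing)
  rep_
}

#' Evaluate directories of prediction/truth label volumes
#'
#' Pairs NIfTI files by sorted order, computes the ten metrics per subject
#' and optionally writes them as CSV (columns: subject then the ten
#' metrics). Per-subject metrics are summarized as mean and sd, matching
#' the usual "mean +/- sd" reporting.
#'
#' @param pred_dir,truth_dir directories of `.nii`/`.nii.gz` label volumes.
#' @param spacing `"auto"` (use each prediction's header spacing) or a mm
#'   triple.
#' @param out optional CSV output path.
#' @return data frame of per-subject metrics, with a `summary` attribute
#'   holding the mean and sd of each metric.
#' @export
evaluate_directories <- function(pred_dir, truth_dir, spacing = "auto",
                                 out = NULL) {
  list_niis <- function(d) sort(list.files(d, pattern = "\\.nii(\\.gz)?$",
                                           full.names = TRUE))
  pf <- list_niis(pred_dir); tf <- list_niis(truth_dir)
  if (length(pf) == 0L) stop("no NIfTI files in ", pred_dir, call. = FALSE)
  if (length(pf) != length(tf))
    stop("prediction/truth counts differ", call. = FALSE)
  rows <- lapply(seq_along(pf), function(i) {
    pv <- read_volume(pf[i]); tv <- read_volume(tf[i])
    sp <- if (identical(spacing, "auto")) pv$spacing else as.numeric(spacing)
    r <- evaluate_masks(pv$data, tv$data, sp)
    data.frame(subject = sub("\\.nii(\\.gz)?$", "", basename(pf[i])),
               as.data.frame(unclass(r)))
  })
  res <- do.call(rbind, rows)
  num <- res[, -1, drop = FALSE]
  attr(res, "summary") <- data.frame(
    metric = names(num),
    mean = vapply(num, function(v) mean(v, na.rm = TRUE), numeric(1)),
    sd = vapply(num, function(v) stats::sd(v, na.rm = TRUE), numeric(1)))
  if (!is.null(out)) utils::write.csv(res, out, row.names = FALSE)
  res
}
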