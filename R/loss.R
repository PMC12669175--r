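# Combined Dice + cross-entropy objective with deep supervision.
#
#   L_total = sum_i w_i * (1/2 L_CE + 1/2 L_Dice)      (levels i = 0, 1, ...)
#
# with raw level weights 1/2^i (full resolution first) normalized to sum to
# one. The Dice term is computed over the foreground class only — the lesion
# task is binary with severe class imbalance, and a background Dice would be
# saturated at ~1 regardless of lesion quality.

#' Loss configuration
#'
#' @param ce_weight weight of the cross-entropy term (default 1/2).
#' @param dice_weight weight of the Dice term (default 1/2).
#' @param epsilon Dice smoothing constant (default 1e-6).
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(ce_weight = 0.5, dice_weight = 0.5, epsilon = 1e-6) {
  if (ce_weight < 0 || dice_weight < 0 || epsilon <= 0)
    stop("weights must be >= 0 and epsilon > 0", call. = FALSE)
  structure(list(ce_weight = ce_weight, dice_weight = dice_weight,
                 epsilon = epsilon),
            class = "loss_config")
}

#' Soft Dice loss
#'
#' `1 - (2 sum(p*y) + eps) / (sum(p) + sum(y) + eps)`; bounded in `[0, 1]`
#' up to epsilon effects.
#'
#' @param p predicted foreground probabilities in `[0, 1]`.
#' @param y binary ground-truth labels (same length).
#' @param epsilon smoothing constant.
#' @return A single real.
#' @export
dice_loss <- function(p, y, epsilon = 1e-6) {
  p <- as.numeric(p); y <- as.numeric(y)
  if (length(p) != length(y))
    stop("p and y must have the same length", call. = FALSE)
  1 - (2 * sum(p * y) + epsilon) / (sum(p) + sum(y) + epsilon)
}

#' Binary cross-entropy loss
#'
#' Mean negative log-likelihood; probabilities are clamped to
#' `[clamp, 1 - clamp]` because the raw expression is unbounded at 0 and 1.
#'
#' @inheritParams dice_loss
#' @param clamp clamping floor (default 1e-7).
#' @return A single real.
#' @export
ce_loss <- function(p, y, clamp = 1e-7) {
  p <- pmin(pmax(as.numeric(p), clamp), 1 - clamp)
  y <- as.numeric(y)
  if (length(p) != length(y))
    stop("p and y must have the same length", call. = FALSE)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# nearest-neighbour down-sampling of a binary 3-D mask to a target shape
downsample_mask <- function(mask, target) {
  d <- dim(mask)
  if (all(d == target)) return(mask)
  idx <- lapply(1:3, function(ax) {
    g <- (seq_len(target[ax]) - 1) * d[ax] / target[ax]
    as.integer(round(pmin(g, d[ax] - 1))) + 1L
  })
  mask[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

level_weights <- function(n) {
  w <- 1 / 2^(seq_len(n) - 1)
  w / sum(w)
}

# foreground probability from class logits (2-channel softmax); the
# foreground class is the last channel
fg_prob <- function(logits) {
  nc <- dim(logits)[1]
  z <- array(logits[nc, , , , drop = FALSE] - logits[1, , , , drop = FALSE],
             dim(logits)[2:4])
  1 / (1 + exp(-z))
}

#' Deep-supervision total loss
#'
#' Combined Dice + cross-entropy evaluated at the full-resolution logits and
#' at every auxiliary resolution, with level weights `1/2^i` normalized to
#' sum to one; targets are matched to each auxiliary resolution by
#' nearest-neighbour down-sampling so labels stay binary.
#'
#' @param outputs a list with `logits` (`(num_classes, nx, ny, nz)` array)
#'   and optionally `aux` (list of lower-resolution logit arrays, ordered
#'   shallow to deep), as returned by [network_forward()].
#' @param target binary ground-truth mask: 3-D array or [msm_volume].
#' @param cfg a [loss_config].
#' @return A single real.
#' @export
total_loss <- function(outputs, target, cfg = loss_config()) {
  if (is_volume(target)) target <- target$data
  levels <- c(list(outputs$logits), outputs$aux)
  w <- level_weights(length(levels))
  tot <- 0
  for (i in seq_along(levels)) {
    lg <- levels[[i]]
    tg <- downsample_mask(target, dim(lg)[2:4])
    p <- fg_prob(lg)
    tot <- tot + w[i] * (cfg$ce_weight * ce_loss(p, tg) +
                         cfg$dice_weight * dice_loss(p, tg, cfg$epsilon))
  }
  tot
}

# loss + gradients with respect to every logit level
total_loss_grad <- function(outputs, target, cfg = loss_config(),
                            clamp = 1e-7) {
  if (is_volume(target)) target <- target$data
  levels <- c(list(outputs$logits), outputs$aux)
  w <- level_weights(length(levels))
  tot <- 0
  dlevels <- vector("list", length(levels))
  for (i in seq_along(levels)) {
    lg <- levels[[i]]
    tg <- as.numeric(downsample_mask(target, dim(lg)[2:4]))
    nvox <- length(tg)
    p <- as.numeric(fg_prob(lg))
    pc <- pmin(pmax(p, clamp), 1 - clamp)
    ce <- -mean(tg * log(pc) + (1 - tg) * log(1 - pc))
    eps <- cfg$epsilon
    num <- 2 * sum(p * tg) + eps
    den <- sum(p) + sum(tg) + eps
    dice <- 1 - num / den
    tot <- tot + w[i] * (cfg$ce_weight * ce + cfg$dice_weight * dice)
    # d loss / d p
    inside <- (p > clamp) & (p < 1 - clamp)
    dce_dp <- ifelse(inside, (-tg / pc + (1 - tg) / (1 - pc)) / nvox, 0)
    ddice_dp <- -(2 * tg * den - num) / den^2
    dp <- w[i] * (cfg$ce_weight * dce_dp + cfg$dice_weight * ddice_dp)
    # p = sigmoid(z_fg - z_bg)
    dz <- dp * p * (1 - p)
    dl <- array(0, dim(lg))
    nc <- dim(lg)[1]
    dl[nc, , , ] <- dz
    dl[1, , , ] <- -dz
    dlevels[[i]] <- dl
  }
  list(loss = tot, dlogits = dlevels[[1]],
       daux = if (length(dlevels) > 1L) dlevels[-1] else NULL)
}
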