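# Training loop: AdamW with decoupled weight decay, cosine learning-rate
# decay, deep-supervised Dice + cross-entropy loss, k-fold cross-validation
# and a pretrain -> fine-tune transfer workflow.

#' Training configuration
#'
#' @param epochs number of epochs (>= 1).
#' @param lr initial learning rate (default 0.001, cosine-decayed to 0 at
#'   the final epoch).
#' @param weight_decay AdamW decoupled weight decay (default 0.05).
#' @param batch_size subjects per gradient step (default 2).
#' @param seed RNG seed recorded in every artifact (default 1).
#' @param folds fold count for cross-validation (default 5).
#' @param fine_tune_from optional checkpoint path; training starts from its
#'   parameters with a fresh schedule.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 20L, lr = 1e-3, weight_decay = 0.05,
                         batch_size = 2L, seed = 1L, folds = 5L,
                         fine_tune_from = NULL) {
  epochs <- as.integer(epochs)
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  if (lr <= 0) stop("lr must be positive", call. = FALSE)
  structure(list(epochs = epochs, lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 folds = as.integer(folds), fine_tune_from = fine_tune_from),
            class = "train_config")
}

#' Cosine learning-rate schedule
#'
#' `lr0 * 0.5 * (1 + cos(pi * epoch / (epochs - 1)))` for 0-based `epoch`;
#' the first epoch runs at `lr0`, the last at 0.
#'
#' @param epoch 0-based epoch index.
#' @param epochs total epochs.
#' @param lr0 initial learning rate.
#' @return The learning rate for `epoch`.
#' @export
cosine_lr <- function(epoch, epochs, lr0 = 1e-3) {
  lr0 * 0.5 * (1 + cos(pi * epoch / max(epochs - 1L, 1L)))
}

adamw_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adamw_step <- function(state, theta, grad, lr, wd,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  theta <- theta - lr * (mhat / (sqrt(vhat) + eps) + wd * theta)
  list(state = state, theta = theta)
}

#' Balanced k-fold assignment
#'
#' @param n number of subjects.
#' @param k number of folds.
#' @param seed optional RNG seed.
#' @return Integer vector of length `n`; each subject appears in exactly one
#'   validation fold.
#' @export
kfold_split <- function(n, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

normalize_image <- function(x) {
  mu <- mean(x); sdv <- stats::sd(as.vector(x))
  if (is.finite(sdv) && sdv > 0) (x - mu) / sdv else x - mu
}

prepare_subject <- function(subj, spec) {
  img <- if (is_volume(subj$image)) subj$image$data else subj$image
  msk <- if (is_volume(subj$mask)) subj$mask$data else subj$mask
  x <- as_feature_grid(normalize_image(img))
  if (dim(x)[1] == 1L && spec$in_channels > 1L)
    x <- array(rep(x, spec$in_channels), dim = c(spec$in_channels, dim(x)[2:4]))
  tsr <- total_stride(spec)
  sp <- dim(x)[2:4]
  target <- vapply(1:3, function(ax) next_multiple(sp[ax], tsr[ax]), integer(1))
  x <- pad_spatial_fwd(x, target)$y
  mp <- array(0, target)
  mp[seq_len(sp[1]), seq_len(sp[2]), seq_len(sp[3])] <- msk
  list(x = x, mask = mp, orig_shape = sp)
}

validation_dice <- function(net, data) {
  if (length(data) == 0L) return(NA_real_)
  mean(vapply(data, function(subj) {
    img <- if (is_volume(subj$image)) subj$image
           else msm_volume(subj$image)
    msk <- if (is_volume(subj$mask)) subj$mask$data else subj$mask
    pred <- predict(net, img)$data
    cc <- confusion(pred, msk)
    if (cc$TP + cc$FP + cc$FN == 0) 1 else 2 * cc$TP / (2 * cc$TP + cc$FP + cc$FN)
  }, numeric(1)))
}

#' Train a segmentation network
#'
#' Runs AdamW with a cosine schedule on the deep-supervised combined loss.
#' All randomness (shuffling) is governed by `tc$seed`. A non-finite loss
#' aborts with diagnostics. When `tc$fine_tune_from` is set the checkpoint's
#' parameters replace `net`'s and the schedule restarts.
#'
#' @param net an `msm_network` from [build_network()].
#' @param data list of subjects, each `list(image = , mask = )` with
#'   [msm_volume]s or arrays.
#' @param tc a [train_config].
#' @param val_data optional held-out subjects; per-epoch validation Dice is
#'   logged.
#' @param loss_cfg a [loss_config].
#' @param verbose print per-epoch progress.
#' @return list with the trained `net` and `log`, a data frame with columns
#'   epoch, lr, train_loss, val_dice.
#' @export
run_training <- function(net, data, tc, val_data = NULL,
                         loss_cfg = loss_config(), verbose = FALSE) {
  if (!is.null(tc$fine_tune_from)) net <- load_checkpoint(tc$fine_tune_from)
  spec <- net$spec
  set.seed(tc$seed)
  subjects <- lapply(data, prepare_subject, spec = spec)
  theta <- param_unlist(net$params)
  opt <- adamw_init(length(theta))
  log <- data.frame(epoch = integer(), lr = numeric(),
                    train_loss = numeric(), val_dice = numeric())
  for (epoch in seq_len(tc$epochs) - 1L) {
    lr <- cosine_lr(epoch, tc$epochs, tc$lr)
    ord <- sample(length(subjects))
    epoch_loss <- 0
    i <- 1L
    while (i <= length(ord)) {
      batch <- ord[i:min(i + tc$batch_size - 1L, length(ord))]
      gsum <- NULL
      bloss <- 0
      for (s in batch) {
        sub <- subjects[[s]]
        fw <- network_forward(net, sub$x, want_cache = TRUE)
        lg <- total_loss_grad(list(logits = fw$logits, aux = fw$aux),
                              sub$mask, loss_cfg)
        if (!is.finite(lg$loss))
          stop(sprintf("non-finite loss (epoch %d, subject %d): aborting",
                       epoch, s), call. = FALSE)
        bw <- network_backward(net, fw$cache, lg$dlogits, lg$daux)
        gsum <- if (is.null(gsum)) bw$grads else param_add(gsum, bw$grads)
        bloss <- bloss + lg$loss
      }
      grad <- param_unlist(gsum) / length(batch)
      step <- adamw_step(opt, theta, grad, lr, tc$weight_decay)
      opt <- step$state
      theta <- step$theta
      if (!all(is.finite(theta)))
        stop("non-finite parameters after update: aborting", call. = FALSE)
      net$params <- param_relist(net$params, theta)
      epoch_loss <- epoch_loss + bloss
      i <- i + tc$batch_size
    }
    epoch_loss <- epoch_loss / length(subjects)
    vd <- if (!is.null(val_data)) validation_dice(net, val_data) else NA_real_
    log <- rbind(log, data.frame(epoch = epoch, lr = lr,
                                 train_loss = epoch_loss, val_dice = vd))
    if (verbose)
      message(sprintf("epoch %2d  lr %.5f  loss %.4f  val dice %s",
                      epoch, lr, epoch_loss,
                      ifelse(is.na(vd), "-", sprintf("%.3f", vd))))
  }
  list(net = net, log = log)
}

#' k-fold cross-validation
#'
#' Builds a fresh network per fold (seeded from `tc$seed + fold`), trains on
#' the in-fold subjects and validates on the held-out fold.
#'
#' @param spec a [network_spec].
#' @param data list of subjects (`list(image =, mask =)`).
#' @param tc a [train_config]; `tc$folds` folds are used.
#' @param out_dir optional directory for per-fold checkpoints and logs.
#' @param verbose print progress.
#' @return list with per-fold results (`net`, `log`, `val_dice`, indices)
#'   and `summary` (mean and sd of the fold validation Dice).
#' @export
run_cross_validation <- function(spec, data, tc, out_dir = NULL,
                                 verbose = FALSE) {
  assign_fold <- kfold_split(length(data), tc$folds, seed = tc$seed)
  folds <- vector("list", tc$folds)
  for (f in seq_len(tc$folds)) {
    tr <- which(assign_fold != f)
    va <- which(assign_fold == f)
    net <- build_network(spec, seed = tc$seed + f)
    res <- run_training(net, data[tr], tc, val_data = data[va],
                        verbose = verbose)
    vd <- utils::tail(res$log$val_dice, 1L)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      save_checkpoint(res$net, file.path(out_dir, sprintf("fold%d.rds", f)))
      utils::write.csv(res$log, file.path(out_dir, sprintf("fold%d_log.csv", f)),
                       row.names = FALSE)
    }
    folds[[f]] <- list(net = res$net, log = res$log, val_dice = vd,
                       train_idx = tr, val_idx = va)
  }
  dices <- vapply(folds, `[[`, numeric(1), "val_dice")
  list(folds = folds,
       fold_assignment = assign_fold,
       summary = c(mean = mean(dices), sd = stats::sd(dices)))
}
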