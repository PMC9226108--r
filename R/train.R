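#' Dice loss
#'
#' `1 - (2 * sum(pred * target) + eps) / (sum(pred) + sum(target) + eps)`,
#' the soft complement of the Dice similarity coefficient, computed over all
#' supplied elements (a slab or a whole batch).  On binary inputs it equals
#' `1 - DSC` up to the smoothing constant.
#'
#' @param pred numeric array of probabilities in [0, 1].
#' @param target binary array of the same shape.
#' @param eps smoothing constant guarding empty inputs.
#' @return scalar loss in [0, 1].
#' @export
dice_loss <- function(pred, target, eps = 1e-6) {
  if (!identical(dim(pred) %||% length(pred), dim(target) %||% length(target)))
    stopf("pred and target shapes differ")
  assert_binary(target, "target")
  1 - (2 * sum(pred * target) + eps) / (sum(pred) + sum(target) + eps)
}

# Gradient of dice_loss w.r.t. pred (same global-sum formulation).
dice_loss_grad <- function(pred, target, eps = 1e-6) {
  denom <- sum(pred) + sum(target) + eps
  num <- 2 * sum(pred * target) + eps
  (num / denom^2) - (2 * target) / denom
}

stack_batch <- function(samples, idx) {
  d <- dim(samples[[idx[1]]]$x)
  x <- array(0, c(d[1], d[2], d[3], length(idx)))
  y <- array(0, c(d[1], d[2], 1L, length(idx)))
  for (j in seq_along(idx)) {
    x[, , , j] <- samples[[idx[j]]]$x
    y[, , 1L, j] <- samples[[idx[j]]]$y
  }
  list(x = x, y = y)
}

eval_dice <- function(model, samples, batch_size) {
  if (length(samples) == 0L) return(NA_real_)
  num <- 0; den <- 0
  idx <- seq_along(samples)
  for (b in split(idx, ceiling(idx / batch_size))) {
    ba <- stack_batch(samples, b)
    prob <- unet_forward(model, ba$x, training = FALSE)$prob
    num <- num + 2 * sum(prob * ba$y)
    den <- den + sum(prob) + sum(ba$y)
  }
  if (den == 0) return(NA_real_)
  num / den
}

#' Train a U-Net on slab samples
#'
#' Adam optimization of the Dice loss over shuffled mini-batches, with
#' per-epoch soft-Dice curves on the training and validation sets.  The
#' checkpoint with the best validation Dice is retained as the returned
#' model.  Training and validation sets must not share patients; sharing is
#' rejected because the data split is defined at the patient level.
#'
#' @param model a [build_unet()] model.
#' @param train_samples list of samples, each
#'   `list(x = slab array in [0, 1], y = binary matrix, patient_id)`.
#' @param val_samples optional validation samples of the same form.
#' @param epochs,learning_rate,batch_size overrides of the model config.
#' @param verbose print per-epoch progress.
#' @return The trained `unet_model`; `$curves` holds a data frame with
#'   columns epoch, train_dice, val_dice, loss.
#' @export
train_unet <- function(model, train_samples, val_samples = list(),
                       epochs = NULL, learning_rate = NULL,
                       batch_size = NULL, verbose = FALSE) {
  cfg <- model$cfg
  epochs <- epochs %||% cfg$epochs
  lr <- learning_rate %||% cfg$learning_rate
  bs <- batch_size %||% cfg$batch_size
  if (length(train_samples) == 0L) stopf("training set is empty")
  tp <- unique(vapply(train_samples, function(s)
    s$patient_id %||% "unknown", character(1)))
  vp <- unique(vapply(val_samples, function(s)
    s$patient_id %||% "unknown", character(1)))
  both <- intersect(tp, vp)
  if (length(both) > 0)
    stopf("patients present in both training and validation: %s",
          paste(both, collapse = ", "))

  adam_m <- lapply(model$par, function(p) array(0, dim(p) %||% length(p)))
  adam_v <- adam_m
  b1 <- 0.9; b2 <- 0.999; aeps <- 1e-8
  step <- 0L
  curves <- data.frame(epoch = integer(), train_dice = numeric(),
                       val_dice = numeric(), loss = numeric())
  best <- list(dice = -Inf, par = model$par, bn = model$bn)
  n <- length(train_samples)
  with_seed(child_seed(cfg$seed, "train"), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (b in split(ord, ceiling(seq_along(ord) / bs))) {
        ba <- stack_batch(train_samples, b)
        fwd <- unet_forward(model, ba$x, training = TRUE)
        model$bn <- fwd$bn
        loss <- dice_loss(fwd$prob, ba$y)
        dprob <- dice_loss_grad(fwd$prob, ba$y)
        grads <- unet_backward(model, fwd, dprob)
        step <- step + 1L
        corr <- sqrt(1 - b2^step) / (1 - b1^step)
        for (nm in names(grads)) {
          adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * grads[[nm]]
          adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * grads[[nm]]^2
          model$par[[nm]] <- model$par[[nm]] -
            lr * corr * adam_m[[nm]] / (sqrt(adam_v[[nm]]) + aeps)
        }
        losses <- c(losses, loss)
      }
      vd <- eval_dice(model, val_samples, bs)
      curves <- rbind(curves,
                      data.frame(epoch = ep,
                                 train_dice = 1 - mean(losses),
                                 val_dice = vd, loss = mean(losses)))
      track <- if (is.na(vd)) 1 - mean(losses) else vd
      if (track >= best$dice)
        best <- list(dice = track, par = model$par, bn = model$bn)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val dice %s", ep,
                        mean(losses),
                        ifelse(is.na(vd), "-", sprintf("%.4f", vd))))
    }
  })
  model$par <- best$par
  model$bn <- best$bn
  model$curves <- curves
  model
}

#' Write training curves to CSV
#'
#' @param model a trained `unet_model`.
#' @param path output CSV (epoch, train_dice, val_dice, loss).
#' @return `path`, invisibly.
#' @export
write_training_curves <- function(model, path) {
  if (is.null(model$curves)) stopf("model has no training curves")
  utils::write.csv(model$curves, path, row.names = FALSE)
  invisible(path)
}

#' Predict the kidney mask for a whole stack
#'
#' Every informative frame (per [filter_blank_frames()]) is segmented through
#' its 3-frame slab; probabilities are resampled back to the analysis
#' geometry and binarized at the configured threshold.  Frames removed by
#' the blank-frame filter receive empty masks and zero probability.
#'
#' @param model a trained `unet_model`.
#' @param stack a standardized [us_stack()] whose in-plane size equals
#'   `cfg$target_inplane`.
#' @param cfg the [preprocess_config()] used at training time.
#' @return list with `prob` (H x W x Z probability volume), `mask`
#'   ([seg_mask()]), and `kept` (frame indices segmented).
#' @export
predict_stack <- function(model, stack, cfg = preprocess_config()) {
  d <- dim(stack$voxels)
  if (d[1] != cfg$target_inplane || d[2] != cfg$target_inplane)
    stopf("stack geometry %dx%d does not match the configured %d px frame",
          d[1], d[2], cfg$target_inplane)
  if (cfg$slab_size != model$cfg$slab_size)
    stopf("preprocess slab size %d does not match the model input %d",
          cfg$slab_size, model$cfg$slab_size)
  kept <- filter_blank_frames(stack, cfg)
  prob <- array(0, d)
  if (length(kept) > 0) {
    s <- cfg$slab_size
    bs <- model$cfg$batch_size
    for (b in split(kept, ceiling(seq_along(kept) / bs))) {
      x <- array(0, c(s, s, 3L, length(b)))
      for (j in seq_along(b))
        x[, , , j] <- make_slab(stack, b[j], cfg)$image / 255
      p <- unet_forward(model, x, training = FALSE)$prob
      for (j in seq_along(b))
        prob[, , b[j]] <- unresample_prob(p[, , 1L, j], d[1:2])
    }
  }
  # binarize kept frames only; filtered-out frames stay empty even at
  # threshold 0
  mask <- array(0L, d)
  for (k in kept)
    mask[, , k] <- (prob[, , k] >= model$cfg$binarize_threshold) * 1L
  list(prob = prob,
       mask = seg_mask(mask, stack$spacing),
       kept = kept)
}
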