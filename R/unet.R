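#' U-Net configuration
#'
#' Describes the six-level 2D U-Net used for slab-wise kidney segmentation:
#' encoder filters double per level from `base_filters` up to `max_filters`
#' (32, 64, 128, 256, 512, 1024 by default), the convolution kernel shrinks
#' from 7x7 at the top through 5x5 to 3x3 at the base and widens back
#' symmetrically in the decoder, and a sigmoid on the final 1x1 convolution
#' yields per-pixel kidney probabilities.  Training minimizes the Dice loss.
#'
#' The clinical-scale defaults (256 px slabs, learning rate 1e-6 -- a
#' fine-tuning regime that presumes pretrained weights -- and 200 epochs) can
#' be overridden for desk-scale CPU experiments, where a higher learning rate
#' and narrower filters are appropriate because training starts from random
#' initialization.
#'
#' @param levels number of resolution levels (default 6).
#' @param base_filters encoder filters at the first level (default 32).
#' @param max_filters cap on the doubling filter schedule (default 1024).
#' @param slab_size model input size in px; must be divisible by
#'   `2^(levels - 1)`.
#' @param in_channels slab channels (3 consecutive frames).
#' @param kernels optional explicit per-level kernel sizes (odd integers);
#'   default derives the 7/5/3 schedule for `levels` levels.
#' @param learning_rate Adam step size.
#' @param epochs training epochs.
#' @param batch_size slabs per optimization step.
#' @param binarize_threshold probability cut for mask binarization.
#' @param pretrained_weights_path optional checkpoint (written by
#'   [save_unet()]) loaded after construction -- the transfer-learning hook.
#' @param seed RNG seed for weight initialization and batch shuffling.
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(levels = 6L, base_filters = 32L, max_filters = 1024L,
                        slab_size = 256L, in_channels = 3L, kernels = NULL,
                        learning_rate = 1e-6, epochs = 200L, batch_size = 8L,
                        binarize_threshold = 0.5,
                        pretrained_weights_path = NULL, seed = 1L) {
  levels <- as.integer(levels)
  if (levels < 1L) stopf("levels must be at least 1")
  if (is.null(kernels)) kernels <- kernel_schedule(levels)
  if (length(kernels) != levels || any(kernels %% 2 == 0))
    stopf("kernels must give one odd size per level")
  structure(list(levels = levels, base_filters = as.integer(base_filters),
                 max_filters = as.integer(max_filters),
                 slab_size = as.integer(slab_size),
                 in_channels = as.integer(in_channels),
                 kernels = as.integer(kernels),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 binarize_threshold = binarize_threshold,
                 pretrained_weights_path = pretrained_weights_path,
                 seed = as.integer(seed)),
            class = "unet_config")
}

# 7 -> 5 -> 3 kernel schedule across `levels` encoder levels; the decoder
# mirrors it back up to 7x7 at the top.
kernel_schedule <- function(levels) {
  sort(rep_len(c(3L, 5L, 7L), levels), decreasing = TRUE)
}

unet_filters <- function(cfg) {
  pmin(cfg$base_filters * 2^(seq_len(cfg$levels) - 1L), cfg$max_filters)
}

he_init <- function(dims) {
  fan_in <- prod(dims[-length(dims)])
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

#' Build a U-Net model
#'
#' Instantiates all parameters (He initialization, seeded), batch-norm
#' buffers, and an architecture summary listing per-level kernel sizes and
#' filter counts together with the trainable parameter count.  If
#' `cfg$pretrained_weights_path` is set, weights are loaded from that
#' checkpoint after construction.
#'
#' @param cfg a [unet_config()].
#' @return An object of class `unet_model` with elements `cfg`, `par`
#'   (named flat list of parameter arrays), `bn` (running statistics),
#'   `summary` (data frame) and `n_params`.
#' @export
build_unet <- function(cfg = unet_config()) {
  if (cfg$slab_size %% 2^(cfg$levels - 1L) != 0L)
    stopf("slab size %d is not divisible by 2^%d; choose a compatible size",
          cfg$slab_size, cfg$levels - 1L)
  f <- unet_filters(cfg)
  L <- cfg$levels
  par <- list(); bn <- list()
  rows <- list()
  add_bn <- function(name, C) {
    par[[paste0(name, ".g")]] <<- rep(1, C)
    par[[paste0(name, ".beta")]] <<- rep(0, C)
    bn[[paste0(name, ".mean")]] <<- rep(0, C)
    bn[[paste0(name, ".var")]] <<- rep(1, C)
  }
  with_seed(cfg$seed, {
    for (i in seq_len(L)) {
      cin <- if (i == 1L) cfg$in_channels else f[i - 1L]
      k <- cfg$kernels[i]
      par[[sprintf("enc%d.w", i)]] <- he_init(c(k, k, cin, f[i]))
      par[[sprintf("enc%d.b", i)]] <- rep(0, f[i])
      add_bn(sprintf("enc%d", i), f[i])
      rows[[length(rows) + 1L]] <-
        data.frame(stage = "encoder", level = i, kernel = k,
                   in_channels = cin, out_channels = f[i])
    }
    for (i in rev(seq_len(L - 1L))) {
      par[[sprintf("up%d.w", i)]] <- he_init(c(2L, 2L, f[i + 1L], f[i]))
      par[[sprintf("up%d.b", i)]] <- rep(0, f[i])
      k <- cfg$kernels[i]
      par[[sprintf("dec%d.w", i)]] <- he_init(c(k, k, 2L * f[i], f[i]))
      par[[sprintf("dec%d.b", i)]] <- rep(0, f[i])
      add_bn(sprintf("dec%d", i), f[i])
      rows[[length(rows) + 1L]] <-
        data.frame(stage = "decoder", level = i, kernel = k,
                   in_channels = 2L * f[i], out_channels = f[i])
    }
    par[["final.w"]] <- he_init(c(1L, 1L, f[1L], 1L))
    par[["final.b"]] <- 0
  })
  rows[[length(rows) + 1L]] <-
    data.frame(stage = "head", level = 1L, kernel = 1L,
               in_channels = f[1L], out_channels = 1L)
  model <- structure(list(cfg = cfg, par = par, bn = bn,
                          summary = do.call(rbind, rows),
                          n_params = sum(vapply(par, length, numeric(1)))),
                     class = "unet_model")
  if (!is.null(cfg$pretrained_weights_path))
    model <- load_unet_weights(model, cfg$pretrained_weights_path)
  model
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("unet_model: %d levels, filters %s, %s parameters\n",
              x$cfg$levels,
              paste(unet_filters(x$cfg), collapse = "/"),
              format(x$n_params, big.mark = ",")))
  invisible(x)
}

#' Save / load U-Net checkpoints
#'
#' Checkpoints hold parameters, batch-norm running statistics, the config
#' and the training curves (if any) in R's native serialization.
#'
#' @param model a trained or untrained `unet_model`.
#' @param path checkpoint file.
#' @return `save_unet` returns `path` invisibly; `load_unet` returns the
#'   restored `unet_model`.
#' @export
save_unet <- function(model, path) {
  saveRDS(list(par = model$par, bn = model$bn, cfg = model$cfg,
               curves = model$curves), path)
  invisible(path)
}

#' @rdname save_unet
#' @export
load_unet <- function(path) {
  ck <- readRDS(path)
  model <- build_unet(ck$cfg)
  model$par <- ck$par
  model$bn <- ck$bn
  model$curves <- ck$curves
  model
}

# Transfer-learning hook: copy weights from a checkpoint into a freshly
# built model; shapes must agree.
load_unet_weights <- function(model, path) {
  ck <- readRDS(path)
  for (nm in names(model$par)) {
    if (is.null(ck$par[[nm]]) ||
        !identical(dim(ck$par[[nm]]), dim(model$par[[nm]])) &&
        length(ck$par[[nm]]) != length(model$par[[nm]]))
      stopf("pretrained checkpoint does not match architecture at '%s'", nm)
    model$par[[nm]] <- ck$par[[nm]]
  }
  for (nm in names(model$bn)) model$bn[[nm]] <- ck$bn[[nm]]
  model
}

# ---- forward / backward engine ------------------------------------------

# Batch norm over (H, W, N) per channel.  x is (H, W, C, N).
bn_fwd <- function(x, g, beta, rmean, rvar, training, eps = 1e-5,
                   momentum = 0.1) {
  d <- dim(x)
  xl <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
  if (training) {
    mu <- colMeans(xl)
    xc <- sweep(xl, 2, mu)
    v <- colMeans(xc^2)
    rmean <- (1 - momentum) * rmean + momentum * mu
    rvar <- (1 - momentum) * rvar + momentum * v
  } else {
    mu <- rmean
    xc <- sweep(xl, 2, mu)
    v <- rvar
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, invstd, "*")
  yl <- sweep(sweep(xhat, 2, g, "*"), 2, beta, "+")
  y <- aperm(array(yl, d[c(1, 2, 4, 3)]), c(1, 2, 4, 3))
  list(y = y, xhat = xhat, invstd = invstd, rmean = rmean, rvar = rvar)
}

bn_bwd <- function(dy, cache, g, dims) {
  d <- dims
  dyl <- matrix(aperm(dy, c(1, 2, 4, 3)), ncol = d[3])
  xhat <- cache$xhat
  dg <- colSums(dyl * xhat)
  dbeta <- colSums(dyl)
  m <- nrow(dyl)
  t1 <- sweep(dyl, 2, dbeta / m)
  t2 <- sweep(xhat, 2, dg / m, "*")
  dxl <- sweep(t1 - t2, 2, g * cache$invstd, "*")
  aperm(array(dxl, d[c(1, 2, 4, 3)]), c(1, 2, 4, 3))
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# Full forward pass.  x: (S, S, C, N) in [0, 1].  Returns probabilities and,
# when training, every cache needed by unet_backward().
unet_forward <- function(model, x, training = FALSE) {
  cfg <- model$cfg
  L <- cfg$levels
  par <- model$par
  cache <- list(x = x)
  skips <- vector("list", L)
  h <- x
  for (i in seq_len(L)) {
    nm <- sprintf("enc%d", i)
    z <- cpp_conv2d_fwd(h, par[[paste0(nm, ".w")]], par[[paste0(nm, ".b")]])
    bno <- bn_fwd(z, par[[paste0(nm, ".g")]], par[[paste0(nm, ".beta")]],
                  model$bn[[paste0(nm, ".mean")]],
                  model$bn[[paste0(nm, ".var")]], training)
    if (training) {
      model$bn[[paste0(nm, ".mean")]] <- bno$rmean
      model$bn[[paste0(nm, ".var")]] <- bno$rvar
      cache[[paste0(nm, ".in")]] <- h
      cache[[paste0(nm, ".bn")]] <- bno[c("xhat", "invstd")]
      cache[[paste0(nm, ".mask")]] <- bno$y > 0
    }
    a <- bno$y * (bno$y > 0)
    skips[[i]] <- a
    if (i < L) {
      mp <- cpp_maxpool2_fwd(a)
      if (training) cache[[paste0(nm, ".poolidx")]] <- mp$idx
      h <- mp$y
    } else h <- a
  }
  for (i in rev(seq_len(L - 1L))) {
    nm <- sprintf("dec%d", i)
    up <- sprintf("up%d", i)
    if (training) cache[[paste0(up, ".in")]] <- h
    u <- cpp_upconv2_fwd(h, par[[paste0(up, ".w")]], par[[paste0(up, ".b")]])
    cc <- concat_ch(skips[[i]], u)
    if (training) cache[[paste0(nm, ".in")]] <- cc
    z <- cpp_conv2d_fwd(cc, par[[paste0(nm, ".w")]], par[[paste0(nm, ".b")]])
    bno <- bn_fwd(z, par[[paste0(nm, ".g")]], par[[paste0(nm, ".beta")]],
                  model$bn[[paste0(nm, ".mean")]],
                  model$bn[[paste0(nm, ".var")]], training)
    if (training) {
      model$bn[[paste0(nm, ".mean")]] <- bno$rmean
      model$bn[[paste0(nm, ".var")]] <- bno$rvar
      cache[[paste0(nm, ".bn")]] <- bno[c("xhat", "invstd")]
      cache[[paste0(nm, ".mask")]] <- bno$y > 0
    }
    h <- bno$y * (bno$y > 0)
  }
  if (training) cache[["final.in"]] <- h
  logits <- cpp_conv2d_fwd(h, par[["final.w"]],
                           par[["final.b"]])
  prob <- 1 / (1 + exp(-logits))
  list(prob = prob, cache = cache, bn = model$bn)
}

# Backward pass from dL/dprob; returns named gradients matching model$par.
unet_backward <- function(model, fwd, dprob) {
  cfg <- model$cfg
  L <- cfg$levels
  par <- model$par
  cache <- fwd$cache
  grads <- list()
  dlogits <- dprob * fwd$prob * (1 - fwd$prob)
  g <- cpp_conv2d_bwd(cache[["final.in"]], par[["final.w"]], dlogits)
  grads[["final.w"]] <- g$dw
  grads[["final.b"]] <- g$db
  dh <- g$dx
  dskips <- vector("list", L)
  for (i in seq_len(L - 1L)) {
    nm <- sprintf("dec%d", i)
    up <- sprintf("up%d", i)
    mask <- cache[[paste0(nm, ".mask")]]
    dz <- bn_bwd(dh * mask, cache[[paste0(nm, ".bn")]],
                 par[[paste0(nm, ".g")]], dim(mask))
    dyl <- matrix(aperm(dh * mask, c(1, 2, 4, 3)), ncol = dim(mask)[3])
    grads[[paste0(nm, ".g")]] <- colSums(dyl * cache[[paste0(nm, ".bn")]]$xhat)
    grads[[paste0(nm, ".beta")]] <- colSums(dyl)
    cg <- cpp_conv2d_bwd(cache[[paste0(nm, ".in")]],
                         par[[paste0(nm, ".w")]], dz)
    grads[[paste0(nm, ".w")]] <- cg$dw
    grads[[paste0(nm, ".b")]] <- cg$db
    f_i <- dim(cg$dx)[3] / 2L
    dskip <- cg$dx[, , seq_len(f_i), , drop = FALSE]
    du <- cg$dx[, , f_i + seq_len(f_i), , drop = FALSE]
    dskips[[i]] <- dskip
    ug <- cpp_upconv2_bwd(cache[[paste0(up, ".in")]],
                          par[[paste0(up, ".w")]], du)
    grads[[paste0(up, ".w")]] <- ug$dw
    grads[[paste0(up, ".b")]] <- ug$db
    dh <- ug$dx
  }
  # dh now flows into the base encoder level (i = L); deeper-level gradients
  # add the skip contributions on the way up.
  for (i in rev(seq_len(L))) {
    nm <- sprintf("enc%d", i)
    da <- if (i == L) dh else {
      pooled <- cpp_maxpool2_bwd(dh, cache[[paste0(nm, ".poolidx")]],
                                 dim(dskips[[i]])[1], dim(dskips[[i]])[2])
      pooled + dskips[[i]]
    }
    mask <- cache[[paste0(nm, ".mask")]]
    dyl <- matrix(aperm(da * mask, c(1, 2, 4, 3)), ncol = dim(mask)[3])
    grads[[paste0(nm, ".g")]] <- colSums(dyl * cache[[paste0(nm, ".bn")]]$xhat)
    grads[[paste0(nm, ".beta")]] <- colSums(dyl)
    dz <- bn_bwd(da * mask, cache[[paste0(nm, ".bn")]],
                 par[[paste0(nm, ".g")]], dim(mask))
    cg <- cpp_conv2d_bwd(cache[[paste0(nm, ".in")]],
                         par[[paste0(nm, ".w")]], dz)
    grads[[paste0(nm, ".w")]] <- cg$dw
    grads[[paste0(nm, ".b")]] <- cg$db
    dh <- cg$dx
  }
  grads
}
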