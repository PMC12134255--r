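# Residual U-Net nuclear segmenter. Norm-free pre-activation residual blocks,
# 2x max-pool downsampling, nearest-neighbor-upsample + conv upsampling, skip
# concatenation, sigmoid head. Trained with the hybrid BCE-Dice objective,
# Adam, and a step-decay learning-rate schedule.

#' ResUnet architecture configuration
#'
#' @param in_channels input channels (3 for RGB).
#' @param out_channels output channels (1: nucleus probability).
#' @param depth number of encoder levels, each halving resolution (>= 2).
#' @param base_channels channels at the first level (>= 8); doubled per level.
#' @param use_residual_blocks add the residual shortcut in each double-conv
#'   block (default TRUE).
#' @return object of class `resunet_config`.
#' @export
resunet_config <- function(in_channels = 3, out_channels = 1, depth = 4,
                           base_channels = 32, use_residual_blocks = TRUE) {
  if (depth < 2) stopf("depth must be >= 2")
  if (base_channels < 8) stopf("base_channels must be >= 8")
  structure(list(in_channels = in_channels, out_channels = out_channels,
                 depth = depth, base_channels = base_channels,
                 use_residual_blocks = use_residual_blocks),
            class = "resunet_config")
}

#' Segmentation training configuration
#'
#' Defaults mirror the reference protocol: 100 epochs of Adam with the
#' learning rate multiplied by `lr_gamma = 0.1` every `lr_step = 30` epochs,
#' BCE and Dice terms weighted 1:1, and seeds drawn from \{21, 42, 84\}.
#'
#' @param epochs training epochs.
#' @param initial_lr initial Adam learning rate.
#' @param lr_step epochs between learning-rate decays.
#' @param lr_gamma multiplicative decay factor in (0, 1\].
#' @param seed RNG seed controlling all training randomness.
#' @param bce_weight,dice_weight loss term weights (>= 0, not both 0).
#' @param batch_size minibatch size.
#' @param augment named logical vector with `rotate`, `flip`, `intensity`.
#' @param threshold probability threshold for validation masks.
#' @return object of class `seg_train_config`.
#' @export
seg_train_config <- function(epochs = 100, initial_lr = 1e-3, lr_step = 30,
                             lr_gamma = 0.1, seed = 42,
                             bce_weight = 1, dice_weight = 1, batch_size = 4,
                             augment = c(rotate = TRUE, flip = TRUE,
                                         intensity = TRUE),
                             threshold = 0.5) {
  if (lr_gamma <= 0 || lr_gamma > 1) stopf("lr_gamma must be in (0, 1]")
  if (bce_weight < 0 || dice_weight < 0 || (bce_weight == 0 && dice_weight == 0))
    stopf("loss weights must be >= 0 and not both zero")
  structure(list(epochs = epochs, initial_lr = initial_lr, lr_step = lr_step,
                 lr_gamma = lr_gamma, seed = as.integer(seed),
                 bce_weight = bce_weight, dice_weight = dice_weight,
                 batch_size = batch_size, augment = augment,
                 threshold = threshold),
            class = "seg_train_config")
}

#' Step-decay learning-rate schedule
#'
#' `initial_lr * lr_gamma ^ floor(epoch / lr_step)`; e.g. with the defaults
#' the rate drops by 10x at epochs 30, 60, 90.
#'
#' @param epoch zero-based epoch index.
#' @param initial_lr starting rate.
#' @param lr_step decay interval in epochs.
#' @param lr_gamma decay factor.
#' @return learning rate for that epoch.
#' @export
step_lr <- function(epoch, initial_lr = 1e-3, lr_step = 30, lr_gamma = 0.1) {
  stopifnot(epoch >= 0)
  initial_lr * lr_gamma^(epoch %/% lr_step)
}

# encoder channel widths per level
resunet_channels <- function(config) config$base_channels * 2^(seq_len(config$depth) - 1)

#' Build a ResUnet model with freshly initialized weights
#'
#' Maps H x W x 3 inputs (H, W divisible by `2^depth`) to an H x W
#' probability map through a final sigmoid.
#'
#' @param config a [resunet_config()].
#' @param seed seed for weight initialization.
#' @return object of class `resunet` (config + named parameter list).
#' @export
build_resunet <- function(config = resunet_config(), seed = 42) {
  stopifnot(inherits(config, "resunet_config"))
  chs <- resunet_channels(config)
  d <- config$depth
  params <- list()
  with_seed(seed, {
    add_conv <- function(name, k, cin, cout) {
      params[[paste0(name, ".W")]] <<- he_conv(k, cin, cout)
      params[[paste0(name, ".b")]] <<- numeric(cout)
    }
    add_block <- function(name, cin, cout) {
      add_conv(paste0(name, ".c1"), 3, cin, cout)
      add_conv(paste0(name, ".c2"), 3, cout, cout)
      if (cin != cout) add_conv(paste0(name, ".p"), 1, cin, cout)
    }
    add_conv("stem", 3, config$in_channels, chs[1])
    for (i in seq_len(d))
      add_block(paste0("enc", i), if (i == 1) chs[1] else chs[i - 1], chs[i])
    add_block("bott", chs[d], 2 * chs[d])
    for (i in rev(seq_len(d))) {
      prev <- if (i == d) 2 * chs[d] else chs[i + 1]
      add_conv(paste0("dec", i, ".up"), 3, prev, chs[i])
      add_block(paste0("dec", i), 2 * chs[i], chs[i])
    }
    add_conv("head", 1, chs[1], config$out_channels)
  })
  structure(list(config = config, params = params, seed = seed), class = "resunet")
}

#' Total trainable parameter count of a model
#'
#' @param model a model object with a `params` list.
#' @return integer count.
#' @export
n_parameters <- function(model) sum(vapply(model$params, length, integer(1)))

# residual double-conv block forward; returns out + caches
block_fwd <- function(params, name, x, residual) {
  a1 <- relu_fwd(x)
  c1 <- conv_fwd(a1$out, params[[paste0(name, ".c1.W")]],
                 params[[paste0(name, ".c1.b")]])
  a2 <- relu_fwd(c1$out)
  c2 <- conv_fwd(a2$out, params[[paste0(name, ".c2.W")]],
                 params[[paste0(name, ".c2.b")]])
  out <- c2$out
  pcache <- NULL
  if (residual) {
    pw <- params[[paste0(name, ".p.W")]]
    if (!is.null(pw)) {
      pj <- conv_fwd(x, pw, params[[paste0(name, ".p.b")]], 1L, 0L)
      out <- out + pj$out
      pcache <- pj$cache
    } else out <- out + x
  }
  list(out = out, cache = list(a1 = a1$cache, c1 = c1$cache, a2 = a2$cache,
                               c2 = c2$cache, p = pcache, residual = residual,
                               has_proj = !is.null(params[[paste0(name, ".p.W")]])))
}

block_bwd <- function(params, name, dout, cache, grads) {
  dx <- 0
  if (cache$residual) {
    if (cache$has_proj) {
      pb <- conv_bwd(dout, cache$p, params[[paste0(name, ".p.W")]])
      grads[[paste0(name, ".p.W")]] <- pb$dW
      grads[[paste0(name, ".p.b")]] <- pb$db
      dx <- pb$dx
    } else dx <- dout
  }
  b2 <- conv_bwd(dout, cache$c2, params[[paste0(name, ".c2.W")]])
  grads[[paste0(name, ".c2.W")]] <- b2$dW
  grads[[paste0(name, ".c2.b")]] <- b2$db
  da2 <- relu_bwd(b2$dx, cache$a2)
  b1 <- conv_bwd(da2, cache$c1, params[[paste0(name, ".c1.W")]])
  grads[[paste0(name, ".c1.W")]] <- b1$dW
  grads[[paste0(name, ".c1.b")]] <- b1$db
  dx <- dx + relu_bwd(b1$dx, cache$a1)
  list(dx = dx, grads = grads)
}

resunet_forward <- function(model, x) {
  cfg <- model$config; p <- model$params
  d <- cfg$depth
  if (any(dim(x)[1:2] %% 2^d != 0))
    stopf(paste0("input dims [%d x %d] not divisible by 2^depth = %d; ",
                 "use resize_to_multiple() first"),
          dim(x)[1], dim(x)[2], 2^d)
  caches <- list()
  st <- conv_fwd(x, p$stem.W, p$stem.b)
  caches$stem <- st$cache
  h <- st$out
  skips <- list()
  for (i in seq_len(d)) {
    bf <- block_fwd(p, paste0("enc", i), h, cfg$use_residual_blocks)
    caches[[paste0("enc", i)]] <- bf$cache
    skips[[i]] <- bf$out
    mp <- maxpool_fwd(bf$out, 2L, 2L, 0L)
    caches[[paste0("pool", i)]] <- mp$cache
    h <- mp$out
  }
  bt <- block_fwd(p, "bott", h, cfg$use_residual_blocks)
  caches$bott <- bt$cache
  h <- bt$out
  for (i in rev(seq_len(d))) {
    up <- upsample2_fwd(h)
    uc <- conv_fwd(up, p[[paste0("dec", i, ".up.W")]],
                   p[[paste0("dec", i, ".up.b")]])
    caches[[paste0("dec", i, ".up")]] <- uc$cache
    c1 <- dim(uc$out)[3]; c2 <- dim(skips[[i]])[3]
    cat_ <- array(0, c(dim(uc$out)[1:2], c1 + c2, dim(uc$out)[4]))
    cat_[, , seq_len(c1), ] <- uc$out
    cat_[, , c1 + seq_len(c2), ] <- skips[[i]]
    caches[[paste0("dec", i, ".ncat")]] <- dim(uc$out)[3]
    bf <- block_fwd(p, paste0("dec", i), cat_, cfg$use_residual_blocks)
    caches[[paste0("dec", i)]] <- bf$cache
    h <- bf$out
  }
  hd <- conv_fwd(h, p$head.W, p$head.b, 1L, 0L)
  caches$head <- hd$cache
  prob <- 1 / (1 + exp(-hd$out))
  list(prob = prob, cache = caches)
}

# backward from d(loss)/d(logit); returns named gradient list
resunet_backward <- function(model, dlogit, caches) {
  cfg <- model$config; p <- model$params
  d <- cfg$depth
  grads <- list()
  hb <- conv_bwd(dlogit, caches$head, p$head.W)
  grads$head.W <- hb$dW; grads$head.b <- hb$db
  dh <- hb$dx
  dskips <- vector("list", d)
  for (i in seq_len(d)) {
    bb <- block_bwd(p, paste0("dec", i), dh, caches[[paste0("dec", i)]], grads)
    grads <- bb$grads
    ncat <- caches[[paste0("dec", i, ".ncat")]]
    dcat <- bb$dx
    dup_out <- dcat[, , seq_len(ncat), , drop = FALSE]
    dskips[[i]] <- dcat[, , (ncat + 1):dim(dcat)[3], , drop = FALSE]
    ub <- conv_bwd(dup_out, caches[[paste0("dec", i, ".up")]],
                   p[[paste0("dec", i, ".up.W")]])
    grads[[paste0("dec", i, ".up.W")]] <- ub$dW
    grads[[paste0("dec", i, ".up.b")]] <- ub$db
    dh <- upsample2_bwd(ub$dx)
  }
  bb <- block_bwd(p, "bott", dh, caches$bott, grads)
  grads <- bb$grads
  dh <- bb$dx
  for (i in rev(seq_len(d))) {
    dpool <- maxpool_bwd(dh, caches[[paste0("pool", i)]])
    dpool <- dpool + dskips[[i]]
    bb <- block_bwd(p, paste0("enc", i), dpool, caches[[paste0("enc", i)]], grads)
    grads <- bb$grads
    dh <- bb$dx
  }
  sb <- conv_bwd(dh, caches$stem, p$stem.W)
  grads$stem.W <- sb$dW; grads$stem.b <- sb$db
  grads
}

#' Hybrid BCE-Dice segmentation loss
#'
#' `bce_weight * BCE(pred, targ) + dice_weight * (1 - soft_dice(pred, targ))`.
#' The BCE term is the pixel mean with probabilities clamped to
#' `[1e-7, 1 - 1e-7]`; the soft Dice term uses real-valued predictions in the
#' overlap formula with the global smooth constant.
#'
#' @param pred probability raster in \[0, 1\].
#' @param targ binary raster of the same shape.
#' @param bce_weight,dice_weight term weights (default 1 each).
#' @param smooth Dice smoothing constant.
#' @return non-negative scalar loss.
#' @export
bce_dice_loss <- function(pred, targ, bce_weight = 1, dice_weight = 1,
                          smooth = 1e-32) {
  check_same_shape(pred, targ)
  if (any(pred < 0) || any(pred > 1)) stopf("pred must lie in [0, 1]")
  if (!is_binary(targ)) stopf("targ must be binary")
  p <- clamp(pred, 1e-7, 1 - 1e-7)
  bce <- -mean(targ * log(p) + (1 - targ) * log(1 - p))
  bce_weight * bce + dice_weight * (1 - dice(pred, targ, smooth))
}

# gradient of bce_dice_loss w.r.t. pred (probabilities)
bce_dice_grad <- function(pred, targ, bce_weight = 1, dice_weight = 1,
                          smooth = 1e-32) {
  p <- clamp(pred, 1e-7, 1 - 1e-7)
  n <- length(pred)
  dbce <- (-targ / p + (1 - targ) / (1 - p)) / n
  I <- sum(pred * targ); S <- sum(pred) + sum(targ)
  ddice <- -(2 * targ * (S + smooth) - (2 * I + smooth)) / (S + smooth)^2
  bce_weight * dbce + dice_weight * ddice
}

# gradient w.r.t. the pre-sigmoid logit. The BCE part uses the closed form
# (p - t) / n, which stays finite when the sigmoid saturates (chaining the
# clamped-probability gradient through p(1-p) underflows to zero there and
# freezes training); the Dice part is bounded and chained normally.
bce_dice_grad_logit <- function(prob, targ, bce_weight = 1, dice_weight = 1,
                                smooth = 1e-32) {
  n <- length(prob)
  I <- sum(prob * targ); S <- sum(prob) + sum(targ)
  ddice <- -(2 * targ * (S + smooth) - (2 * I + smooth)) / (S + smooth)^2
  bce_weight * (prob - targ) / n + dice_weight * ddice * prob * (1 - prob)
}

#' Seeded data augmentation for a labeled sample
#'
#' Independently samples a rotation in \{0, 90, 180, 270\} degrees, horizontal
#' and vertical flips, and a multiplicative intensity jitter uniform in
#' \[0.9, 1.1\] (image only, clipped to \[0, 255\]). The identical geometric
#' transform is applied to image and mask; the mask is never touched by the
#' intensity jitter.
#'
#' @param sample a [labeled_image()] with image and mask.
#' @param seed integer seed; identical seeds give identical outputs.
#' @param rotate,flip,intensity enable the corresponding transform family.
#' @return augmented `labeled_image`.
#' @export
augment <- function(sample, seed, rotate = TRUE, flip = TRUE, intensity = TRUE) {
  stopifnot(inherits(sample, "labeled_image"), !is.null(sample$mask))
  with_seed(seed, {
    k <- if (rotate) sample.int(4L, 1L) - 1L else 0L
    fh <- flip && runif(1) < 0.5
    fv <- flip && runif(1) < 0.5
    fac <- if (intensity) runif(1, 0.9, 1.1) else 1
    rot90m <- function(m, k) {
      for (j in seq_len(k %% 4L)) m <- t(m)[ncol(m):1, , drop = FALSE]
      m
    }
    geo <- function(m) {
      m <- rot90m(m, k)
      if (fh) m <- m[, ncol(m):1, drop = FALSE]
      if (fv) m <- m[nrow(m):1, , drop = FALSE]
      m
    }
    img <- sample$image
    chs <- lapply(1:3, function(c) geo(img[, , c]))
    img <- array(c(chs[[1]], chs[[2]], chs[[3]]), c(dim(chs[[1]]), 3))
    if (fac != 1) img <- round_half_up(clamp(img * fac, 0, 255))
    labeled_image(img, geo(sample$mask), sample$label, sample$id)
  })
}

#' Predict a binary nuclear mask for one image
#'
#' @param model trained `resunet`.
#' @param image H x W x 3 array in \[0, 255\], dims divisible by `2^depth`.
#' @param threshold probability threshold (default 0.5); pixels with
#'   probability >= threshold are foreground.
#' @return H x W binary matrix.
#' @export
predict_mask <- function(model, image, threshold = 0.5) {
  stopifnot(inherits(model, "resunet"))
  d <- check_rgb(image)
  x <- array(image / 255, c(d, 1))
  pr <- resunet_forward(model, x)$prob[, , 1, 1]
  (pr >= threshold) * 1
}

# normalize a samples argument: list of labeled_image, or a manifest
as_samples <- function(x) {
  if (is.character(x)) x <- read_manifest(x)
  if (is.data.frame(x)) {
    return(lapply(seq_len(nrow(x)), function(i) {
      labeled_image(read_image(x$image[i]),
                    if (!is.null(x$mask)) read_mask(x$mask[i]) else NULL,
                    if (!is.null(x$label)) x$label[i] else NULL,
                    x$id[i])
    }))
  }
  if (inherits(x, "labeled_image")) return(list(x))
  x
}

#' Train a ResUnet nuclear segmenter
#'
#' Adam with the step-decay schedule, hybrid BCE-Dice loss, optional
#' augmentation, per-epoch validation metrics (Dice, Jaccard, Hausdorff), and
#' best-by-validation-Dice checkpointing. All randomness derives from
#' `train_config$seed`, so identical calls give identical histories.
#'
#' @param train_set,val_set lists of [labeled_image()] (with masks) or
#'   manifests.
#' @param config a [resunet_config()].
#' @param train_config a [seg_train_config()].
#' @param verbose print per-epoch progress.
#' @return object of class `seg_fit`: `model` (best checkpoint), `final_model`,
#'   `history` data.frame (`epoch,loss,val_dice,val_jaccard,val_hausdorff,lr`),
#'   `best_epoch`.
#' @export
train_segmentation <- function(train_set, val_set,
                               config = resunet_config(),
                               train_config = seg_train_config(),
                               verbose = FALSE) {
  train_set <- as_samples(train_set)
  val_set <- as_samples(val_set)
  if (length(train_set) == 0L) stopf("empty training set")
  if (!all(vapply(train_set, function(s) !is.null(s$mask), logical(1))))
    stopf("all training samples need masks")
  tc <- train_config
  model <- build_resunet(config, seed = tc$seed)
  opt <- adam_init(model$params)
  aug <- tc$augment
  hist_rows <- vector("list", tc$epochs)
  best <- list(dice = -Inf, params = model$params, epoch = NA_integer_)
  with_seed(derive_seed(tc$seed, 777L), {
    for (epoch in seq_len(tc$epochs) - 1L) {
      lr <- step_lr(epoch, tc$initial_lr, tc$lr_step, tc$lr_gamma)
      ord <- sample.int(length(train_set))
      losses <- c()
      for (bs in split(ord, ceiling(seq_along(ord) / tc$batch_size))) {
        xs <- lapply(bs, function(i) {
          s <- train_set[[i]]
          if (any(aug)) {
            s <- augment(s, derive_seed(tc$seed, epoch * 10000L + i),
                         rotate = isTRUE(aug[["rotate"]]),
                         flip = isTRUE(aug[["flip"]]),
                         intensity = isTRUE(aug[["intensity"]]))
          }
          s
        })
        hw <- dim(xs[[1]]$image)[1:2]
        x <- array(0, c(hw, 3, length(xs)))
        t_ <- array(0, c(hw, 1, length(xs)))
        for (j in seq_along(xs)) {
          x[, , , j] <- xs[[j]]$image / 255
          t_[, , 1, j] <- xs[[j]]$mask
        }
        fw <- resunet_forward(model, x)
        loss <- bce_dice_loss(fw$prob, t_, tc$bce_weight, tc$dice_weight)
        losses <- c(losses, loss)
        dlogit <- bce_dice_grad_logit(fw$prob, t_, tc$bce_weight, tc$dice_weight)
        grads <- resunet_backward(model, dlogit, fw$cache)
        st <- adam_step(model$params, grads, opt, lr)
        model$params <- st$params; opt <- st$state
      }
      vm <- evaluate_segmentation(model, val_set, threshold = tc$threshold)
      hist_rows[[epoch + 1L]] <- data.frame(
        epoch = epoch, loss = mean(losses), val_dice = vm$dice,
        val_jaccard = vm$jaccard, val_hausdorff = vm$hausdorff, lr = lr)
      if (!is.na(vm$dice) && vm$dice > best$dice) {
        best <- list(dice = vm$dice, params = model$params, epoch = epoch)
      }
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val dice %.4f  lr %g",
                        epoch, mean(losses), vm$dice, lr))
    }
  })
  best_model <- model
  best_model$params <- best$params
  structure(list(model = best_model, final_model = model,
                 history = do.call(rbind, hist_rows),
                 best_epoch = best$epoch, config = config,
                 train_config = tc),
            class = "seg_fit")
}

#' Mean segmentation metrics of a model over a sample set
#'
#' @param model trained `resunet`.
#' @param samples list of [labeled_image()] with masks.
#' @param threshold probability threshold.
#' @return list with mean `dice`, `jaccard`, `hausdorff` (directed; NA pairs
#'   dropped).
#' @export
evaluate_segmentation <- function(model, samples, threshold = 0.5) {
  samples <- as_samples(samples)
  reps <- lapply(samples, function(s) {
    pm <- predict_mask(model, s$image, threshold)
    segmentation_report(pm, s$mask)
  })
  list(dice = mean(vapply(reps, `[[`, numeric(1), "dice")),
       jaccard = mean(vapply(reps, `[[`, numeric(1), "jaccard")),
       hausdorff = mean(vapply(reps, `[[`, numeric(1), "hausdorff"), na.rm = TRUE))
}

#' Save a model checkpoint (weights + config + seed)
#'
#' @param fit a `seg_fit`/`cls_fit` or bare model object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(fit, path) { saveRDS(fit, path); invisible(path) }

#' Load a checkpoint written by [save_checkpoint()]
#' @param path checkpoint file.
#' @return the saved object.
#' @export
load_checkpoint <- function(path) readRDS(path)
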