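# Training: learning-rate schedule, SGD loop with the augmentation
# pipeline, and inference helpers.

#' Training configuration
#'
#' SGD with momentum 0.9 and weight decay 5e-4; base learning rate 1e-2
#' reached through a quadratic warm-up over the first 5 epochs, then
#' dropped to 1e-3 and 1e-4 at the 60% and 85% marks of the total epochs.
#'
#' @param total_epochs training length in epochs.
#' @param base_lr,momentum,weight_decay optimiser settings.
#' @param warmup_epochs quadratic warm-up length.
#' @param lr_drop_points fractions of `total_epochs` at which the rate
#'   drops; `lr_drop_factors` are the multipliers of `base_lr` applied
#'   from each point on.
#' @param batch_size images per optimiser step.
#' @param input_size network input (H, W).
#' @param aug_stop_frac Mosaic/MixUp are disabled for the final fraction
#'   of training.
#' @param use_mosaic,use_mixup,use_hflip augmentation switches.
#' @param seed RNG seed for shuffling and augmentation.
#' @return a `train_config` list.
#' @export
train_config <- function(total_epochs = 50L, base_lr = 1e-2,
                         momentum = 0.9, weight_decay = 5e-4,
                         warmup_epochs = 5, lr_drop_points = c(0.6, 0.85),
                         lr_drop_factors = c(0.1, 0.01), batch_size = 16L,
                         input_size = c(640L, 640L), aug_stop_frac = 0.15,
                         use_mosaic = TRUE, use_mixup = TRUE,
                         use_hflip = TRUE, seed = 1L) {
  stopifnot(all(diff(lr_drop_points) > 0), all(lr_drop_points > 0),
            all(lr_drop_points < 1))
  structure(list(total_epochs = as.integer(total_epochs),
                 base_lr = base_lr, momentum = momentum,
                 weight_decay = weight_decay,
                 warmup_epochs = warmup_epochs,
                 lr_drop_points = lr_drop_points,
                 lr_drop_factors = lr_drop_factors,
                 batch_size = as.integer(batch_size),
                 input_size = as.integer(input_size),
                 aug_stop_frac = aug_stop_frac,
                 use_mosaic = use_mosaic, use_mixup = use_mixup,
                 use_hflip = use_hflip, seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a (fractional) epoch
#'
#' Quadratic warm-up `base_lr (epoch / warmup)^2` over the warm-up
#' period, then the base rate, dropped by the configured factors at the
#' 60% and 85% marks.
#'
#' @param epoch real-valued epoch in \[0, total_epochs\].
#' @param cfg a [train_config()].
#' @return the learning rate.
#' @export
#' @examples
#' lr_at(2.5, train_config(total_epochs = 100))  # 1e-2 * 0.25
lr_at <- function(epoch, cfg) {
  te <- cfg$total_epochs
  lr <- ifelse(epoch < cfg$warmup_epochs,
               cfg$base_lr * (epoch / cfg$warmup_epochs)^2,
               cfg$base_lr)
  for (i in seq_along(cfg$lr_drop_points)) {
    lr <- ifelse(epoch >= cfg$lr_drop_points[i] * te,
                 cfg$base_lr * cfg$lr_drop_factors[i], lr)
  }
  lr
}

# optimiser over the registered leaf modules
sgd_state <- function(model) {
  lapply(model$ctx$mods, function(m) {
    st <- list()
    for (f in intersect(c("w", "g", "b"), ls(m)))
      st[[f]] <- array(0, dim(as.array(m[[f]])))
    st
  })
}

zero_grads <- function(model) {
  for (m in model$ctx$mods)
    for (f in intersect(c("gw", "gg", "gb"), ls(m))) k_zero(m[[f]])
  invisible(NULL)
}

sgd_step <- function(model, state, lr, momentum, weight_decay) {
  gmap <- c(w = "gw", g = "gg", b = "gb")
  mods <- model$ctx$mods
  for (i in seq_along(mods)) {
    m <- mods[[i]]
    for (f in intersect(c("w", "g", "b"), ls(m))) {
      wd <- if (isTRUE(m$decay) && f == "w") weight_decay else 0
      k_sgd_step(m[[f]], m[[gmap[f]]], state[[i]][[f]], lr, momentum, wd)
    }
  }
  invisible(NULL)
}

# draw one augmented training sample at the network input size
draw_sample <- function(ds, tcfg, aug_on) {
  H <- tcfg$input_size[1]; W <- tcfg$input_size[2]
  fit <- function(s) {
    if (!all(dim(s$image) == c(H, W))) {
      sy <- H / nrow(s$image); sx <- W / ncol(s$image)
      b <- s$boxes
      if (nrow(b) > 0) b <- cbind(b[, 1] * sx, b[, 2] * sy,
                                  b[, 3] * sx, b[, 4] * sy)
      s <- list(image = resize_mat(s$image, H, W), boxes = b,
                is_empty = s$is_empty)
    }
    s
  }
  if (aug_on && tcfg$use_mosaic && runif(1) < 0.5) {
    idx <- sample(length(ds), 4, replace = length(ds) < 4)
    s <- mosaic(lapply(ds[idx], fit), c(H, W))
  } else {
    s <- fit(ds[[sample(length(ds), 1)]])
  }
  if (aug_on && tcfg$use_mixup && runif(1) < 0.3) {
    s2 <- fit(ds[[sample(length(ds), 1)]])
    s <- mixup(s, s2, runif(1, 0.35, 0.65))
  }
  if (tcfg$use_hflip && runif(1) < 0.5) s <- hflip(s)
  s
}

#' Train a detector
#'
#' SGD loop over a phantom (or COCO-read) dataset with the package's
#' augmentation pipeline (Mosaic, MixUp, horizontal flip; Mosaic and
#' MixUp are switched off for the final `aug_stop_frac` of training).
#' Deterministic for fixed seeds.
#'
#' @param model a [build_detector()] model whose input size matches
#'   `tcfg$input_size`.
#' @param ds dataset: list of annotated frames.
#' @param tcfg a [train_config()].
#' @param verbose print one line per epoch.
#' @return the model, with `$history` (per-epoch mean losses and the
#'   learning rate) attached.
#' @export
train_detector <- function(model, ds, tcfg, verbose = FALSE) {
  stopifnot(length(ds) > 0)
  if (!any(vapply(ds, function(s) nrow(s$boxes) > 0, logical(1))))
    stop("training set has no positive frames")
  set.seed(tcfg$seed)
  state <- sgd_state(model)
  steps_per_epoch <- max(1L, length(ds) %/% tcfg$batch_size)
  hist <- data.frame()
  for (ep in seq_len(tcfg$total_epochs)) {
    aug_on <- ep <= (1 - tcfg$aug_stop_frac) * tcfg$total_epochs
    ep_loss <- c(total = 0, reg = 0, cls = 0, conf = 0)
    n_seen <- 0L
    for (st in seq_len(steps_per_epoch)) {
      lr <- lr_at(ep - 1 + (st - 1) / steps_per_epoch, tcfg)
      zero_grads(model)
      bl <- 0
      for (bi in seq_len(tcfg$batch_size)) {
        s <- draw_sample(ds, tcfg, aug_on)
        outs <- model$forward(frame_to_input(s$image), training = TRUE)
        r <- detection_loss(outs, s$boxes, with_grad = TRUE)
        if (!is.finite(r$l_total))
          stop("non-finite loss at epoch ", ep, " step ", st)
        # scale gradients by 1/batch for a batch-mean objective
        g <- lapply(r$grads, function(gl)
          lapply(gl, function(a) a / tcfg$batch_size))
        model$backward(g)
        bl <- bl + r$l_total / tcfg$batch_size
        ep_loss <- ep_loss + c(r$l_total, r$l_reg, r$l_cls, r$l_conf)
        n_seen <- n_seen + 1L
      }
      sgd_step(model, state, lr, tcfg$momentum, tcfg$weight_decay)
    }
    ep_loss <- ep_loss / n_seen
    hist <- rbind(hist, data.frame(epoch = ep, l_total = ep_loss[1],
                                   l_reg = ep_loss[2], l_cls = ep_loss[3],
                                   l_conf = ep_loss[4],
                                   lr = lr_at(ep - 1, tcfg)))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f (reg %.3f cls %.3f conf %.3f) lr %.2g",
                      ep, ep_loss[1], ep_loss[2], ep_loss[3], ep_loss[4],
                      lr_at(ep - 1, tcfg)))
  }
  rownames(hist) <- NULL
  model$history <- hist
  invisible(model)
}

#' Run inference on one frame
#'
#' Forward pass in inference mode, decoding, score filtering and NMS.
#'
#' @param model a trained model.
#' @param image (H, W) intensity matrix (0-255) or (H, W, 3) array in
#'   \[0, 1\]; resized to the model input size if needed.
#' @param score_thresh confidence threshold (0.001 for evaluation, 0.25
#'   is a sensible reporting threshold).
#' @param nms_iou NMS IoU threshold.
#' @return detection data.frame (x1, y1, x2, y2, score, label), sorted by
#'   descending score, in the coordinates of the original image.
#' @export
detect <- function(model, image, score_thresh = 0.25, nms_iou = 0.65) {
  if (length(dim(image)) == 2L) {
    img <- image
  } else img <- image[, , 1] * 255
  H0 <- nrow(img); W0 <- ncol(img)
  Hm <- model$input_size[1]; Wm <- model$input_size[2]
  if (H0 != Hm || W0 != Wm) img <- resize_mat(img, Hm, Wm)
  outs <- model$forward(frame_to_input(img), training = FALSE)
  d <- decode_detections(outs, model$strides, score_thresh,
                         image_size = c(Hm, Wm))
  if (nrow(d) > 0) {
    keep <- nms(as.matrix(d[, 1:4]), d$score, nms_iou)
    d <- d[keep, , drop = FALSE]
    d[, c(1, 3)] <- d[, c(1, 3)] * W0 / Wm
    d[, c(2, 4)] <- d[, c(2, 4)] * H0 / Hm
  }
  rownames(d) <- NULL
  d
}

#' Save / load model weights
#'
#' Weights, normalisation statistics and the configuration are stored in
#' an RDS container with a documented layer-naming scheme (modules in
#' registration order).
#'
#' @param model a model.
#' @param path file path.
#' @return `load_weights` returns the model, invisibly.
#' @export
save_weights <- function(model, path) {
  wl <- lapply(model$ctx$mods, function(m) {
    out <- list(kind = m$kind)
    for (f in intersect(c("w", "g", "b", "rm", "rv"), ls(m)))
      out[[f]] <- m[[f]]
    out
  })
  saveRDS(list(cfg = model$cfg, input_size = model$input_size,
               weights = wl), path)
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(model, path) {
  obj <- readRDS(path)
  wl <- obj$weights
  if (length(wl) != length(model$ctx$mods))
    stop("checkpoint does not match the model architecture")
  for (i in seq_along(wl)) {
    m <- model$ctx$mods[[i]]
    for (f in intersect(c("w", "g", "b", "rm", "rv"), names(wl[[i]]))) {
      stopifnot(length(m[[f]]) == length(wl[[i]][[f]]))
      m[[f]] <- wl[[i]][[f]]
    }
  }
  invisible(model)
}
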