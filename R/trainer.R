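# Training and evaluation loop.
#
# Protocol: AdamW (lr0 = 1e-3, cosine annealing over a 300-epoch period down
# to 1e-5), batch size 2, combined cross-entropy + Dice loss, and geometric
# augmentation (horizontal/vertical flips, random rotation) applied jointly
# to image and mask. All randomness (data order, augmentation, anything
# downstream) derives from the configured seed, so a run is reproducible
# bit-for-bit in deterministic CPU arithmetic.

#' Training configuration
#'
#' @param lr0 initial learning rate.
#' @param lr_min cosine-annealing floor.
#' @param schedule_period cosine period in epochs.
#' @param epochs training epochs.
#' @param batch_size images per optimisation step.
#' @param beta1,beta2,adam_eps AdamW moment parameters.
#' @param weight_decay decoupled weight decay.
#' @param flip_p probability of each of horizontal and vertical flip.
#' @param rot_range rotation range in degrees (uniform in `+/- rot_range`).
#' @param loss_weights `(w_ce, w_dice)` loss weighting.
#' @param grad_clip global gradient-norm ceiling (0 disables).
#' @param seed master seed for data order and augmentation.
#' @param early_stop_dsc stop once the running training DSC reaches this
#'   value (NULL to always run all epochs).
#' @return a `dermseg_train_config` list.
#' @export
train_config <- function(lr0 = 1e-3, lr_min = 1e-5, schedule_period = 300L,
                         epochs = 300L, batch_size = 2L,
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                         weight_decay = 1e-2,
                         flip_p = 0.5, rot_range = 30,
                         loss_weights = c(1, 1), grad_clip = 5,
                         seed = 42L, early_stop_dsc = NULL) {
  stopifnot(lr_min < lr0, epochs >= 1L, batch_size >= 1L)
  structure(list(lr0 = lr0, lr_min = lr_min,
                 schedule_period = as.integer(schedule_period),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
                 weight_decay = weight_decay,
                 flip_p = flip_p, rot_range = rot_range,
                 loss_weights = loss_weights, grad_clip = grad_clip,
                 seed = as.integer(seed), early_stop_dsc = early_stop_dsc),
            class = "dermseg_train_config")
}

#' Cosine-annealed learning rate
#'
#' `lr(t) = lr_min + (lr0 - lr_min) * (1 + cos(pi * t / T)) / 2` with period
#' `T = schedule_period`: `lr(0) = lr0`, `lr(T) = lr_min`.
#'
#' @param t epoch index in `[0, T]`.
#' @param cfg a [train_config()].
#' @return learning rate.
#' @export
cosine_lr <- function(t, cfg = train_config()) {
  cfg$lr_min + 0.5 * (cfg$lr0 - cfg$lr_min) *
    (1 + cos(pi * t / cfg$schedule_period))
}

# rotate one (H, W) plane by `ang` radians about the centre; bilinear with
# reflection padding for images, nearest for masks
rotate_plane <- function(plane, ang, nearest = FALSE) {
  H <- nrow(plane); W <- ncol(plane)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  yy <- matrix(seq_len(H) - cy, H, W)
  xx <- matrix(seq_len(W) - cx, H, W, byrow = TRUE)
  sy <- cy + cos(ang) * yy - sin(ang) * xx
  sx <- cx + sin(ang) * yy + cos(ang) * xx
  reflect <- function(v, n) {
    v <- abs(v - 1) %% (2 * (n - 1)) + 1
    ifelse(v > n, 2 * n - v, v)
  }
  if (nearest) {
    ri <- reflect(round(sy), H); ci <- reflect(round(sx), W)
    return(matrix(plane[cbind(as.vector(ri), as.vector(ci))], H, W))
  }
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  gv <- function(yi, xi) {
    matrix(plane[cbind(as.vector(reflect(yi, H)), as.vector(reflect(xi, W)))],
           H, W)
  }
  gv(y0, x0) * (1 - fy) * (1 - fx) + gv(y0 + 1, x0) * fy * (1 - fx) +
    gv(y0, x0 + 1) * (1 - fy) * fx + gv(y0 + 1, x0 + 1) * fy * fx
}

#' Jointly augment an image/mask pair
#'
#' Applies the same randomly drawn geometric transform (vertical flip,
#' horizontal flip, rotation) to both; the mask is resampled with nearest
#' neighbours so it stays strictly binary. Uses the current RNG state.
#'
#' @param image `(C, H, W)` array.
#' @param mask `(H, W)` 0/1 matrix.
#' @param flip_p per-axis flip probability.
#' @param rot_range rotation range in degrees.
#' @return `list(image, mask)` of unchanged sizes.
#' @export
augment <- function(image, mask, flip_p = 0.5, rot_range = 30) {
  if (!identical(dim(image)[2:3], dim(mask))) {
    stop("image and mask are not spatially aligned", call. = FALSE)
  }
  if (stats::runif(1) < flip_p) {                       # horizontal
    image <- image[, , rev(seq_len(dim(image)[3])), drop = FALSE]
    mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
  }
  if (stats::runif(1) < flip_p) {                       # vertical
    image <- image[, rev(seq_len(dim(image)[2])), , drop = FALSE]
    mask <- mask[rev(seq_len(nrow(mask))), , drop = FALSE]
  }
  if (rot_range > 0) {
    ang <- stats::runif(1, -rot_range, rot_range) * pi / 180
    for (c in seq_len(dim(image)[1])) {
      image[c, , ] <- rotate_plane(image[c, , ], ang)
    }
    mask <- rotate_plane(mask, ang, nearest = TRUE)
  }
  list(image = image, mask = mask)
}

# ---- AdamW ------------------------------------------------------------------

adamw_new <- function(model, cfg) {
  refs <- param_refs(model)
  states <- lapply(refs, function(r) {
    p <- r$mod$par[[r$name]]
    list(m = p * 0, v = p * 0)   # preserves the parameter's exact structure
  })
  list(refs = refs, states = states, t = 0L, cfg = cfg)
}

adamw_step <- function(opt, lr) {
  cfg <- opt$cfg
  opt$t <- opt$t + 1L
  bc1 <- 1 - cfg$beta1^opt$t
  bc2 <- 1 - cfg$beta2^opt$t
  if (cfg$grad_clip > 0) {
    gn <- sqrt(sum(vapply(opt$refs, function(r) sum(r$mod$gr[[r$name]]^2), 0)))
    scale <- if (gn > cfg$grad_clip) cfg$grad_clip / gn else 1
  } else {
    scale <- 1
  }
  for (i in seq_along(opt$refs)) {
    r <- opt$refs[[i]]
    g <- r$mod$gr[[r$name]] * scale
    if (is.null(dim(r$mod$par[[r$name]]))) g <- as.numeric(g)
    st <- opt$states[[i]]
    st$m <- cfg$beta1 * st$m + (1 - cfg$beta1) * g
    st$v <- cfg$beta2 * st$v + (1 - cfg$beta2) * g * g
    opt$states[[i]] <- st
    upd <- (st$m / bc1) / (sqrt(st$v / bc2) + cfg$adam_eps)
    r$mod$par[[r$name]] <- r$mod$par[[r$name]] -
      lr * (upd + cfg$weight_decay * r$mod$par[[r$name]])
  }
  opt
}

# stack a list of (C,H,W)/(H,W) pairs into (C,H,W,B) and (H,W,B)
stack_batch <- function(pairs) {
  B <- length(pairs)
  di <- dim(pairs[[1]]$image)
  xi <- array(0, c(di, B))
  ms <- array(0L, c(dim(pairs[[1]]$mask), B))
  for (b in seq_len(B)) {
    xi[, , , b] <- pairs[[b]]$image
    ms[, , b] <- pairs[[b]]$mask
  }
  list(image = xi, mask = ms)
}

#' Train a segmentation model
#'
#' @param model a `seg_network` from [build_model()].
#' @param dataset list of `list(image = (3,H,W), mask = (H,W))` pairs, e.g.
#'   from [load_dataset()].
#' @param cfg a [train_config()].
#' @param val_data optional held-out pairs; when given, the retained best
#'   checkpoint maximises validation DSC, otherwise training DSC.
#' @param checkpoint_path optional path for the best checkpoint.
#' @param verbose print one line per epoch.
#' @return `list(model, history, best)`: `history` is a data.frame with one
#'   row per epoch (lr, mean loss, training DSC, optional validation
#'   metrics); `best` holds the best epoch's parameter state.
#' @export
train <- function(model, dataset, cfg = train_config(), val_data = NULL,
                  checkpoint_path = NULL, verbose = FALSE) {
  stopifnot(length(dataset) > 0)
  set.seed(cfg$seed)
  opt <- adamw_new(model, cfg)
  hist <- vector("list", cfg$epochs)
  best_dsc <- -Inf
  best_state <- NULL
  best_epoch <- NA_integer_
  for (epoch in seq_len(cfg$epochs)) {
    lr <- cosine_lr(min(epoch - 1L, cfg$schedule_period), cfg)
    ord <- sample(seq_along(dataset))
    losses <- c()
    conf <- structure(list(TP = 0, TN = 0, FP = 0, FN = 0, k = 1L),
                      class = "dermseg_confusion")
    for (start in seq(1L, length(ord), by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      pairs <- lapply(dataset[idx], function(p) {
        augment(p$image, p$mask, cfg$flip_p, cfg$rot_range)
      })
      batch <- stack_batch(pairs)
      logits <- mod_forward(model, batch$image, training = TRUE)
      loss <- combined_loss(logits, batch$mask, cfg$loss_weights)
      if (!is.finite(loss)) {
        stop(sprintf(
          "non-finite loss at epoch %d, batch starting at example %d (%s)",
          epoch, start, paste(idx, collapse = ",")), call. = FALSE)
      }
      losses <- c(losses, loss)
      pred <- matrix(as.integer(sigmoid(as.numeric(logits)) >= 0.5))
      conf <- add_confusion(conf, confusion(pred, matrix(as.integer(batch$mask))))
      zero_grads(model)
      dlogits <- combined_loss_grad(logits, batch$mask, cfg$loss_weights)
      mod_backward(model, dlogits)
      opt <- adamw_step(opt, lr)
    }
    train_dsc <- compute_metrics(conf)$DSC
    row <- data.frame(epoch = epoch, lr = lr, loss = mean(losses),
                      train_dsc = train_dsc)
    sel_dsc <- train_dsc
    if (!is.null(val_data)) {
      vm <- evaluate(model, val_data)
      row$val_dsc <- vm$DSC
      row$val_miou <- vm$mIoU
      sel_dsc <- vm$DSC
    }
    hist[[epoch]] <- row
    if (sel_dsc > best_dsc) {
      best_dsc <- sel_dsc
      best_state <- param_state(model)
      best_epoch <- epoch
    }
    if (verbose) {
      message(sprintf("epoch %3d  lr %.2e  loss %.4f  DSC %.4f",
                      epoch, lr, mean(losses), train_dsc))
    }
    if (!is.null(cfg$early_stop_dsc) && train_dsc >= cfg$early_stop_dsc) {
      hist <- hist[seq_len(epoch)]
      break
    }
  }
  history <- do.call(rbind, hist)
  if (!is.null(checkpoint_path) && !is.null(best_state)) {
    cur <- param_state(model)
    load_param_state(model, best_state)
    save_checkpoint(model, checkpoint_path, history)
    load_param_state(model, cur)
  }
  list(model = model, history = history,
       best = list(epoch = best_epoch, dsc = best_dsc, state = best_state))
}

#' Evaluate a model on a dataset
#'
#' Confusion counts are pooled over the whole set before computing the rate
#' metrics; HD95 is computed per image and summarised as mean and standard
#' deviation (empty-mask sentinels reported separately).
#'
#' @param model a `seg_network`.
#' @param dataset list of image/mask pairs.
#' @param threshold probability threshold for binarisation.
#' @param batch_size evaluation batch size.
#' @return a `dermseg_metrics` list extended with `HD95`, `HD95_sd`,
#'   `HD95_values` and `n_images`.
#' @export
evaluate <- function(model, dataset, threshold = 0.5, batch_size = 2L) {
  stopifnot(length(dataset) > 0)
  conf <- structure(list(TP = 0, TN = 0, FP = 0, FN = 0, k = 1L),
                    class = "dermseg_confusion")
  hd <- numeric(length(dataset))
  sentinel <- logical(length(dataset))
  for (start in seq(1L, length(dataset), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, length(dataset))
    batch <- stack_batch(dataset[idx])
    logits <- mod_forward(model, batch$image, training = FALSE)
    prob <- sigmoid(logits)
    for (k in seq_along(idx)) {
      pm <- matrix(as.integer(prob[1, , , k] >= threshold),
                   dim(prob)[2], dim(prob)[3])
      gm <- batch$mask[, , k]
      conf <- add_confusion(conf, confusion(pm, gm))
      hd[idx[k]] <- hd95(pm, gm)
      sentinel[idx[k]] <- xor(sum(pm) == 0, sum(gm) == 0)
    }
  }
  out <- compute_metrics(conf)
  out$HD95 <- mean(hd)
  out$HD95_sd <- stats::sd(hd)
  out$HD95_values <- hd
  out$HD95_sentinels <- sum(sentinel)
  out$n_images <- length(dataset)
  out
}

#' Serialise an evaluation report to a plain list (for JSON/CSV export)
#' @param m metrics from [evaluate()] or [compute_metrics()].
#' @return flat named list; percentages on the 0-100 scale with 2 decimals.
#' @export
metrics_as_list <- function(m) {
  out <- list(mIoU_pct = round(100 * m$mIoU, 2),
              DSC_pct = round(100 * m$DSC, 2),
              Acc_pct = round(100 * m$Acc, 2),
              Sen_pct = round(100 * m$Sen, 2),
              Spe_pct = round(100 * m$Spe, 2),
              TP = m$confusion$TP, TN = m$confusion$TN,
              FP = m$confusion$FP, FN = m$confusion$FN)
  if (!is.null(m$HD95)) {
    out$HD95_mean <- m$HD95
    out$HD95_sd <- m$HD95_sd
    out$HD95_empty_mask_sentinels <- m$HD95_sentinels
    out$n_images <- m$n_images
  }
  out
}
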