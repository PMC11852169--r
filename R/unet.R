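#' U-Net configuration
#'
#' The classical encoder-decoder segmentation network: four stages of
#' convolution blocks starting with 32 filters and doubling per stage
#' (32/64/128/256), trained with the Dice loss, an initial learning rate of
#' 0.001 halved when validation performance plateaus for `lr_patience`
#' epochs, and early stopping after `early_stop_patience` epochs without
#' improvement.
#'
#' @param stages Number of encoder stages.
#' @param base_filters Filters in the first stage (doubled per stage).
#' @param input_side Square input patch side in pixels; must be divisible
#'   by `2^(stages - 1)`.
#' @param in_channels Input channels (1 = working gray channel).
#' @param lr_init,lr_factor,lr_patience Initial learning rate, plateau
#'   reduction factor, and plateau patience in epochs.
#' @param early_stop_patience Epochs without validation improvement before
#'   training stops.
#' @param batch_size,max_epochs Minibatch size and epoch cap.
#' @param val_fraction Held-out fraction of patches used as the validation
#'   split (seeded).
#' @param augment Apply seeded on-the-fly augmentation to training patches.
#' @param seed Integer seed controlling initialization, splits, shuffling,
#'   and augmentation.
#' @param type Lesion type the model is trained for (one per model).
#' @param profile Imaging profile the model expects at inference.
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(stages = 4L, base_filters = 32L, input_side = 96L,
                        in_channels = 1L, lr_init = 0.001, lr_factor = 0.5,
                        lr_patience = 3L, early_stop_patience = 10L,
                        batch_size = 16L, max_epochs = 100L,
                        val_fraction = 0.1, augment = TRUE, seed = 1L,
                        type = NA_character_, profile = "CFP") {
  if (stages < 1L || base_filters < 1L) config_error("stages and base_filters must be >= 1")
  if (lr_factor <= 0 || lr_factor >= 1) config_error("lr_factor must be in (0, 1)")
  if (input_side %% 2L^(stages - 1L) != 0L) {
    config_error(sprintf("input_side must be divisible by %d", 2L^(stages - 1L)))
  }
  structure(
    list(
      stages = as.integer(stages), base_filters = as.integer(base_filters),
      input_side = as.integer(input_side), in_channels = as.integer(in_channels),
      lr_init = lr_init, lr_factor = lr_factor,
      lr_patience = as.integer(lr_patience),
      early_stop_patience = as.integer(early_stop_patience),
      batch_size = as.integer(batch_size), max_epochs = as.integer(max_epochs),
      val_fraction = val_fraction, augment = isTRUE(augment),
      seed = as.integer(seed), type = type, profile = profile
    ),
    class = "unet_config"
  )
}

# 3x3 conv block parameters: He-normal kernels plus instance-norm scale and
# shift (the conv bias is omitted; the normalization shift replaces it).
he_conv <- function(cin, cout) {
  list(
    W = matrix(rnorm(9L * cin * cout, sd = sqrt(2 / (9 * cin))), 9L * cin, cout),
    b = numeric(cout),
    g = rep(1, cout),
    be = numeric(cout)
  )
}

#' Initialize a U-Net model
#'
#' @param config A [unet_config()].
#' @return An object of class `unet_model` with seeded He-normal weights.
#' @export
unet_init <- function(config = unet_config()) {
  nf <- config$base_filters * 2L^(seq_len(config$stages) - 1L)
  params <- with_seed(config$seed, {
    p <- list()
    cin <- config$in_channels
    for (s in seq_len(config$stages)) {
      p[[sprintf("enc%da", s)]] <- he_conv(cin, nf[s])
      p[[sprintf("enc%db", s)]] <- he_conv(nf[s], nf[s])
      cin <- nf[s]
    }
    for (s in rev(seq_len(config$stages - 1L))) {
      p[[sprintf("dec%da", s)]] <- he_conv(nf[s + 1L] + nf[s], nf[s])
      p[[sprintf("dec%db", s)]] <- he_conv(nf[s], nf[s])
    }
    p$out <- list(
      W = matrix(rnorm(nf[1], sd = sqrt(2 / nf[1])), nf[1], 1L),
      b = 0
    )
    p
  })
  structure(
    list(params = params, config = config, stage_filters = nf, history = NULL),
    class = "unet_model"
  )
}

#' Encoder filter counts per stage
#'
#' Derived from the actual weight shapes, not the configuration.
#'
#' @param model A `unet_model`.
#' @return Integer vector, e.g. `c(32, 64, 128, 256)`.
#' @export
unet_stage_filters <- function(model) {
  vapply(
    seq_len(model$config$stages),
    function(s) ncol(model$params[[sprintf("enc%db", s)]]$W),
    integer(1)
  )
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf(
    "<unet_model> %d stages (%s filters), input %dx%d, type %s\n",
    x$config$stages, paste(unet_stage_filters(x), collapse = "/"),
    x$config$input_side, x$config$input_side, x$config$type
  ))
  invisible(x)
}

# Full forward pass on one [H, W, Cin] sample; returns probability map and
# every cache needed for backprop.
unet_forward <- function(model, x) {
  P <- model$params
  S <- model$config$stages
  cache <- list(enc = vector("list", S), pool = vector("list", S - 1L))
  block_fw <- function(h, layer) {
    cv <- conv_fw(h, layer)
    nn <- in_fw(cv$y, layer$g, layer$be)
    list(cv = cv, nn = nn, y = relu_fw(nn$y))
  }
  h <- x
  for (s in seq_len(S)) {
    ba <- block_fw(h, P[[sprintf("enc%da", s)]])
    bb <- block_fw(ba$y, P[[sprintf("enc%db", s)]])
    cache$enc[[s]] <- list(ba = ba, bb = bb, yb = bb$y)
    if (s < S) {
      pl <- pool_fw(bb$y)
      cache$pool[[s]] <- pl
      h <- pl$y
    } else {
      h <- bb$y
    }
  }
  cache$dec <- vector("list", S - 1L)
  for (s in rev(seq_len(S - 1L))) {
    up <- up_fw(h)
    cat_in <- concat_ch(up, cache$enc[[s]]$yb)
    ba <- block_fw(cat_in, P[[sprintf("dec%da", s)]])
    bb <- block_fw(ba$y, P[[sprintf("dec%db", s)]])
    cache$dec[[s]] <- list(up_ch = dim(up)[3], ba = ba, bb = bb, yb = bb$y)
    h <- bb$y
  }
  d <- dim(h)
  hmat <- matrix(h, d[1] * d[2], d[3])
  logits <- hmat %*% P$out$W + P$out$b
  p <- 1 / (1 + exp(-logits))
  cache$head_in <- hmat
  cache$head_dim <- d
  cache$p <- matrix(p, d[1], d[2])
  cache
}

# Backward pass given dL/dp; returns gradients named like model$params.
unet_backward <- function(model, cache, dp) {
  P <- model$params
  S <- model$config$stages
  g <- list()
  p <- cache$p
  dlogit <- matrix(dp * p * (1 - p), length(p), 1L)
  g$out <- list(W = crossprod(cache$head_in, dlogit), b = sum(dlogit))
  d <- cache$head_dim
  dh <- array(dlogit %*% t(P$out$W), d)
  block_bw <- function(dout, blk, layer) {
    dout <- relu_bw(dout, blk$y)
    nb <- in_bw(dout, layer$g, blk$nn)
    cb <- conv_bw(nb$dx, blk$cv, layer)
    list(grad = list(W = cb$dW, b = cb$db, g = nb$dg, be = nb$dbe), dx = cb$dx)
  }
  for (s in seq_len(S - 1L)) {
    dc <- cache$dec[[s]]
    bb <- block_bw(dh, dc$bb, P[[sprintf("dec%db", s)]])
    g[[sprintf("dec%db", s)]] <- bb$grad
    ba <- block_bw(bb$dx, dc$ba, P[[sprintf("dec%da", s)]])
    g[[sprintf("dec%da", s)]] <- ba$grad
    nup <- dc$up_ch
    dup <- ba$dx[, , seq_len(nup), drop = FALSE]
    dskip <- ba$dx[, , nup + seq_len(dim(ba$dx)[3] - nup), drop = FALSE]
    # gradient flowing into encoder stage s via the skip connection is
    # accumulated when that stage is unwound below
    cache$enc[[s]]$dskip <- dskip
    dh <- up_bw(dup)
  }
  for (s in rev(seq_len(S))) {
    ec <- cache$enc[[s]]
    dyb <- if (s == S) dh else pool_bw(dh, cache$pool[[s]]) + ec$dskip
    bb <- block_bw(dyb, ec$bb, P[[sprintf("enc%db", s)]])
    g[[sprintf("enc%db", s)]] <- bb$grad
    ba <- block_bw(bb$dx, ec$ba, P[[sprintf("enc%da", s)]])
    g[[sprintf("enc%da", s)]] <- ba$grad
    dh <- ba$dx
  }
  g
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(pred * target) + eps) / (sum(pred) + sum(target) + eps)`
#' with `eps = 1e-6`; bounded in `[0, 1]` and symmetric in its arguments.
#'
#' @param pred Probability raster in `[0, 1]`.
#' @param target Binary raster of the same shape.
#' @param eps Stabilizer.
#' @return Loss value.
#' @export
dice_loss <- function(pred, target, eps = 1e-6) {
  if (!identical(dim(pred), dim(target)) || length(pred) != length(target)) {
    input_error("pred and target must have identical shape")
  }
  1 - (2 * sum(pred * target) + eps) / (sum(pred) + sum(target) + eps)
}

dice_loss_grad <- function(pred, target, eps = 1e-6) {
  num <- 2 * sum(pred * target) + eps
  den <- sum(pred) + sum(target) + eps
  -(2 * target) / den + num / den^2
}

#' Plateau learning-rate schedule with early stopping
#'
#' Tracks the best validation metric seen; when it fails to improve for
#' `lr_patience` consecutive epochs the learning rate is multiplied by
#' `lr_factor`, and after `stop_patience` epochs without improvement the
#' `stop` flag is raised.
#'
#' @param lr_init Initial learning rate.
#' @param lr_factor,lr_patience Reduction factor and patience (epochs).
#' @param stop_patience Early-stopping patience (epochs).
#' @return A schedule state list; feed it to [plateau_update()].
#' @export
plateau_state <- function(lr_init = 0.001, lr_factor = 0.5, lr_patience = 3L,
                          stop_patience = 10L) {
  list(
    lr = lr_init, lr_factor = lr_factor, lr_patience = as.integer(lr_patience),
    stop_patience = as.integer(stop_patience),
    best = -Inf, wait_lr = 0L, wait_stop = 0L, stop = FALSE
  )
}

#' @rdname plateau_state
#' @param state A schedule state.
#' @param metric Validation performance for the finished epoch (higher is
#'   better; the harness uses the validation Dice coefficient).
#' @export
plateau_update <- function(state, metric) {
  if (metric > state$best + 1e-8) {
    state$best <- metric
    state$wait_lr <- 0L
    state$wait_stop <- 0L
  } else {
    state$wait_lr <- state$wait_lr + 1L
    state$wait_stop <- state$wait_stop + 1L
    if (state$wait_lr >= state$lr_patience) {
      state$lr <- state$lr * state$lr_factor
      state$wait_lr <- 0L
    }
  }
  state$stop <- state$wait_stop >= state$stop_patience
  state
}

patch_tensor <- function(patch, type, side) {
  x <- resize_plane(patch$window, side)
  mask <- patch$label_masks[[type]]
  y <- if (is.null(mask)) matrix(0, side, side) else resize_plane(mask * 1, side, nearest = TRUE)
  list(x = array(x, c(side, side, 1L)), y = (y > 0.5) * 1)
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(grads)) {
    for (part in names(grads[[nm]])) {
      gv <- grads[[nm]][[part]]
      st <- state[[nm]][[part]]
      st$m <- beta1 * st$m + (1 - beta1) * gv
      st$v <- beta2 * st$v + (1 - beta2) * gv^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      params[[nm]][[part]] <- params[[nm]][[part]] - lr * mhat / (sqrt(vhat) + eps)
      state[[nm]][[part]] <- st
    }
  }
  list(params = params, state = state)
}

#' Train a U-Net on mined training patches
#'
#' Trains with the Dice loss (aggregated over each minibatch, so paired
#' background-only patches regularize rather than dominate), Adam, a seeded
#' 10% validation split, optional seeded on-the-fly augmentation, plateau
#' learning-rate halving, and early stopping.  The validation metric is the
#' Dice coefficient aggregated over the held-out split.  Fully reproducible
#' given `config$seed` on a single CPU thread.
#'
#' @param patches List of `training_patch` objects (lesion and background)
#'   for one lesion type.
#' @param config A [unet_config()]; `config$type` selects the label channel.
#' @return A trained `unet_model` with a per-epoch `history` data frame
#'   (`epoch`, `train_loss`, `val_dice`, `lr`).
#' @export
train_unet <- function(patches, config = unet_config()) {
  if (!length(patches)) input_error("empty patch archive")
  type <- config$type
  if (is.na(type)) {
    types <- unique(vapply(patches, function(p) p$type, character(1)))
    if (length(types) != 1L) config_error("config$type must be set for mixed-type archives")
    type <- types
    config$type <- type
  }
  kinds <- vapply(patches, function(p) p$kind, character(1))
  if (sum(kinds == "LESION") < 2L || sum(kinds == "BACKGROUND") < 2L) {
    input_error("need at least 2 lesion and 2 background patches")
  }
  side <- config$input_side
  model <- unet_init(config)
  astate <- lapply(model$params, function(l) {
    lapply(l, function(p) list(m = p * 0, v = p * 0))
  })
  n <- length(patches)
  history <- list()
  with_seed(config$seed + 1L, {
    n_val <- max(1L, round(config$val_fraction * n))
    val_idx <- sample.int(n, n_val)
    train_idx <- setdiff(seq_len(n), val_idx)
    val_data <- lapply(patches[val_idx], patch_tensor, type = type, side = side)
    base_data <- lapply(patches, patch_tensor, type = type, side = side)
    sched <- plateau_state(
      config$lr_init, config$lr_factor,
      config$lr_patience, config$early_stop_patience
    )
    tstep <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(train_idx)
      losses <- numeric(0)
      for (start in seq(1L, length(ord), by = config$batch_size)) {
        batch <- ord[start:min(start + config$batch_size - 1L, length(ord))]
        samples <- lapply(batch, function(i) {
          if (config$augment) {
            patch_tensor(
              augment_patch(patches[[i]], rng_seed = sample.int(2^30, 1L), out_side = side),
              type = type, side = side
            )
          } else {
            base_data[[i]]
          }
        })
        caches <- lapply(samples, function(smp) unet_forward(model, smp$x))
        # Dice aggregated over the minibatch: background-only patches of a
        # lesion/background pair contribute to the denominator only, so an
        # all-background prediction is not a loss minimum.
        eps <- 1e-6
        s_pt <- sum(vapply(seq_along(batch), function(k) {
          sum(caches[[k]]$p * samples[[k]]$y)
        }, numeric(1)))
        s_p <- sum(vapply(caches, function(cc) sum(cc$p), numeric(1)))
        s_t <- sum(vapply(samples, function(smp) sum(smp$y), numeric(1)))
        num <- 2 * s_pt + eps
        den <- s_p + s_t + eps
        grads <- NULL
        for (k in seq_along(batch)) {
          dp <- -(2 * samples[[k]]$y) / den + num / den^2
          g <- unet_backward(model, caches[[k]], dp)
          if (is.null(grads)) {
            grads <- g
          } else {
            for (nm in names(g)) {
              for (part in names(g[[nm]])) {
                grads[[nm]][[part]] <- grads[[nm]][[part]] + g[[nm]][[part]]
              }
            }
          }
        }
        tstep <- tstep + 1L
        upd <- adam_step(model$params, grads, astate, sched$lr, tstep)
        model$params <- upd$params
        astate <- upd$state
        losses <- c(losses, 1 - num / den)
      }
      val_p <- lapply(val_data, function(smp) unet_forward(model, smp$x)$p)
      val_dice <- (2 * sum(vapply(seq_along(val_data), function(k) {
        sum(val_p[[k]] * val_data[[k]]$y)
      }, numeric(1))) + 1e-6) /
        (sum(vapply(val_p, sum, numeric(1))) +
          sum(vapply(val_data, function(smp) sum(smp$y), numeric(1))) + 1e-6)
      history[[epoch]] <- data.frame(
        epoch = epoch, train_loss = mean(losses), val_dice = val_dice,
        lr = sched$lr
      )
      sched <- plateau_update(sched, val_dice)
      if (sched$stop) break
    }
  })
  model$history <- do.call(rbind, history)
  model
}

#' Sliding-window inference over a full image
#'
#' Tiles the image with `input_side` windows at half-window stride, averages
#' overlapping probabilities, thresholds at `threshold`, and returns the
#' binary mask plus its 8-connected components as detections.
#'
#' @param model A trained `unet_model`.
#' @param gray A [gray_image()]; its profile must match the model's.
#' @param threshold Probability threshold.
#' @return List with `prob` (matrix), `mask` (logical), and `regions`
#'   (list of detections with `idx`, `area`, `bbox`).
#' @export
infer_masks <- function(model, gray, threshold = 0.5) {
  if (!is.na(model$config$type) && !is.null(gray$profile) &&
      !is.null(model$config$profile) &&
      !identical(model$config$profile, gray$profile)) {
    config_error(sprintf(
      "model trained for profile %s applied to a %s image",
      model$config$profile, gray$profile
    ))
  }
  px <- gray$pixels
  side <- model$config$input_side
  nr <- nrow(px)
  nc <- ncol(px)
  if (nr < side || nc < side) {
    ri <- pmin(seq_len(max(nr, side)), nr)
    ci <- pmin(seq_len(max(nc, side)), nc)
    px <- px[ri, ci, drop = FALSE]
  }
  H <- nrow(px)
  W <- ncol(px)
  stride <- max(1L, side %/% 2L)
  starts <- function(total) unique(c(seq(1L, total - side + 1L, by = stride), total - side + 1L))
  acc <- matrix(0, H, W)
  cnt <- matrix(0, H, W)
  for (r0 in starts(H)) {
    for (c0 in starts(W)) {
      rows <- r0:(r0 + side - 1L)
      cols <- c0:(c0 + side - 1L)
      tile <- array(px[rows, cols], c(side, side, 1L))
      p <- unet_forward(model, tile)$p
      acc[rows, cols] <- acc[rows, cols] + p
      cnt[rows, cols] <- cnt[rows, cols] + 1
    }
  }
  prob <- (acc / pmax(cnt, 1))[seq_len(nr), seq_len(nc), drop = FALSE]
  mask <- prob >= threshold & gray$fov
  regions <- list()
  if (any(mask)) {
    lab <- label8(mask)
    pos <- which(lab > 0L)
    for (g in split(pos, lab[pos])) {
      r <- ((g - 1L) %% nr) + 1L
      cl <- ((g - 1L) %/% nr) + 1L
      regions[[length(regions) + 1L]] <- list(
        idx = g, area = length(g),
        bbox = c(r0 = min(r), r1 = max(r), c0 = min(cl), c1 = max(cl))
      )
    }
  }
  list(prob = prob, mask = mask, regions = regions)
}

#' Save / load a trained model artifact
#'
#' Single-file serialized weights with the configuration and training
#' history embedded.
#'
#' @param model A `unet_model`.
#' @param path File path.
#' @return `path` (save) or the model (load).
#' @export
save_unet <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_unet
#' @export
load_unet <- function(path) {
  if (!file.exists(path)) input_error(sprintf("model file not found: '%s'", path))
  readRDS(path)
}
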