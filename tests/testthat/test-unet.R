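test_that("configuration invariants are enforced", {
  expect_error(unet_config(lr_factor = 1.5), class = "retilab_config_error")
  expect_error(unet_config(stages = 0L), class = "retilab_config_error")
  expect_error(unet_config(input_side = 50L), class = "retilab_config_error")
  cfg <- unet_config()
  expect_equal(cfg$lr_init, 0.001)
  expect_equal(cfg$lr_factor, 0.5)
  expect_equal(cfg$lr_patience, 3L)
  expect_equal(cfg$early_stop_patience, 10L)
})

test_that("the encoder has four stages with 32/64/128/256 filters", {
  model <- unet_init(unet_config(input_side = 32L))
  expect_identical(unet_stage_filters(model), c(32L, 64L, 128L, 256L))
  # weight shapes double per stage on the way down
  expect_equal(dim(model$params$enc1a$W), c(9L, 32L))
  expect_equal(dim(model$params$enc2a$W), c(9L * 32L, 64L))
  expect_equal(dim(model$params$enc3a$W), c(9L * 64L, 128L))
  expect_equal(dim(model$params$enc4a$W), c(9L * 128L, 256L))
})

test_that("dice loss matches its closed form and is symmetric and bounded", {
  t1 <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_lt(dice_loss(t1, t1), 1e-6)
  expect_gt(dice_loss(1 - t1, t1), 1 - 1e-5)

  pred <- matrix(0.5, 4, 4)
  target <- matrix(rep(c(1, 0), each = 8), 4, 4)
  direct <- 1 - (2 * sum(pred * target) + 1e-6) / (sum(pred) + sum(target) + 1e-6)
  expect_equal(dice_loss(pred, target), direct)

  set.seed(3)
  p <- matrix(rbinom(16, 1, 0.5), 4, 4)
  q <- matrix(rbinom(16, 1, 0.5), 4, 4)
  expect_equal(dice_loss(p, q), dice_loss(q, p))
  expect_gte(dice_loss(p, q), 0)
  expect_lte(dice_loss(p, q), 1)
  expect_error(dice_loss(matrix(0, 2, 2), matrix(0, 3, 3)), class = "retilab_input_error")
})

test_that("backpropagation matches finite differences", {
  cfg <- unet_config(stages = 3L, base_filters = 2L, input_side = 8L, seed = 9L)
  model <- unet_init(cfg)
  set.seed(4)
  x <- array(runif(64), c(8, 8, 1))
  y <- matrix(rbinom(64, 1, 0.3), 8, 8)
  cache <- retilab:::unet_forward(model, x)
  L0 <- dice_loss(cache$p, y)
  g <- retilab:::unet_backward(model, cache, retilab:::dice_loss_grad(cache$p, y))
  eps <- 1e-6
  for (nm in c("enc1a", "enc3b", "dec1a", "out")) {
    for (part in c("W", "g")) {
      if (is.null(model$params[[nm]][[part]])) next
      k <- length(model$params[[nm]][[part]])
      for (i in sample(k, min(3, k))) {
        m2 <- model
        m2$params[[nm]][[part]][i] <- m2$params[[nm]][[part]][i] + eps
        L1 <- dice_loss(retilab:::unet_forward(m2, x)$p, y)
        num <- (L1 - L0) / eps
        expect_lt(abs(num - g[[nm]][[part]][i]), 1e-4 + 1e-3 * abs(num))
      }
    }
  }
})

test_that("plateau schedule halves the rate after 3 stale epochs and stops after 10", {
  st <- plateau_state(0.001, 0.5, 3L, 10L)
  st <- plateau_update(st, 0.5) # first epoch sets the best
  for (i in 1:2) st <- plateau_update(st, 0.5)
  expect_equal(st$lr, 0.001) # only 2 stale epochs so far
  st <- plateau_update(st, 0.5)
  expect_equal(st$lr, 0.0005) # third stale epoch triggers the halving
  expect_false(st$stop)

  st <- plateau_update(st, 0.9) # improvement resets both counters
  expect_equal(st$wait_stop, 0L)
  for (i in 1:9) {
    st <- plateau_update(st, 0.9)
    expect_false(st$stop)
  }
  st <- plateau_update(st, 0.9)
  expect_true(st$stop) # 10th stale epoch
})

test_that("training decreases the Dice loss and is reproducible under a fixed seed", {
  patches <- c(
    lapply(1:12, synth_patch, lesion = TRUE, side = 24L),
    lapply(13:24, synth_patch, lesion = FALSE, side = 24L)
  )
  cfg <- unet_config(
    input_side = 16L, max_epochs = 3L, batch_size = 8L,
    augment = FALSE, seed = 2L, type = "microaneurysm"
  )
  m1 <- train_unet(patches, cfg)
  expect_equal(nrow(m1$history), 3L)
  expect_lt(m1$history$train_loss[3], m1$history$train_loss[1])
  m2 <- train_unet(patches, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params$out$W, m2$params$out$W)

  expect_error(train_unet(list(), cfg), class = "retilab_input_error")
  expect_error(train_unet(patches[1:3], cfg), class = "retilab_input_error")
})

test_that("training with on-the-fly augmentation stays finite and seeded", {
  patches <- c(
    lapply(1:6, synth_patch, lesion = TRUE, side = 24L),
    lapply(7:12, synth_patch, lesion = FALSE, side = 24L)
  )
  cfg <- unet_config(
    input_side = 16L, max_epochs = 1L, batch_size = 6L,
    augment = TRUE, seed = 5L, type = "microaneurysm"
  )
  m1 <- train_unet(patches, cfg)
  m2 <- train_unet(patches, cfg)
  expect_identical(m1$history, m2$history)
  expect_true(all(is.finite(m1$history$train_loss)))
})

test_that("inference tiles deterministically, thresholds, and checks the profile", {
  patches <- c(
    lapply(1:8, synth_patch, lesion = TRUE, side = 24L),
    lapply(9:16, synth_patch, lesion = FALSE, side = 24L)
  )
  cfg <- unet_config(
    input_side = 16L, max_epochs = 1L, batch_size = 8L,
    augment = FALSE, seed = 3L, type = "microaneurysm", profile = "CFP"
  )
  model <- train_unet(patches, cfg)
  set.seed(8)
  g <- gray_image(matrix(runif(48 * 48, 0.4, 0.7), 48, 48), profile = "CFP")
  r1 <- infer_masks(model, g)
  r2 <- infer_masks(model, g)
  expect_identical(r1$prob, r2$prob)
  expect_true(all(r1$prob >= 0 & r1$prob <= 1))
  expect_false(any(infer_masks(model, g, threshold = 1.0)$mask))

  g_uwf <- gray_image(matrix(0.5, 48, 48), profile = "UWF")
  expect_error(infer_masks(model, g_uwf), class = "retilab_config_error")
})

test_that("model artifacts round-trip through disk", {
  model <- unet_init(unet_config(stages = 2L, base_filters = 2L, input_side = 8L))
  path <- withr::local_tempfile(fileext = ".rds")
  save_unet(model, path)
  back <- load_unet(path)
  expect_identical(back$params, model$params)
  expect_error(load_unet("/nonexistent.rds"), class = "retilab_input_error")
})
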