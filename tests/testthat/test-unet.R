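tiny_cfg <- function(seed = 7) unet_config(levels = 3, base_channels = 2, seed = seed)

tiny_sample <- function(seed, size = 48, noise = 0) {
  generate_phantom(phantom_spec(image_size = size, n_cells = 2,
                                cell_radius_range = c(4, 7),
                                cluster_fraction = 0, ambiguous_fraction = 0.5,
                                noise_sd = noise, fpol_targets = c(0.15, 0.3),
                                seed = seed))
}

test_that("the network respects its shape and normalization contracts", {
  net <- build_network(unet_config(levels = 5, base_channels = 4, seed = 1))
  ph <- tiny_sample(1, size = 48)
  probs <- predict_pair(net, ph$pair)
  expect_equal(dim(probs$high_quality), c(48, 48))
  total <- probs$background + probs$ambiguous + probs$high_quality
  expect_true(all(abs(total - 1) < 1e-5))
  expect_true(all(probs$high_quality >= 0 & probs$high_quality <= 1))

  ## spatial dims must be divisible by 2^(levels-1)
  odd <- generate_phantom(phantom_spec(image_size = 36, n_cells = 1,
                                       cell_radius_range = c(4, 6), seed = 2))
  expect_error(predict_pair(net, odd$pair), "divisible by 16.*pad")

  ## wrong channel count is rejected at the config level
  expect_error(unet_config(in_channels = 1), "2 input channels")
  x1 <- array(0, c(32, 32, 1))
  expect_error(fpolcyto:::unet_forward(net, x1), "\\(H, W, 2\\)")
})

test_that("parameter initialization is seeded and reproducible", {
  a <- build_network(tiny_cfg(seed = 5))
  b <- build_network(tiny_cfg(seed = 5))
  expect_identical(a$params, b$params)
  c <- build_network(tiny_cfg(seed = 6))
  expect_false(identical(a$params, c$params))
})

test_that("analytic gradients match finite differences", {
  set.seed(21)
  net <- build_network(tiny_cfg())
  x <- array(runif(16 * 16 * 2), c(16, 16, 2))
  lab <- matrix(sample(0:2, 256, replace = TRUE), 16, 16)
  lg <- fpolcyto:::unet_loss_grad(net, x, lab)
  eps <- 1e-5
  for (nm in c("enc1_conv1", "enc3_conv2", "up2", "dec1_conv2", "out")) {
    for (w in c("W", "b")) {
      p <- net$params[[nm]][[w]]
      for (k in sample(length(p), min(3, length(p)))) {
        n1 <- net; n1$params[[nm]][[w]][k] <- p[k] + eps
        n2 <- net; n2$params[[nm]][[w]][k] <- p[k] - eps
        num <- (fpolcyto:::unet_loss_grad(n1, x, lab)$loss -
                fpolcyto:::unet_loss_grad(n2, x, lab)$loss) / (2 * eps)
        ana <- lg$grads[[nm]][[w]][k]
        expect_lt(abs(num - ana) / max(abs(num), abs(ana), 1e-8), 1e-4)
      }
    }
  }
})

test_that("training reduces the loss and is reproducible", {
  samples <- lapply(1:6, tiny_sample, noise = 1)
  net <- build_network(tiny_cfg())
  tcfg <- train_config(epochs = 8, crop_size = 32, batch_size = 4,
                       learning_rate = 2e-3, seed = 3)
  tr1 <- train_network(net, samples, tcfg)
  expect_lt(tail(tr1$loss_history, 1), tr1$loss_history[1])

  tr2 <- train_network(net, samples, tcfg)
  expect_identical(tr1$loss_history, tr2$loss_history)
  expect_identical(tr1$net$params, tr2$net$params)

  expect_error(train_network(net, list(), tcfg), "at least one sample")
})

test_that("a single repeated sample is memorized to near-zero loss", {
  s <- tiny_sample(9, size = 48)
  net <- build_network(unet_config(levels = 3, base_channels = 4, seed = 2))
  ## no geometric augmentation, full-size crop: the target is constant
  tcfg <- train_config(epochs = 80, crop_size = 48, batch_size = 1,
                       learning_rate = 3e-3, rotation = c(0, 0),
                       flips = FALSE, scale = c(1, 1), shear = c(0, 0),
                       seed = 4)
  tr <- train_network(net, list(s), tcfg)
  expect_lt(tail(tr$loss_history, 1), 0.05)
})

test_that("augmentation preserves label classes and crop geometry", {
  s <- tiny_sample(12, size = 64)
  ts <- fpolcyto:::as_training_sample(s)
  tcfg <- train_config(crop_size = 32, elastic = TRUE, seed = 5)
  set.seed(5)
  for (i in 1:5) {
    aug <- fpolcyto:::augment_sample(ts$x, ts$labels, tcfg)
    expect_equal(dim(aug$x), c(32, 32, 2))
    expect_equal(dim(aug$labels), c(32, 32))
    expect_true(all(aug$labels %in% 0:2))
    expect_true(all(aug$x >= 0 & aug$x <= 1))
  }
})

test_that("checkpoints round-trip a trained model", {
  d <- withr::local_tempdir()
  net <- build_network(tiny_cfg())
  p <- file.path(d, "model.ckpt")
  save_unet(net, p)
  back <- load_unet(p)
  expect_identical(back$params, net$params)
  expect_identical(back$cfg, net$cfg)
  ph <- tiny_sample(3, size = 48)
  expect_identical(predict_pair(net, ph$pair), predict_pair(back, ph$pair))
})
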