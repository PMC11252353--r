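## Supervised training of the segmentation network.
##
## Cross-entropy loss with equal class weights, Adam, batch size 4, and
## online augmentation (fresh random draws each epoch): rotation, flips,
## scaling, shearing, random cropping, and optional elastic deformation.
## Label masks are warped with nearest-neighbor interpolation so class
## ids stay intact.

#' Training configuration
#'
#' @param epochs training epochs.
#' @param batch_size samples per optimizer step (default 4).
#' @param learning_rate Adam step size.
#' @param crop_size side length of the random crops fed to the network;
#'   must be a multiple of `2^(levels-1)` and at most the image size.
#' @param rotation rotation range in degrees.
#' @param flips allow random horizontal/vertical flips.
#' @param scale zoom factor range.
#' @param shear shear range in degrees.
#' @param elastic enable elastic deformation (off by default).
#' @param elastic_alpha,elastic_sigma displacement amplitude (px) and
#'   smoothing SD (px) of the elastic field.
#' @param seed RNG seed for shuffling, augmentation, and cropping; a
#'   fixed seed makes the whole training run reproducible.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 30, batch_size = 4, learning_rate = 1e-3,
                         crop_size = 64, rotation = c(-180, 180),
                         flips = TRUE, scale = c(0.8, 1.2),
                         shear = c(-10, 10), elastic = FALSE,
                         elastic_alpha = 8, elastic_sigma = 6, seed = 1) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0, crop_size >= 16)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 crop_size = as.integer(crop_size),
                 rotation = rotation, flips = isTRUE(flips), scale = scale,
                 shear = shear, elastic = isTRUE(elastic),
                 elastic_alpha = elastic_alpha, elastic_sigma = elastic_sigma,
                 seed = as.integer(seed)),
            class = "train_config")
}

## bilinear sampling of a matrix at fractional coordinates; outside -> fill
bilinear_sample <- function(img, yi, xi, fill = 0) {
  n <- nrow(img); p <- ncol(img)
  y0 <- floor(yi); x0 <- floor(xi)
  fy <- yi - y0; fx <- xi - x0
  get <- function(r, c) {
    ok <- r >= 1 & r <= n & c >= 1 & c <= p
    v <- numeric(length(r)); v[] <- fill
    v[ok] <- img[cbind(r[ok], c[ok])]
    v
  }
  get(y0, x0) * (1 - fy) * (1 - fx) + get(y0 + 1, x0) * fy * (1 - fx) +
    get(y0, x0 + 1) * (1 - fy) * fx + get(y0 + 1, x0 + 1) * fy * fx
}

nearest_sample <- function(img, yi, xi, fill = 0L) {
  n <- nrow(img); p <- ncol(img)
  r <- round(yi); c <- round(xi)
  ok <- r >= 1 & r <= n & c >= 1 & c <= p
  v <- rep(fill, length(r))
  v[ok] <- img[cbind(r[ok], c[ok])]
  v
}

## draw one random geometric transform and apply it to an (H, W, C) image
## stack (bilinear) and its label grid (nearest), then random-crop.
## Consumes the current RNG stream.
augment_sample <- function(x, labels, tcfg) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  theta <- runif(1, tcfg$rotation[1], tcfg$rotation[2]) * pi / 180
  k <- runif(1, tcfg$scale[1], tcfg$scale[2])
  sh <- tan(runif(1, tcfg$shear[1], tcfg$shear[2]) * pi / 180)
  fy <- if (tcfg$flips && runif(1) < 0.5) -1 else 1
  fx <- if (tcfg$flips && runif(1) < 0.5) -1 else 1
  ## forward map: scale, shear, rotate, flip; sampling uses its inverse
  A <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2) %*%
       matrix(c(1, 0, sh, 1), 2) %*% diag(c(k * fy, k * fx))
  Ainv <- solve(A)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  gy <- rep(seq_len(H) - cy, times = W)
  gx <- rep(seq_len(W) - cx, each = H)
  yi <- Ainv[1, 1] * gy + Ainv[1, 2] * gx + cy
  xi <- Ainv[2, 1] * gy + Ainv[2, 2] * gx + cx
  if (tcfg$elastic) {
    disp <- elastic_field(H, W, tcfg$elastic_alpha, tcfg$elastic_sigma)
    yi <- yi + as.vector(disp$dy)
    xi <- xi + as.vector(disp$dx)
  }
  xw <- array(0, d)
  for (ch in seq_len(C))
    xw[, , ch] <- matrix(bilinear_sample(x[, , ch], yi, xi), H, W)
  lw <- matrix(nearest_sample(labels, yi, xi), H, W)
  ## random crop
  cs <- min(tcfg$crop_size, H, W)
  r0 <- if (H > cs) sample.int(H - cs + 1, 1) else 1
  c0 <- if (W > cs) sample.int(W - cs + 1, 1) else 1
  list(x = xw[r0:(r0 + cs - 1), c0:(c0 + cs - 1), , drop = FALSE],
       labels = lw[r0:(r0 + cs - 1), c0:(c0 + cs - 1)])
}

## smooth random displacement field for elastic deformation
elastic_field <- function(H, W, alpha, sigma) {
  dy <- matrix(as.numeric(EBImage::gblur(matrix(runif(H * W, -1, 1), H, W),
                                         sigma = sigma)), H, W)
  dx <- matrix(as.numeric(EBImage::gblur(matrix(runif(H * W, -1, 1), H, W),
                                         sigma = sigma)), H, W)
  list(dy = dy / max(abs(dy)) * alpha, dx = dx / max(abs(dx)) * alpha)
}

## normalize heterogeneous training-sample inputs to (x, labels)
as_training_sample <- function(s) {
  if (inherits(s, "phantom_sample"))
    return(list(x = pair_to_input(s$pair), labels = tri_mask_to_labels(s$masks)))
  if (is.list(s) && inherits(s$pair, "polarized_pair")) {
    lab <- if (inherits(s$masks, "tri_mask")) tri_mask_to_labels(s$masks)
           else as.matrix(s$labels)
    if (!identical(dim(lab), dim(s$pair$co)))
      stop("mask/image dimension mismatch in training sample")
    return(list(x = pair_to_input(s$pair), labels = lab))
  }
  stop("training samples must be phantom_sample objects or lists with ",
       "a polarized_pair and a tri_mask (or label grid)")
}

#' Train the segmentation network
#'
#' Fully supervised end-to-end training on (image pair, three-class mask)
#' samples. Each epoch shuffles the samples and applies fresh random
#' augmentations; gradients are averaged over each mini-batch and applied
#' with Adam. The run is a deterministic function of the data, the
#' network, and the training config (including its seed).
#'
#' @param net a [build_network()] model.
#' @param samples list of training samples: `phantom_sample` objects or
#'   lists with elements `pair` ([polarized_pair()]) and `masks`
#'   ([tri_mask()]) or `labels` (0/1/2 grid).
#' @param tcfg a [train_config()].
#' @param verbose print per-epoch mean loss.
#' @return A list with `net` (trained model) and `loss_history` (mean
#'   cross-entropy per epoch).
#' @export
train_network <- function(net, samples, tcfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(net, "unet"), inherits(tcfg, "train_config"))
  if (!is.list(samples) || length(samples) == 0)
    stop("training requires at least one sample")
  data <- lapply(samples, as_training_sample)
  f <- 2^(net$cfg$levels - 1)
  if (tcfg$crop_size %% f != 0)
    stop("crop_size must be a multiple of ", f, " (2^(levels-1))")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(tcfg$seed)

  params <- net$params
  state <- adam_init(params)
  nS <- length(data)
  loss_history <- numeric(tcfg$epochs)
  for (ep in seq_len(tcfg$epochs)) {
    ord <- sample.int(nS)
    losses <- c()
    i <- 1
    while (i <= nS) {
      idx <- ord[i:min(i + tcfg$batch_size - 1, nS)]
      acc <- NULL; bloss <- 0
      for (j in idx) {
        aug <- augment_sample(data[[j]]$x, data[[j]]$labels, tcfg)
        lg <- unet_loss_grad(structure(list(cfg = net$cfg, params = params),
                                       class = "unet"),
                             aug$x, aug$labels)
        bloss <- bloss + lg$loss
        acc <- if (is.null(acc)) lg$grads else accumulate_grads(acc, lg$grads)
      }
      nb <- length(idx)
      acc <- scale_grads(acc, 1 / nb)
      st <- adam_step(params, acc, state, lr = tcfg$learning_rate)
      params <- st$params; state <- st$state
      losses <- c(losses, bloss / nb)
      i <- i + tcfg$batch_size
    }
    loss_history[ep] <- mean(losses)
    if (verbose)
      message(sprintf("epoch %3d/%d  loss %.5f", ep, tcfg$epochs, loss_history[ep]))
  }
  list(net = structure(list(cfg = net$cfg, params = params), class = "unet"),
       loss_history = loss_history)
}

accumulate_grads <- function(a, b) {
  for (nm in names(a)) for (w in names(a[[nm]]))
    a[[nm]][[w]] <- a[[nm]][[w]] + b[[nm]][[w]]
  a
}

scale_grads <- function(g, s) {
  for (nm in names(g)) for (w in names(g[[nm]]))
    g[[nm]][[w]] <- g[[nm]][[w]] * s
  g
}

#' Dice coefficient of two binary masks
#'
#' `2|A intersect B| / (|A| + |B|)`; returns 1 when both masks are empty.
#'
#' @param a,b logical (or 0/1) matrices of equal dimensions.
#' @return Scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  a <- a != 0; b <- b != 0
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Mean high-quality-class Dice over held-out samples
#'
#' Predicts each sample, takes the per-pixel argmax class, and compares
#' the high-quality class against the ground-truth high-quality mask.
#'
#' @param net trained model.
#' @param samples list of `phantom_sample` objects (or pair+masks lists).
#' @return Numeric vector of per-sample Dice scores.
#' @export
evaluate_dice <- function(net, samples) {
  vapply(samples, function(s) {
    ts <- as_training_sample(s)
    pair <- if (inherits(s, "phantom_sample")) s$pair else s$pair
    probs <- predict_pair(net, pair)
    pred <- probs$high_quality >= pmax(probs$background, probs$ambiguous)
    dice_coefficient(pred, ts$labels == 2L)
  }, numeric(1))
}
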