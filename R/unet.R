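## Encoder-decoder segmentation network (standard U-Net).
##
## A from-scratch implementation: 3x3 same-padding convolutions via
## im2col + BLAS matrix multiplication, ReLU, 2x2 max pooling, 2x2
## stride-2 transposed-convolution upsampling, skip concatenation at each
## resolution level, and a 3-class softmax head trained with
## cross-entropy (equal class weights) and Adam. Feature maps are R
## arrays of shape (H, W, C); everything runs on the CPU.

#' Network configuration
#'
#' @param levels number of resolution levels (default 5: four poolings).
#' @param base_channels feature maps at the first level (default 16,
#'   doubling at each level).
#' @param in_channels input channels; 2 (co- and cross-polarized).
#' @param out_classes output classes; 3 (background, ambiguous,
#'   high-quality).
#' @param seed parameter-initialization seed.
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(levels = 5, base_channels = 16, in_channels = 2,
                        out_classes = 3, seed = 1) {
  stopifnot(levels >= 2, base_channels >= 1)
  if (in_channels != 2)
    stop("the network takes exactly 2 input channels (co and cross)")
  if (out_classes != 3)
    stop("the network has exactly 3 output classes ",
         "(background, ambiguous, high-quality)")
  structure(list(levels = as.integer(levels),
                 base_channels = as.integer(base_channels),
                 in_channels = 2L, out_classes = 3L, seed = as.integer(seed)),
            class = "unet_config")
}

## ---- layer primitives -----------------------------------------------

conv3_init <- function(cin, cout) {
  list(W = matrix(rnorm(cin * 9 * cout, 0, sqrt(2 / (cin * 9))), cin * 9, cout),
       b = numeric(cout))
}

conv3_forward <- function(x, p) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  xp <- array(0, c(H + 2, W + 2, C))
  xp[2:(H + 1), 2:(W + 1), ] <- x
  xcol <- matrix(0, H * W, C * 9)
  k <- 0
  for (dj in 0:2) for (di in 0:2) {
    k <- k + 1
    xcol[, ((k - 1) * C + 1):(k * C)] <- matrix(xp[di + (1:H), dj + (1:W), ], H * W)
  }
  out <- xcol %*% p$W
  out <- out + matrix(p$b, nrow(out), ncol(out), byrow = TRUE)
  list(out = array(out, c(H, W, ncol(p$W))), xcol = xcol, dim = d)
}

conv3_backward <- function(dout, p, cache) {
  d <- cache$dim; H <- d[1]; W <- d[2]; C <- d[3]
  dmat <- matrix(dout, H * W)
  dW <- crossprod(cache$xcol, dmat)
  db <- colSums(dmat)
  dxcol <- tcrossprod(dmat, p$W)
  dxp <- array(0, c(H + 2, W + 2, C))
  k <- 0
  for (dj in 0:2) for (di in 0:2) {
    k <- k + 1
    dxp[di + (1:H), dj + (1:W), ] <- dxp[di + (1:H), dj + (1:W), ] +
      array(dxcol[, ((k - 1) * C + 1):(k * C)], c(H, W, C))
  }
  list(dx = dxp[2:(H + 1), 2:(W + 1), , drop = FALSE], dW = dW, db = db)
}

conv1_init <- function(cin, cout) {
  list(W = matrix(rnorm(cin * cout, 0, sqrt(2 / cin)), cin, cout),
       b = numeric(cout))
}

conv1_forward <- function(x, p) {
  d <- dim(x)
  xmat <- matrix(x, d[1] * d[2])
  out <- xmat %*% p$W
  out <- out + matrix(p$b, nrow(out), ncol(out), byrow = TRUE)
  list(out = array(out, c(d[1], d[2], ncol(p$W))), xmat = xmat, dim = d)
}

conv1_backward <- function(dout, p, cache) {
  d <- cache$dim
  dmat <- matrix(dout, d[1] * d[2])
  list(dx = array(tcrossprod(dmat, p$W), d),
       dW = crossprod(cache$xmat, dmat), db = colSums(dmat))
}

relu_forward <- function(x) list(out = pmax(x, 0), mask = x > 0)
relu_backward <- function(dout, cache) dout * cache$mask

maxpool_forward <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  stopifnot(H %% 2 == 0, W %% 2 == 0)
  m <- cbind(as.vector(x[seq(1, H, 2), seq(1, W, 2), , drop = FALSE]),
             as.vector(x[seq(2, H, 2), seq(1, W, 2), , drop = FALSE]),
             as.vector(x[seq(1, H, 2), seq(2, W, 2), , drop = FALSE]),
             as.vector(x[seq(2, H, 2), seq(2, W, 2), , drop = FALSE]))
  arg <- max.col(m, ties.method = "first")
  list(out = array(m[cbind(seq_len(nrow(m)), arg)], c(H / 2, W / 2, C)),
       arg = arg, dim = d)
}

maxpool_backward <- function(dout, cache) {
  d <- cache$dim; H <- d[1]; W <- d[2]; C <- d[3]
  h2 <- H / 2; w2 <- W / 2
  idx0 <- 0:(h2 * w2 * C - 1)
  i2 <- idx0 %% h2
  j2 <- (idx0 %/% h2) %% w2
  cc <- idx0 %/% (h2 * w2)
  di <- c(0L, 1L, 0L, 1L)[cache$arg]
  dj <- c(0L, 0L, 1L, 1L)[cache$arg]
  target <- (2L * i2 + di) + (2L * j2 + dj) * H + cc * H * W + 1L
  dx <- array(0, d)
  dx[target] <- as.vector(dout)
  dx
}

upconv_init <- function(cin, cout) {
  list(W = array(rnorm(cin * cout * 4, 0, sqrt(2 / cin)), c(cin, cout, 4)),
       b = numeric(cout))
}

## transposed convolution, 2x2 kernel, stride 2: output is 2H x 2W
upconv_forward <- function(x, p) {
  d <- dim(x); h <- d[1]; w <- d[2]
  cout <- dim(p$W)[2]
  xmat <- matrix(x, h * w)
  out <- array(0, c(2 * h, 2 * w, cout))
  pos <- list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  for (q in 1:4) {
    Y <- xmat %*% p$W[, , q]
    Y <- Y + matrix(p$b, nrow(Y), cout, byrow = TRUE)
    out[seq(1, 2 * h, 2) + pos[[q]][1], seq(1, 2 * w, 2) + pos[[q]][2], ] <-
      array(Y, c(h, w, cout))
  }
  list(out = out, xmat = xmat, dim = d)
}

upconv_backward <- function(dout, p, cache) {
  d <- cache$dim; h <- d[1]; w <- d[2]
  cin <- dim(p$W)[1]; cout <- dim(p$W)[2]
  dW <- array(0, dim(p$W)); db <- numeric(cout)
  dxmat <- matrix(0, h * w, cin)
  pos <- list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  for (q in 1:4) {
    dY <- matrix(dout[seq(1, 2 * h, 2) + pos[[q]][1],
                      seq(1, 2 * w, 2) + pos[[q]][2], , drop = FALSE], h * w)
    dW[, , q] <- crossprod(cache$xmat, dY)
    db <- db + colSums(dY)
    dxmat <- dxmat + tcrossprod(dY, p$W[, , q])
  }
  list(dx = array(dxmat, d), dW = dW, db = db)
}

softmax_probs <- function(logits) {
  d <- dim(logits)
  l <- matrix(logits, d[1] * d[2])
  l <- l - apply(l, 1, max)
  e <- exp(l)
  array(e / rowSums(e), d)
}

## cross-entropy loss over a 0-based class-label grid; returns loss and
## gradient w.r.t. logits (already divided by pixel count)
softmax_ce <- function(logits, labels) {
  d <- dim(logits)
  n <- d[1] * d[2]
  p <- matrix(softmax_probs(logits), n)
  tgt <- cbind(seq_len(n), as.vector(labels) + 1L)
  loss <- -mean(log(pmax(p[tgt], 1e-12)))
  p[tgt] <- p[tgt] - 1
  list(loss = loss, dlogits = array(p / n, d))
}

## ---- network --------------------------------------------------------

#' Build an encoder-decoder segmentation network
#'
#' Constructs the parameter set of a standard U-Net: at each encoder
#' level two 3x3 convolutions + ReLU followed by 2x2 max pooling; a
#' two-convolution bottleneck; and a decoder that upsamples with 2x2
#' stride-2 transposed convolutions, concatenates the skip connection
#' from the same level, and applies two more convolutions. A final 1x1
#' convolution maps to 3 class logits. Same-padding keeps the spatial
#' output equal to the input. Initialization is He-normal, seeded from
#' the config, so two builds with the same seed are identical.
#'
#' @param cfg a [unet_config()].
#' @return An object of class `unet`: list with `cfg` and `params`.
#' @export
build_network <- function(cfg = unet_config()) {
  stopifnot(inherits(cfg, "unet_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)
  L <- cfg$levels
  ch <- cfg$base_channels * 2^(0:(L - 1))
  params <- list()
  cin <- cfg$in_channels
  for (l in 1:L) {
    params[[paste0("enc", l, "_conv1")]] <- conv3_init(cin, ch[l])
    params[[paste0("enc", l, "_conv2")]] <- conv3_init(ch[l], ch[l])
    cin <- ch[l]
  }
  for (l in (L - 1):1) {
    params[[paste0("up", l)]] <- upconv_init(ch[l + 1], ch[l])
    params[[paste0("dec", l, "_conv1")]] <- conv3_init(2 * ch[l], ch[l])
    params[[paste0("dec", l, "_conv2")]] <- conv3_init(ch[l], ch[l])
  }
  params[["out"]] <- conv1_init(ch[1], cfg$out_classes)
  structure(list(cfg = cfg, params = params), class = "unet")
}

#' @export
print.unet <- function(x, ...) {
  npar <- sum(vapply(x$params, function(p) length(p$W) + length(p$b), numeric(1)))
  cat(sprintf("<unet> %d levels, base %d channels, %s parameters\n",
              x$cfg$levels, x$cfg$base_channels, format(npar, big.mark = ",")))
  invisible(x)
}

check_input_dims <- function(cfg, H, W) {
  f <- 2^(cfg$levels - 1)
  if (H %% f != 0 || W %% f != 0)
    stop("input dimensions ", H, "x", W, " are not divisible by ", f,
         " (2^(levels-1)); pad or crop the image to a multiple of ", f)
}

## full forward pass; keep_cache = TRUE retains everything backward needs
unet_forward <- function(net, x, keep_cache = FALSE) {
  cfg <- net$cfg; p <- net$params
  d <- dim(x)
  if (length(d) != 3 || d[3] != cfg$in_channels)
    stop("input must be an (H, W, ", cfg$in_channels, ") array; got ",
         paste(d, collapse = "x"))
  check_input_dims(cfg, d[1], d[2])
  L <- cfg$levels
  caches <- list(); skips <- list()
  for (l in 1:L) {
    c1 <- conv3_forward(x, p[[paste0("enc", l, "_conv1")]])
    r1 <- relu_forward(c1$out)
    c2 <- conv3_forward(r1$out, p[[paste0("enc", l, "_conv2")]])
    r2 <- relu_forward(c2$out)
    if (keep_cache) caches[[paste0("enc", l)]] <- list(c1 = c1, r1 = r1, c2 = c2, r2 = r2)
    if (l < L) {
      skips[[l]] <- r2$out
      mp <- maxpool_forward(r2$out)
      if (keep_cache) caches[[paste0("pool", l)]] <- mp
      x <- mp$out
    } else x <- r2$out
  }
  for (l in (L - 1):1) {
    up <- upconv_forward(x, p[[paste0("up", l)]])
    cs <- dim(skips[[l]])[3]
    xc <- array(c(skips[[l]], up$out), c(dim(up$out)[1], dim(up$out)[2],
                                         cs + dim(up$out)[3]))
    c1 <- conv3_forward(xc, p[[paste0("dec", l, "_conv1")]])
    r1 <- relu_forward(c1$out)
    c2 <- conv3_forward(r1$out, p[[paste0("dec", l, "_conv2")]])
    r2 <- relu_forward(c2$out)
    if (keep_cache) caches[[paste0("dec", l)]] <- list(up = up, cs = cs, c1 = c1,
                                                       r1 = r1, c2 = c2, r2 = r2)
    x <- r2$out
  }
  head <- conv1_forward(x, p[["out"]])
  if (keep_cache) caches[["out"]] <- head
  list(logits = head$out, caches = caches)
}

## backward pass from dlogits; returns gradient list parallel to params
unet_backward <- function(net, dlogits, caches) {
  cfg <- net$cfg; p <- net$params
  L <- cfg$levels
  grads <- list()
  bo <- conv1_backward(dlogits, p[["out"]], caches[["out"]])
  grads[["out"]] <- list(W = bo$dW, b = bo$db)
  ## decoder, from the full-resolution level down to the bottleneck
  dx <- bo$dx
  dskip <- vector("list", L - 1)
  for (l in 1:(L - 1)) {
    cc <- caches[[paste0("dec", l)]]
    dr2 <- relu_backward(dx, cc$r2)
    b2 <- conv3_backward(dr2, p[[paste0("dec", l, "_conv2")]], cc$c2)
    grads[[paste0("dec", l, "_conv2")]] <- list(W = b2$dW, b = b2$db)
    dr1 <- relu_backward(b2$dx, cc$r1)
    b1 <- conv3_backward(dr1, p[[paste0("dec", l, "_conv1")]], cc$c1)
    grads[[paste0("dec", l, "_conv1")]] <- list(W = b1$dW, b = b1$db)
    dskip[[l]] <- b1$dx[, , 1:cc$cs, drop = FALSE]
    dup <- b1$dx[, , (cc$cs + 1):dim(b1$dx)[3], drop = FALSE]
    bu <- upconv_backward(dup, p[[paste0("up", l)]], cc$up)
    grads[[paste0("up", l)]] <- list(W = bu$dW, b = bu$db)
    dx <- bu$dx                      # flows into the next-coarser level
  }
  ## encoder, from the bottleneck back up to the input; below the top
  ## level the output gradient has two sources: the pooled path and the
  ## skip connection
  for (l in L:1) {
    if (l < L)
      dx <- maxpool_backward(dx, caches[[paste0("pool", l)]]) + dskip[[l]]
    cc <- caches[[paste0("enc", l)]]
    dr2 <- relu_backward(dx, cc$r2)
    b2 <- conv3_backward(dr2, p[[paste0("enc", l, "_conv2")]], cc$c2)
    grads[[paste0("enc", l, "_conv2")]] <- list(W = b2$dW, b = b2$db)
    dr1 <- relu_backward(b2$dx, cc$r1)
    b1 <- conv3_backward(dr1, p[[paste0("enc", l, "_conv1")]], cc$c1)
    grads[[paste0("enc", l, "_conv1")]] <- list(W = b1$dW, b = b1$db)
    dx <- b1$dx
  }
  grads
}

## loss and gradients for one (input, label) pair
unet_loss_grad <- function(net, x, labels) {
  fw <- unet_forward(net, x, keep_cache = TRUE)
  ce <- softmax_ce(fw$logits, labels)
  grads <- unet_backward(net, ce$dlogits, fw$caches)
  list(loss = ce$loss, grads = grads)
}

#' Per-pixel class probabilities for an image pair
#'
#' Runs the network on a co-/cross-polarized pair (intensities are scaled
#' to `[0, 1]` by dividing by 255). Inference is deterministic for a
#' fixed model. Output spatial dimensions equal the input dimensions and
#' per-pixel probabilities sum to 1.
#'
#' @param net a trained or freshly built [build_network()] model.
#' @param pair a [polarized_pair()] whose dimensions are divisible by
#'   `2^(levels-1)`.
#' @return An object of class `probability_maps`: list of three matrices
#'   `background`, `ambiguous`, `high_quality`.
#' @export
predict_pair <- function(net, pair) {
  stopifnot(inherits(net, "unet"), inherits(pair, "polarized_pair"))
  x <- pair_to_input(pair)
  fw <- unet_forward(net, x, keep_cache = FALSE)
  probs <- softmax_probs(fw$logits)
  structure(list(background = probs[, , 1], ambiguous = probs[, , 2],
                 high_quality = probs[, , 3]),
            class = "probability_maps")
}

pair_to_input <- function(pair) {
  d <- dim(pair$co)
  x <- array(0, c(d[1], d[2], 2))
  x[, , 1] <- pair$co / 255
  x[, , 2] <- pair$cross / 255
  x
}

#' @export
print.probability_maps <- function(x, ...) {
  cat(sprintf("<probability_maps> %d x %d px, classes: background/ambiguous/high_quality\n",
              nrow(x$background), ncol(x$background)))
  invisible(x)
}

## ---- Adam optimizer --------------------------------------------------

adam_init <- function(params) {
  list(t = 0,
       m = lapply(params, function(p) lapply(p, function(w) w * 0)),
       v = lapply(params, function(p) lapply(p, function(w) w * 0)))
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    for (w in names(params[[nm]])) {
      g <- grads[[nm]][[w]]
      state$m[[nm]][[w]] <- beta1 * state$m[[nm]][[w]] + (1 - beta1) * g
      state$v[[nm]][[w]] <- beta2 * state$v[[nm]][[w]] + (1 - beta2) * g^2
      mhat <- state$m[[nm]][[w]] / bc1
      vhat <- state$v[[nm]][[w]] / bc2
      params[[nm]][[w]] <- params[[nm]][[w]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is self-describing: it stores the network configuration
#' (including the initialization seed) together with the parameters.
#'
#' @param net a `unet` object.
#' @param path checkpoint file path.
#' @return `path` invisibly; `load_unet` returns the `unet`.
#' @export
save_unet <- function(net, path) {
  stopifnot(inherits(net, "unet"))
  saveRDS(list(cfg = net$cfg, params = net$params, format = "fpolcyto-unet-1"),
          path)
  invisible(path)
}

#' @rdname save_unet
#' @export
load_unet <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "fpolcyto-unet-1"))
    stop("not a recognized model checkpoint: ", path)
  structure(list(cfg = obj$cfg, params = obj$params), class = "unet")
}
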