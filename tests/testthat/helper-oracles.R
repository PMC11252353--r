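## Independent brute-force oracles used to cross-check the morphology and
## labeling implementations. These work on coordinate sets rather than
## matrix shifts, per the textbook set definitions.

## dilation as the union of kernel translates of the foreground set
oracle_dilate <- function(mask, kernel, iterations = 1) {
  n <- nrow(mask); p <- ncol(mask)
  kc <- which(kernel != 0, arr.ind = TRUE)
  off <- cbind(kc[, 1] - (nrow(kernel) + 1) %/% 2,
               kc[, 2] - (ncol(kernel) + 1) %/% 2)
  for (it in seq_len(iterations)) {
    fg <- which(mask != 0, arr.ind = TRUE)
    out <- matrix(FALSE, n, p)
    for (k in seq_len(nrow(off))) {
      ii <- fg[, 1] + off[k, 1]
      jj <- fg[, 2] + off[k, 2]
      keep <- ii >= 1 & ii <= n & jj >= 1 & jj <= p
      out[cbind(ii[keep], jj[keep])] <- TRUE
    }
    mask <- out
  }
  mask
}

## erosion through complement duality: pad with background, complement,
## dilate with the reflected kernel, complement, crop
oracle_erode <- function(mask, kernel, iterations = 1) {
  n <- nrow(mask); p <- ncol(mask)
  r <- max(nrow(kernel), ncol(kernel))
  refl <- kernel[rev(seq_len(nrow(kernel))), rev(seq_len(ncol(kernel))), drop = FALSE]
  for (it in seq_len(iterations)) {
    padded <- matrix(FALSE, n + 2 * r, p + 2 * r)
    padded[r + (1:n), r + (1:p)] <- mask != 0
    comp <- !padded
    dil <- oracle_dilate(comp, refl)
    mask <- (!dil)[r + (1:n), r + (1:p)]
  }
  mask
}

oracle_open <- function(mask, kernel) {
  oracle_dilate(oracle_erode(mask, kernel), kernel)
}

oracle_refine <- function(mask) {
  k3 <- matrix(TRUE, 3, 3)
  d <- seq(-7, 7)
  ell <- outer(d, d, function(dy, dx) (dy / 7)^2 + (dx / 7)^2 <= 1)
  m <- oracle_dilate(mask, k3, iterations = 3)
  m <- oracle_erode(m, k3, iterations = 3)
  oracle_open(m, ell)
}

## breadth-first flood-fill labeling; labels assigned in raster-scan
## (row-major) order of each region's first pixel
oracle_label <- function(mask, connectivity = 8) {
  n <- nrow(mask); p <- ncol(mask)
  nb <- if (connectivity == 8)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  lab <- matrix(0L, n, p)
  cur <- 0L
  for (i in seq_len(n)) for (j in seq_len(p)) {   # raster scan
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      queue <- list(c(i, j)); lab[i, j] <- cur
      while (length(queue) > 0) {
        q <- queue[[1]]; queue <- queue[-1]
        for (k in seq_len(nrow(nb))) {
          ii <- q[1] + nb[k, 1]; jj <- q[2] + nb[k, 2]
          if (ii >= 1 && ii <= n && jj >= 1 && jj <= p &&
              mask[ii, jj] && lab[ii, jj] == 0L) {
            lab[ii, jj] <- cur
            queue[[length(queue) + 1]] <- c(ii, jj)
          }
        }
      }
    }
  }
  lab
}

## small phantom builders shared across tests
desk_phantom_spec <- function(seed, image_size = 128, n_cells = 5,
                              noise_sd = 1.5, fpols = seq(0.10, 0.33,
                                                          length.out = n_cells),
                              ...) {
  phantom_spec(image_size = image_size, n_cells = n_cells,
               cell_radius_range = c(8, 16), cluster_fraction = 0.2,
               ambiguous_fraction = 0.2, noise_sd = noise_sd,
               fpol_targets = fpols, seed = seed, ...)
}

random_mask <- function(n = 64, density = 0.3, blobs = 6) {
  m <- matrix(runif(n * n) < density * 0.3, n, n)
  for (b in seq_len(blobs)) {
    cy <- sample.int(n, 1); cx <- sample.int(n, 1)
    r <- sample(2:9, 1)
    ys <- max(1, cy - r):min(n, cy + r)
    xs <- max(1, cx - r):min(n, cx + r)
    m[ys, xs] <- m[ys, xs] |
      outer(ys - cy, xs - cx, function(a, b) a^2 + b^2 <= r^2)
  }
  m
}
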