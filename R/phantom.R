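## Synthetic polarized-image phantom generation.
##
## Phantoms emulate pairs of averaged co-/cross-polarized fluorescence
## emission images of methylene-blue stained cells: smooth elliptical
## cell blobs with a brighter nuclear core on a near-zero background,
## optional cell clustering, blurred/dim "ambiguous" cells, additive
## noise, and 8-bit quantization. The cross channel is derived from the
## co channel by inverting the Fpol formula per cell, so every
## high-quality cell has a known ground-truth Fpol.

#' Phantom generation parameters
#'
#' @param image_size pixels per side of the (square) image; default 1000,
#'   reducible for desk-scale tests.
#' @param pixel_size micrometres per pixel.
#' @param n_cells number of high-quality cells.
#' @param fpol_targets per-cell true Fpol values in `(-1, 1]`, recycled to
#'   `n_cells`. Defaults span the range observed in thyroid cells
#'   (0.10-0.33).
#' @param base_co_intensity mean co-channel level per cell on the 8-bit
#'   scale, in `[3, 254]`; recycled to `n_cells`.
#' @param g_factor instrument calibration factor.
#' @param cell_radius_range min/max cell semi-major axis in pixels.
#' @param cluster_fraction fraction of cells placed adjacent to an
#'   already-placed cell (exercises touching-cell merging downstream).
#' @param ambiguous_fraction additional blurred, dim cells rendered as
#'   "ambiguous" (low-quality) signal, as a fraction of `n_cells`. These
#'   appear only in the ambiguous mask and carry no ground-truth Fpol.
#' @param noise_sd SD of additive Gaussian noise, 8-bit counts.
#' @param background_level constant background level in counts; must stay
#'   below the Fpol validity threshold of 3 counts.
#' @param quantize if TRUE (default) intensities are rounded half-up to
#'   integers and clipped to `[0, 255]`, matching the 8-bit input format.
#' @param seed integer RNG seed; the phantom is a deterministic function
#'   of the spec including the seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 1000,
                         pixel_size = PIXEL_SIZE_DEFAULT,
                         n_cells = 30,
                         fpol_targets = seq(0.10, 0.33, length.out = max(n_cells, 1)),
                         base_co_intensity = 160,
                         g_factor = FPOL_G_DEFAULT,
                         cell_radius_range = c(15, 35),
                         cluster_fraction = 0.2,
                         ambiguous_fraction = 0.15,
                         noise_sd = 2,
                         background_level = 1,
                         quantize = TRUE,
                         seed = 1) {
  stopifnot(image_size >= 16, pixel_size > 0, n_cells >= 0,
            g_factor > 0, length(cell_radius_range) == 2,
            cell_radius_range[1] > 0,
            cell_radius_range[2] >= cell_radius_range[1],
            cluster_fraction >= 0, cluster_fraction <= 1,
            ambiguous_fraction >= 0, noise_sd >= 0)
  if (any(fpol_targets <= -1 | fpol_targets > 1))
    stop("fpol_targets must lie in (-1, 1]")
  if (any(base_co_intensity < 3 | base_co_intensity > 254))
    stop("base_co_intensity must lie in [3, 254]")
  if (background_level < 0 || background_level >= 3)
    stop("background_level must lie in [0, 3) so background pixels fall ",
         "below the Fpol validity threshold")
  if (image_size <= 2 * cell_radius_range[2])
    stop("image_size must exceed twice the maximum cell radius")
  structure(list(image_size = as.integer(image_size),
                 pixel_size = pixel_size, n_cells = as.integer(n_cells),
                 fpol_targets = fpol_targets,
                 base_co_intensity = base_co_intensity,
                 g_factor = g_factor,
                 cell_radius_range = cell_radius_range,
                 cluster_fraction = cluster_fraction,
                 ambiguous_fraction = ambiguous_fraction,
                 noise_sd = noise_sd, background_level = background_level,
                 quantize = isTRUE(quantize), seed = as.integer(seed)),
            class = "phantom_spec")
}

## Pixel set of a rotated ellipse, returned as linear (column-major)
## indices into an size x size matrix.
ellipse_pixels <- function(cy, cx, a, b, theta, size) {
  r <- ceiling(a) + 1
  ys <- max(1, floor(cy - r)):min(size, ceiling(cy + r))
  xs <- max(1, floor(cx - r)):min(size, ceiling(cx + r))
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  rho2 <- u^2 + v^2
  sel <- which(rho2 <= 1)
  list(idx = as.vector(outer(ys, (xs - 1) * size, `+`))[sel],
       rho2 = rho2[sel])
}

#' Generate one synthetic phantom sample
#'
#' Deterministic given the spec (including its seed). High-quality cells
#' are elliptical blobs with a Gaussian-profile brighter core; their cross
#' channel is set per cell via [fpol_to_cross_intensity()] so that
#' quantifying the ground-truth mask recovers the specified Fpol (exactly
#' with `quantize = FALSE`, within the 8-bit quantization bound
#' otherwise). Ambiguous cells are dimmer, Gaussian-blurred blobs that
#' appear only in the ambiguous mask. Cells that cannot be placed within
#' the image bounds raise an error.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_sample`: list with `pair`
#'   ([polarized_pair()]), `masks` ([tri_mask()]), `labels` (ground-truth
#'   label matrix of high-quality cells, raster-ordered), `truth`
#'   (data.frame cell_id, fpol, area_px) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  n <- spec$image_size
  nc <- spec$n_cells
  fpols <- if (nc > 0) rep_len(spec$fpol_targets, nc) else numeric(0)
  bases <- if (nc > 0) rep_len(spec$base_co_intensity, nc) else numeric(0)

  co <- matrix(spec$background_level, n, n)
  cross <- matrix(spec$background_level, n, n)
  labels <- matrix(0L, n, n)
  ambiguous <- matrix(FALSE, n, n)

  placed <- data.frame(cy = numeric(0), cx = numeric(0), r = numeric(0))
  place_cell <- function(r, cluster, min_gap) {
    margin <- r + 2
    for (try in 1:400) {
      if (cluster && nrow(placed) > 0) {
        j <- sample.int(nrow(placed), 1)
        ang <- runif(1, 0, 2 * pi)
        d <- placed$r[j] + r + 1          # adjacent: ~1 px gap, may touch
        cy <- placed$cy[j] + d * sin(ang)
        cx <- placed$cx[j] + d * cos(ang)
        if (cy < margin || cy > n - margin || cx < margin || cx > n - margin) next
        ok <- all(sqrt((placed$cy - cy)^2 + (placed$cx - cx)^2) >= placed$r + r + 1)
      } else {
        cy <- runif(1, margin, n - margin)
        cx <- runif(1, margin, n - margin)
        ok <- nrow(placed) == 0 ||
          all(sqrt((placed$cy - cy)^2 + (placed$cx - cx)^2) >= placed$r + r + min_gap)
      }
      if (ok) return(c(cy, cx))
    }
    stop("could not place a cell of radius ", r,
         " within image bounds; reduce n_cells or cell radii")
  }

  truth <- vector("list", nc)
  for (i in seq_len(nc)) {
    r <- runif(1, spec$cell_radius_range[1], spec$cell_radius_range[2])
    cluster <- runif(1) < spec$cluster_fraction
    pos <- place_cell(r, cluster, min_gap = 3)
    placed[nrow(placed) + 1, ] <- c(pos[1], pos[2], r)
    q <- runif(1, 0.65, 1)                  # axis ratio
    theta <- runif(1, 0, pi)
    ep <- ellipse_pixels(pos[1], pos[2], r, q * r, theta, n)
    keep <- labels[ep$idx] == 0L            # keep truth sets disjoint
    idx <- ep$idx[keep]
    rho2 <- ep$rho2[keep]
    ## smooth profile: dimmer rim, brighter nuclear core
    prof <- 0.75 + 0.45 * exp(-rho2 / (2 * 0.35^2))
    ico <- pmin(bases[i] * prof, 252)
    co[idx] <- ico
    cross[idx] <- fpol_to_cross_intensity(ico, fpols[i], spec$g_factor)
    labels[idx] <- i
    truth[[i]] <- list(cell_id = i, fpol = fpols[i], area_px = length(idx))
  }

  ## ambiguous (low-quality) cells: dim, blurred, no ground truth
  n_amb <- round(spec$ambiguous_fraction * nc)
  if (n_amb > 0) {
    amb_co <- matrix(0, n, n)
    for (i in seq_len(n_amb)) {
      r <- runif(1, spec$cell_radius_range[1], spec$cell_radius_range[2])
      pos <- place_cell(r, cluster = FALSE, min_gap = 6)
      placed[nrow(placed) + 1, ] <- c(pos[1], pos[2], r)
      q <- runif(1, 0.65, 1); theta <- runif(1, 0, pi)
      ep <- ellipse_pixels(pos[1], pos[2], r, q * r, theta, n)
      amb_co[ep$idx] <- pmax(amb_co[ep$idx], 0.45 * mean(bases))
      ambiguous[ep$idx] <- TRUE
    }
    sigma <- max(2, spec$cell_radius_range[1] / 3)
    ## gblur can ring slightly negative at sharp edges; clamp
    amb_co <- pmax(matrix(as.numeric(EBImage::gblur(amb_co, sigma = sigma)), n, n), 0)
    ## blur spreads signal slightly beyond the drawn footprint
    ambiguous <- ambiguous | (amb_co > 2 & labels == 0L)
    amb_cross <- fpol_to_cross_intensity(amb_co, 0.15, spec$g_factor)
    sel <- labels == 0L
    co[sel] <- co[sel] + amb_co[sel]
    cross[sel] <- cross[sel] + amb_cross[sel]
  }

  if (spec$noise_sd > 0) {
    co <- co + rnorm(n * n, 0, spec$noise_sd)
    cross <- cross + rnorm(n * n, 0, spec$noise_sd)
  }
  if (spec$quantize) {
    co <- quantize_8bit(co)
    cross <- quantize_8bit(cross)
  } else {
    co <- pmin(pmax(co, 0), 255)
    cross <- pmin(pmax(cross, 0), 255)
  }

  high <- labels > 0L
  ambiguous <- ambiguous & !high
  masks <- tri_mask(background = !(high | ambiguous),
                    ambiguous = ambiguous, high_quality = high)
  truth_df <- if (nc > 0) do.call(rbind, lapply(truth, as.data.frame))
              else data.frame(cell_id = integer(0), fpol = numeric(0),
                              area_px = integer(0))
  if (nc > 0) {
    ## renumber cells into raster order so truth ids match the ids that
    ## connected-component labeling and quantification assign
    lr <- as_labeled_regions(labels)
    old_at_new <- vapply(seq_len(lr$n),
                         function(k) labels[which(lr$labels == k)[1]],
                         integer(1))
    labels <- lr$labels
    truth_df <- truth_df[old_at_new, ]
    truth_df$cell_id <- seq_len(nrow(truth_df))
    rownames(truth_df) <- NULL
  }
  structure(list(pair = polarized_pair(co, cross, spec$pixel_size),
                 masks = masks, labels = labels, truth = truth_df,
                 spec = spec),
            class = "phantom_sample")
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample> %d x %d px, %d high-quality cells, seed %d\n",
              nrow(x$pair$co), ncol(x$pair$co), nrow(x$truth), x$spec$seed))
  invisible(x)
}

#' Write a set of phantom samples to disk as an image fixture set
#'
#' Writes, per sample, the co and cross channels as 8-bit grayscale TIFF,
#' the ground-truth cell label mask as 16-bit TIFF, the three binary masks
#' as PNG, and a CSV manifest with columns `sample_id, class, co_path,
#' cross_path, mask_path, seed`.
#'
#' @param specs list of [phantom_spec()] objects (may be empty).
#' @param out_dir output directory (created if missing).
#' @param classes diagnosis class per sample (e.g. "malignant", "benign",
#'   "normal"); recycled.
#' @return The manifest data.frame, invisibly; also written to
#'   `file.path(out_dir, "manifest.csv")`.
#' @export
write_fixture_set <- function(specs, out_dir, classes = "unspecified") {
  if (inherits(specs, "phantom_spec")) specs <- list(specs)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  k <- length(specs)
  classes <- rep_len(classes, max(k, 1))
  rows <- vector("list", k)
  for (i in seq_len(k)) {
    sm <- generate_phantom(specs[[i]])
    id <- sprintf("sample_%03d", i)
    co_path <- file.path(out_dir, paste0(id, "_co.tif"))
    cross_path <- file.path(out_dir, paste0(id, "_cross.tif"))
    mask_path <- file.path(out_dir, paste0(id, "_labels.tif"))
    write_image_8bit(sm$pair$co, co_path)
    write_image_8bit(sm$pair$cross, cross_path)
    write_label_tiff(sm$labels, mask_path)
    for (m in c("background", "ambiguous", "high_quality"))
      write_mask_png(sm$masks[[m]], file.path(out_dir, paste0(id, "_", m, ".png")))
    write_cell_table(quantify_sample(sm$pair, sm$labels,
                                     g = specs[[i]]$g_factor),
                     file.path(out_dir, paste0(id, "_cells.csv")),
                     sample_id = id)
    rows[[i]] <- data.frame(sample_id = id, class = classes[i],
                            co_path = co_path, cross_path = cross_path,
                            mask_path = mask_path, seed = specs[[i]]$seed,
                            stringsAsFactors = FALSE)
  }
  manifest <- if (k > 0) do.call(rbind, rows) else
    data.frame(sample_id = character(0), class = character(0),
               co_path = character(0), cross_path = character(0),
               mask_path = character(0), seed = integer(0))
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
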