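## Per-cell fluorescence polarization (Fpol) and area quantification.
##
## Fpol = (I_co - G * I_cross) / (I_co + G * I_cross), where I_co and
## I_cross are the mean co- and cross-polarized intensities over the valid
## pixels of a cell and G is the instrument calibration factor (0.75 for
## the system this models). Saturated (> 254) and background (< 3) pixels
## are excluded from the means in both channels jointly.

#' Cross-channel intensity for a target Fpol
#'
#' Algebraic inversion of the Fpol formula: given a co-polarized
#' intensity, a target polarization and the calibration factor, returns
#' the cross-polarized intensity that yields exactly that Fpol,
#' `i_cross = i_co * (1 - fpol) / (g * (1 + fpol))`. Used by the phantom
#' generator to render image pairs with known ground truth.
#'
#' @param i_co co-polarized intensity (counts, >= 0); vectorized.
#' @param fpol target polarization in `(-1, 1]`.
#' @param g calibration factor (> 0).
#' @return Cross-polarized intensity in counts (pre-quantization).
#' @export
fpol_to_cross_intensity <- function(i_co, fpol, g = FPOL_G_DEFAULT) {
  if (!all(g > 0)) stop("calibration factor g must be positive")
  if (any(fpol <= -1 | fpol > 1))
    stop("fpol must lie in (-1, 1]; fpol = -1 implies division by zero")
  if (any(i_co < 0)) stop("i_co must be non-negative")
  i_co * (1 - fpol) / (g * (1 + fpol))
}

#' Fpol from mean channel intensities
#'
#' @param mean_co,mean_cross mean intensities (counts).
#' @param g calibration factor.
#' @return Fpol, dimensionless in `[-1, 1]` for non-negative intensities.
#' @export
fpol_from_means <- function(mean_co, mean_cross, g = FPOL_G_DEFAULT) {
  if (!all(g > 0)) stop("calibration factor g must be positive")
  (mean_co - g * mean_cross) / (mean_co + g * mean_cross)
}

#' Valid-pixel mask for Fpol computation
#'
#' A pixel is valid iff, in both channels, its value is at least 3 (above
#' background) and at most 254 (not saturated). Invalid pixels are dropped
#' from both channel means so the two means are always computed over the
#' identical pixel set.
#'
#' @param pair a [polarized_pair()].
#' @param low,high inclusive validity band (defaults 3 and 254).
#' @return Logical matrix.
#' @export
valid_pixel_mask <- function(pair, low = 3, high = 254) {
  stopifnot(inherits(pair, "polarized_pair"))
  pair$co >= low & pair$co <= high & pair$cross >= low & pair$cross <= high
}

#' Fpol and mean intensities of one cell region
#'
#' Means are arithmetic means over the valid pixels of the region; Fpol is
#' computed from the means (Fpol-of-means). The per-pixel alternative
#' (mean of per-pixel Fpol) is available for sensitivity analysis; the two
#' agree exactly on uniform-intensity regions.
#'
#' @param pixels integer vector of linear pixel indices (column-major, as
#'   from `which()`), or a logical matrix.
#' @param pair a [polarized_pair()].
#' @param g calibration factor.
#' @param min_valid_frac minimum fraction of region pixels that must be
#'   valid for the cell to keep quality flag "high" (default 0.5).
#' @param method "fpol_of_means" (default) or "mean_of_fpol".
#' @return List with `mean_co`, `mean_cross`, `fpol`, `n_valid`,
#'   `quality_flag` ("high" or "excluded"). Regions with no valid pixel or
#'   a zero denominator get `fpol = NA` and flag "excluded".
#' @export
cell_fpol <- function(pixels, pair, g = FPOL_G_DEFAULT,
                      min_valid_frac = 0.5,
                      method = c("fpol_of_means", "mean_of_fpol")) {
  stopifnot(inherits(pair, "polarized_pair"))
  method <- match.arg(method)
  if (is.matrix(pixels)) pixels <- which(pixels != 0)
  if (length(pixels) == 0) stop("cell region is empty")
  valid <- valid_pixel_mask(pair)
  vpix <- pixels[valid[pixels]]
  n_valid <- length(vpix)
  if (n_valid == 0) {
    return(list(mean_co = NA_real_, mean_cross = NA_real_, fpol = NA_real_,
                n_valid = 0L, quality_flag = "excluded"))
  }
  mean_co <- mean(pair$co[vpix])
  mean_cross <- mean(pair$cross[vpix])
  denom <- mean_co + g * mean_cross
  if (denom == 0) {
    return(list(mean_co = mean_co, mean_cross = mean_cross, fpol = NA_real_,
                n_valid = n_valid, quality_flag = "excluded"))
  }
  fpol <- if (method == "fpol_of_means") {
    fpol_from_means(mean_co, mean_cross, g)
  } else {
    mean(fpol_from_means(pair$co[vpix], pair$cross[vpix], g))
  }
  flag <- if (n_valid / length(pixels) >= min_valid_frac) "high" else "excluded"
  list(mean_co = mean_co, mean_cross = mean_cross, fpol = fpol,
       n_valid = n_valid, quality_flag = flag)
}

#' Cell area in square micrometres
#'
#' @param pixels pixel index vector, logical matrix, or a pixel count.
#' @param pixel_size micrometres per pixel.
#' @return Area in um^2: `n_pixels * pixel_size^2`.
#' @export
cell_area <- function(pixels, pixel_size = PIXEL_SIZE_DEFAULT) {
  n <- if (is.matrix(pixels)) sum(pixels != 0)
       else if (length(pixels) == 1 && is.numeric(pixels) && pixels == round(pixels) && pixels >= 0) pixels
       else length(pixels)
  if (n == 0) stop("cell region is empty")
  n * pixel_size^2
}

#' Quantify all labeled cells in one sample
#'
#' Computes, for every labeled region, the pixel area, physical area,
#' mean valid-pixel intensities in both channels, and Fpol. Regions whose
#' valid-pixel fraction falls below `min_valid_frac` (or with no valid
#' pixels at all) are retained with `quality_flag = "excluded"`.
#'
#' @param pair a [polarized_pair()].
#' @param labels a `labeled_regions` object or integer label matrix.
#' @param g calibration factor.
#' @param min_valid_frac see [cell_fpol()].
#' @param method see [cell_fpol()].
#' @return data.frame with one row per region, ordered by `cell_id`:
#'   columns `cell_id, area_px, area_um2, mean_co, mean_cross, fpol,
#'   n_valid, quality_flag`.
#' @export
quantify_sample <- function(pair, labels, g = FPOL_G_DEFAULT,
                            min_valid_frac = 0.5,
                            method = c("fpol_of_means", "mean_of_fpol")) {
  stopifnot(inherits(pair, "polarized_pair"))
  method <- match.arg(method)
  labels <- as_labeled_regions(labels)
  if (!identical(dim(labels$labels), dim(pair$co)))
    stop("label mask dimensions do not match the image pair")
  k <- labels$n
  empty <- data.frame(cell_id = integer(0), area_px = integer(0),
                      area_um2 = numeric(0), mean_co = numeric(0),
                      mean_cross = numeric(0), fpol = numeric(0),
                      n_valid = integer(0), quality_flag = character(0),
                      stringsAsFactors = FALSE)
  if (k == 0) return(empty)
  lab <- labels$labels
  valid <- valid_pixel_mask(pair)
  fg <- which(lab > 0)
  ids <- lab[fg]
  area_px <- tabulate(ids, nbins = k)
  v <- valid[fg]
  n_valid <- tabulate(ids[v], nbins = k)
  sum_co <- rowsum_safe(pair$co[fg][v], ids[v], k)
  sum_cross <- rowsum_safe(pair$cross[fg][v], ids[v], k)
  mean_co <- ifelse(n_valid > 0, sum_co / n_valid, NA_real_)
  mean_cross <- ifelse(n_valid > 0, sum_cross / n_valid, NA_real_)
  if (method == "fpol_of_means") {
    denom <- mean_co + g * mean_cross
    fpol <- ifelse(n_valid > 0 & denom != 0,
                   (mean_co - g * mean_cross) / denom, NA_real_)
  } else {
    pf <- fpol_from_means(pair$co[fg][v], pair$cross[fg][v], g)
    fpol <- ifelse(n_valid > 0, rowsum_safe(pf, ids[v], k) / n_valid, NA_real_)
  }
  flag <- ifelse(is.na(fpol) | n_valid / area_px < min_valid_frac,
                 "excluded", "high")
  data.frame(cell_id = seq_len(k), area_px = area_px,
             area_um2 = area_px * pair$pixel_size^2,
             mean_co = mean_co, mean_cross = mean_cross, fpol = fpol,
             n_valid = n_valid, quality_flag = flag,
             stringsAsFactors = FALSE)
}

## rowsum over group ids 1..k, returning zeros for absent groups.
rowsum_safe <- function(x, ids, k) {
  out <- numeric(k)
  if (length(x) > 0) {
    s <- rowsum(x, ids)
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}
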