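## Image and table I/O.
##
## Convention used throughout the package: images are numeric matrices
## indexed [row, col], row-major reading order, origin at the top-left.
## Intensities are 8-bit counts in [0, 255]; label masks are integer
## matrices with 0 = background and 1..k = regions.

#' Construct a validated co-/cross-polarized image pair
#'
#' @param co,cross numeric matrices of identical dimensions with values in
#'   `[0, 255]` (8-bit counts; fractional values are allowed for
#'   pre-quantization data such as frame averages or noiseless phantoms).
#' @param pixel_size pixel pitch in micrometres per pixel (> 0).
#' @return An object of class `polarized_pair`.
#' @export
polarized_pair <- function(co, cross, pixel_size = PIXEL_SIZE_DEFAULT) {
  co <- as.matrix(co); cross <- as.matrix(cross)
  if (!identical(dim(co), dim(cross)))
    stop("co and cross channels have different dimensions (",
         paste(dim(co), collapse = "x"), " vs ",
         paste(dim(cross), collapse = "x"), ")")
  if (!is.numeric(co) || !is.numeric(cross))
    stop("intensity grids must be numeric")
  rng <- range(co, cross)
  if (rng[1] < 0 || rng[2] > 255)
    stop("intensities outside [0, 255]: range ",
         paste(signif(rng, 4), collapse = " .. "))
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stop("pixel_size must be a single positive number")
  structure(list(co = co, cross = cross, pixel_size = pixel_size),
            class = "polarized_pair")
}

#' @export
print.polarized_pair <- function(x, ...) {
  cat(sprintf("<polarized_pair> %d x %d px, %.4g um/px, co [%g, %g], cross [%g, %g]\n",
              nrow(x$co), ncol(x$co), x$pixel_size,
              min(x$co), max(x$co), min(x$cross), max(x$cross)))
  invisible(x)
}

#' Construct the three-mask label scheme
#'
#' The labeling scheme used for supervised segmentation: `background`,
#' `ambiguous` (cell-like signal not selected by the expert, e.g. out of
#' focus), and `high_quality` (diagnostically relevant cells). A pixel in
#' the high-quality mask must never be in the background mask.
#'
#' @param background,ambiguous,high_quality logical matrices of identical
#'   dimensions.
#' @return An object of class `tri_mask`.
#' @export
tri_mask <- function(background, ambiguous, high_quality) {
  background <- background != 0
  ambiguous <- ambiguous != 0
  high_quality <- high_quality != 0
  if (!identical(dim(background), dim(ambiguous)) ||
      !identical(dim(background), dim(high_quality)))
    stop("the three masks must share dimensions")
  if (any(background & high_quality))
    stop("a pixel cannot be both background and high-quality")
  structure(list(background = background, ambiguous = ambiguous,
                 high_quality = high_quality),
            class = "tri_mask")
}

#' Collapse a tri_mask into a single label grid
#'
#' @param masks a [tri_mask()].
#' @return Integer matrix: 0 = background, 1 = ambiguous, 2 = high-quality.
#'   High-quality takes precedence over ambiguous.
#' @export
tri_mask_to_labels <- function(masks) {
  stopifnot(inherits(masks, "tri_mask"))
  lab <- matrix(0L, nrow(masks$background), ncol(masks$background))
  lab[masks$ambiguous] <- 1L
  lab[masks$high_quality] <- 2L
  lab
}

#' Expand a class-label grid into a tri_mask
#'
#' @param labels integer matrix with values 0 (background), 1 (ambiguous),
#'   2 (high-quality).
#' @return A [tri_mask()].
#' @export
labels_to_tri_mask <- function(labels) {
  tri_mask(labels == 0L, labels == 1L, labels == 2L)
}

img_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) return("tiff")
  if (ext == "png") return("png")
  stop("unsupported image format '", ext, "' for ", path,
       " (use TIFF or PNG)")
}

#' Read a single-channel 8-bit grayscale image
#'
#' @param path TIFF or PNG file.
#' @return Integer matrix of counts in `[0, 255]`, indexed `[row, col]`.
#' @export
read_image_8bit <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- img_format(path)
  if (fmt == "tiff") {
    img <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    bits <- attr(img, "bits.per.sample")
    if (!is.null(bits) && bits != 8)
      stop("expected 8-bit image, got ", bits, "-bit: ", path)
  } else {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    if (!is.null(info$bit.depth) && info$bit.depth != 8)
      stop("expected 8-bit image, got ", info$bit.depth, "-bit: ", path)
    img <- round(img * 255)
  }
  if (length(dim(img)) == 3) {
    if (dim(img)[3] == 1) img <- img[, , 1]
    else stop("expected single-channel grayscale image, got ",
              dim(img)[3], " channels: ", path)
  }
  storage.mode(img) <- "integer"
  img
}

#' Write a single-channel 8-bit grayscale image
#'
#' Values are quantized with [quantize_8bit()] before writing.
#'
#' @param img numeric matrix in `[0, 255]`.
#' @param path destination TIFF or PNG path.
#' @return `path`, invisibly.
#' @export
write_image_8bit <- function(img, path) {
  fmt <- img_format(path)
  img <- quantize_8bit(img)
  ok <- tryCatch({
    if (fmt == "tiff") tiff::writeTIFF(img / 255, path, bits.per.sample = 8)
    else png::writePNG(img / 255, path)
    TRUE
  }, error = function(e) {
    stop("failed to write image ", path, ": ", conditionMessage(e))
  })
  invisible(path)
}

#' Read a co-/cross-polarized image pair from disk
#'
#' Both files must decode to single-channel 8-bit grids of identical
#' dimensions.
#'
#' @param co_path,cross_path image file paths (TIFF or PNG).
#' @param pixel_size pixel pitch in micrometres per pixel.
#' @return A [polarized_pair()].
#' @export
read_pair <- function(co_path, cross_path, pixel_size = PIXEL_SIZE_DEFAULT) {
  co <- read_image_8bit(co_path)
  cross <- read_image_8bit(cross_path)
  if (!identical(dim(co), dim(cross)))
    stop("dimension mismatch between channels: ", co_path, " is ",
         paste(dim(co), collapse = "x"), " but ", cross_path, " is ",
         paste(dim(cross), collapse = "x"))
  polarized_pair(co, cross, pixel_size)
}

#' Average a stack of frames
#'
#' Pixel-wise arithmetic mean of repeated acquisitions, kept at floating
#' precision (quantization happens only at write time).
#'
#' @param frames list of numeric matrices with identical dimensions.
#' @return Numeric matrix of the same dimensions.
#' @export
average_frames <- function(frames) {
  if (!is.list(frames) || length(frames) == 0)
    stop("average_frames requires at least one frame")
  d <- dim(frames[[1]])
  for (f in frames)
    if (!identical(dim(f), d)) stop("frames have differing dimensions")
  Reduce(`+`, frames) / length(frames)
}

#' Quantize intensities to 8-bit counts
#'
#' Round half up to the nearest integer, then clip to `[0, 255]`.
#'
#' @param x numeric matrix or vector.
#' @return Same shape, integer-valued.
#' @export
quantize_8bit <- function(x) {
  pmin(pmax(floor(x + 0.5), 0), 255)
}

#' Write / read a binary mask as PNG (0/255)
#'
#' @param mask logical (or 0/1) matrix.
#' @param path PNG path.
#' @return `path` invisibly; `read_mask_png` returns a logical matrix.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG((mask != 0) * 1, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img >= 0.5
}

#' Write / read a label mask as 16-bit TIFF
#'
#' Region ids 0..k are stored as 16-bit gray levels, so up to 65535
#' regions per image are representable.
#'
#' @param labels integer matrix, 0 = background, 1..k = regions.
#' @param path TIFF path.
#' @return `path` invisibly; `read_label_tiff` returns an integer matrix.
#' @export
write_label_tiff <- function(labels, path) {
  labels <- as.matrix(labels)
  if (max(labels) > 65535) stop("more than 65535 labels cannot be stored")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_label_tiff
#' @export
read_label_tiff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3) img <- img[, , 1]
  storage.mode(img) <- "integer"
  img
}

#' Write a per-cell result table to CSV
#'
#' One row per cell with columns `sample_id, cell_id, area_px, area_um2,
#' mean_co, mean_cross, fpol, quality_flag`. An empty cell list yields a
#' header-only table.
#'
#' @param cells data.frame as produced by [quantify_sample()].
#' @param path destination CSV path.
#' @param sample_id identifier written into the `sample_id` column
#'   (ignored if `cells` already has one).
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path, sample_id = NA_character_) {
  cols <- c("sample_id", "cell_id", "area_px", "area_um2",
            "mean_co", "mean_cross", "fpol", "quality_flag")
  if (is.null(cells) || nrow(cells) == 0) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  } else {
    if (is.null(cells$sample_id)) cells$sample_id <- sample_id
    out <- cells[, cols]
  }
  tryCatch(write.csv(out, path, row.names = FALSE),
           error = function(e) stop("failed to write cell table ", path,
                                    ": ", conditionMessage(e)))
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.csv(path, stringsAsFactors = FALSE)
}
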