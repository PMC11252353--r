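## Morphological post-processing of segmentation probability maps.
##
## The chain applied to the high-quality class probability map is:
## threshold at 0.5, dilation (3x3 square, 3 iterations), erosion (same
## kernel and iterations), then a morphological opening with a 15x15
## elliptical structuring element, and finally connected component
## labeling. Pixels outside the image are treated as background for all
## operators.

#' Structuring elements
#'
#' `kernel_square(n)` is an n x n all-ones element; `kernel_ellipse(n)` is
#' the discrete filled ellipse with semi-axes `(n-1)/2` (for the default
#' 15 x 15 this is a disc of radius 7).
#'
#' @param n odd kernel side length.
#' @return Logical matrix with the origin at the central pixel.
#' @export
kernel_square <- function(n = 3) {
  stopifnot(n >= 1, n %% 2 == 1)
  matrix(TRUE, n, n)
}

#' @rdname kernel_square
#' @export
kernel_ellipse <- function(n = 15) {
  stopifnot(n >= 1, n %% 2 == 1)
  r <- (n - 1) / 2
  d <- seq(-r, r)
  outer(d, d, function(dy, dx) (dy / r)^2 + (dx / r)^2 <= 1)
}

kernel_offsets <- function(kernel) {
  stopifnot(is.matrix(kernel), nrow(kernel) %% 2 == 1, ncol(kernel) %% 2 == 1)
  idx <- which(kernel != 0, arr.ind = TRUE)
  cbind(di = idx[, 1] - (nrow(kernel) + 1) %/% 2,
        dj = idx[, 2] - (ncol(kernel) + 1) %/% 2)
}

## Shift a logical matrix by (di, dj); vacated positions filled with `fill`.
shift_mask <- function(m, di, dj, fill = FALSE) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(fill, n, p)
  ri <- max(1, 1 + di):min(n, n + di)
  ci <- max(1, 1 + dj):min(p, p + dj)
  if (length(ri) > 0 && length(ci) > 0)
    out[ri, ci] <- m[ri - di, ci - dj, drop = FALSE]
  out
}

check_binary <- function(mask) {
  if (is.logical(mask)) return(mask)
  u <- unique(as.vector(mask))
  if (!all(u %in% c(0, 1)))
    stop("mask is not binary (values other than 0/1 present)")
  mask != 0
}

#' Binary dilation / erosion / opening
#'
#' Set-theoretic morphology on binary masks. Dilation is the union of
#' kernel translates of the foreground; erosion is its dual: a pixel stays
#' foreground only if every kernel offset lands on foreground (offsets
#' falling outside the image count as background, so regions touching the
#' border erode there too). Opening is erosion followed by dilation.
#'
#' @param mask logical (or 0/1) matrix.
#' @param kernel logical structuring element with odd dimensions, origin
#'   at the center.
#' @param iterations number of repeated applications.
#' @return Logical matrix.
#' @export
mask_dilate <- function(mask, kernel = kernel_square(3), iterations = 1) {
  mask <- check_binary(mask)
  off <- kernel_offsets(kernel)
  for (it in seq_len(iterations)) {
    out <- matrix(FALSE, nrow(mask), ncol(mask))
    for (k in seq_len(nrow(off)))
      out <- out | shift_mask(mask, off[k, 1], off[k, 2])
    mask <- out
  }
  mask
}

#' @rdname mask_dilate
#' @export
mask_erode <- function(mask, kernel = kernel_square(3), iterations = 1) {
  mask <- check_binary(mask)
  off <- kernel_offsets(kernel)
  for (it in seq_len(iterations)) {
    out <- matrix(TRUE, nrow(mask), ncol(mask))
    for (k in seq_len(nrow(off)))
      out <- out & shift_mask(mask, -off[k, 1], -off[k, 2])
    mask <- out
  }
  mask
}

#' @rdname mask_dilate
#' @export
mask_open <- function(mask, kernel = kernel_ellipse(15)) {
  mask_dilate(mask_erode(mask, kernel), kernel)
}

#' Threshold a probability map to a binary mask
#'
#' A pixel is foreground iff its probability is greater than or equal to
#' the threshold (ties at exactly the threshold are foreground).
#'
#' @param prob numeric matrix with values in `[0, 1]`.
#' @param threshold scalar in `[0, 1]`, default 0.5.
#' @return Logical matrix.
#' @export
binarize <- function(prob, threshold = 0.5) {
  if (!is.numeric(prob)) stop("probability grid must be numeric")
  if (any(prob < 0 | prob > 1))
    stop("probabilities outside [0, 1]")
  prob >= threshold
}

#' Morphological refinement of a binary segmentation mask
#'
#' Applies, in order: dilation (3 x 3 square kernel, 3 iterations),
#' erosion (same kernel and iterations, reverting dilated areas to their
#' initial boundaries while keeping small gaps closed), and a
#' morphological opening with a 15 x 15 elliptical structuring element
#' that removes spurious pixel clusters too small to contain the element.
#'
#' @param mask logical (or 0/1) matrix.
#' @param dilate_kernel,dilate_iter,erode_kernel,erode_iter,open_kernel
#'   the operator chain parameters; defaults implement the standard chain.
#' @return Logical matrix.
#' @export
refine_mask <- function(mask,
                        dilate_kernel = kernel_square(3), dilate_iter = 3,
                        erode_kernel = kernel_square(3), erode_iter = 3,
                        open_kernel = kernel_ellipse(15)) {
  mask <- check_binary(mask)
  mask <- mask_dilate(mask, dilate_kernel, dilate_iter)
  mask <- mask_erode(mask, erode_kernel, erode_iter)
  mask_open(mask, open_kernel)
}

#' Connected component labeling
#'
#' Deterministic labeling of maximal connected foreground regions. Labels
#' are assigned 1..k in raster-scan order (row by row, left to right) of
#' each region's first pixel.
#'
#' @param mask logical (or 0/1) matrix.
#' @param connectivity 8 (default; diagonal neighbors connect) or 4.
#' @return An object of class `labeled_regions`: list with `labels`
#'   (integer matrix), `sizes` (pixel count per region) and `n` (number of
#'   regions).
#' @export
label_components <- function(mask, connectivity = 8) {
  mask <- check_binary(mask)
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  lab <- EBImage::bwlabel(mask * 1)          # 4-connected base labeling
  storage.mode(lab) <- "integer"
  nlab <- max(lab)
  if (nlab > 0 && connectivity == 8) {
    ## merge labels that touch diagonally: union-find over label ids
    parent <- seq_len(nlab)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    union2 <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
    n <- nrow(lab); p <- ncol(lab)
    if (n > 1 && p > 1) {
      a1 <- lab[-n, -p]; b1 <- lab[-1, -1]    # down-right diagonal
      a2 <- lab[-1, -p]; b2 <- lab[-n, -1]    # up-right diagonal
      sel1 <- which(a1 > 0 & b1 > 0 & a1 != b1)
      sel2 <- which(a2 > 0 & b2 > 0 & a2 != b2)
      prs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
      if (length(prs)) for (r in seq_len(nrow(prs))) union2(prs[r, 1], prs[r, 2])
    }
    roots <- vapply(seq_len(nlab), find, integer(1))
    lab[lab > 0] <- roots[lab[lab > 0]]
  }
  relabel_raster(lab)
}

## Renumber labels 1..k by raster (row-major) order of first pixel.
relabel_raster <- function(lab) {
  n <- nrow(lab); p <- ncol(lab)
  fg <- which(lab > 0)
  if (length(fg) == 0) {
    return(structure(list(labels = matrix(0L, n, p), sizes = integer(0), n = 0L),
                     class = "labeled_regions"))
  }
  ## raster key: row-major position of each pixel
  rows <- (fg - 1L) %% n + 1L
  cols <- (fg - 1L) %/% n + 1L
  raster <- (rows - 1L) * p + cols
  ids <- lab[fg]
  first <- tapply(raster, ids, min)
  ord <- order(first)                       # old ids sorted by first pixel
  newid <- integer(max(ids))
  newid[as.integer(names(first))[ord]] <- seq_along(ord)
  out <- matrix(0L, n, p)
  out[fg] <- newid[ids]
  sizes <- tabulate(out[fg], nbins = length(ord))
  structure(list(labels = out, sizes = sizes, n = length(ord)),
            class = "labeled_regions")
}

#' Coerce an integer label matrix to labeled_regions
#'
#' Renumbers labels into raster order and recomputes region sizes. Regions
#' need not be connected (e.g. hand-drawn masks); connectivity is not
#' enforced here.
#'
#' @param labels integer matrix, 0 = background.
#' @return A `labeled_regions` object.
#' @export
as_labeled_regions <- function(labels) {
  if (inherits(labels, "labeled_regions")) return(labels)
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  relabel_raster(labels)
}

#' @export
print.labeled_regions <- function(x, ...) {
  cat(sprintf("<labeled_regions> %d x %d px, %d regions, %d foreground px\n",
              nrow(x$labels), ncol(x$labels), x$n, sum(x$sizes)))
  invisible(x)
}

#' Full post-processing of a probability map
#'
#' Thresholds the high-quality class probability map, refines the binary
#' mask morphologically, and labels connected components.
#'
#' @param prob probability matrix for the high-quality class.
#' @param threshold binarization threshold (default 0.5).
#' @param connectivity component connectivity (default 8).
#' @param ... passed to [refine_mask()].
#' @return A `labeled_regions` object.
#' @export
postprocess_probability <- function(prob, threshold = 0.5, connectivity = 8, ...) {
  label_components(refine_mask(binarize(prob, threshold), ...),
                   connectivity = connectivity)
}
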