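## Automated-vs-manual (AU vs MA) segmentation agreement.
##
## Cells delineated by both methods are "matched"; cells found by only
## one method are "unmatched". Per matched pair, the symmetric percent
## difference 100 * (a - b) / ((a + b) / 2) is reported for Fpol and
## area, with AU as the first argument.

#' Symmetric percent difference
#'
#' `100 * (a - b) / ((a + b) / 2)`. Antisymmetric in its arguments and
#' invariant under common rescaling.
#'
#' @param a,b scalars (or equal-length vectors) with `a + b != 0`.
#' @param digits if non-NULL, round to this many decimals
#'   (half-away-from-zero, matching reported precision).
#' @return Percent difference.
#' @export
pct_diff <- function(a, b, digits = NULL) {
  if (any(a + b == 0))
    stop("percent difference undefined when a + b = 0")
  out <- 100 * (a - b) / ((a + b) / 2)
  if (!is.null(digits)) out <- round_half_out(out, digits)
  out
}

#' Round half away from zero
#'
#' Reporting convention for printed percentages: ties at 5 in the first
#' dropped digit round away from zero (so 1.45 -> 1.5 and -1.45 -> -1.5),
#' unlike base R's round-half-even.
#'
#' @param x numeric.
#' @param digits decimals to keep.
#' @return Rounded numeric.
#' @export
round_half_out <- function(x, digits = 1) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Cell-count selection excess of the automated method
#'
#' Percent by which the automated method selected more cells than the
#' manual one: `100 * (n_au_total - n_ma_total) / n_ma_total`, where each
#' total is matched + method-only cells.
#'
#' @param n_matched cells found by both methods.
#' @param n_au_only,n_ma_only unmatched cells per method.
#' @param digits decimals for the reported value (default 1).
#' @return Percent excess (positive when AU selects more cells).
#' @export
selection_excess <- function(n_matched, n_au_only, n_ma_only, digits = 1) {
  n_ma <- n_matched + n_ma_only
  if (n_ma <= 0) stop("no manually selected cells: excess undefined")
  n_au <- n_matched + n_au_only
  round_half_out(100 * (n_au - n_ma) / n_ma, digits)
}

#' Match automated and manual cell segmentations
#'
#' Greedy one-to-one pairing of AU and MA regions by descending pixel
#' overlap. A pair is accepted only if the overlap exceeds
#' `overlap_frac` of the smaller region's area (default 0.5). Ties are
#' broken deterministically by smaller AU id, then smaller MA id.
#'
#' @param au,ma `labeled_regions` (or integer label matrices) on the same
#'   image geometry.
#' @param overlap_frac minimum overlap as a fraction of the smaller
#'   region's area, exclusive (default 0.5).
#' @return An object of class `match_result`: list with `matched`
#'   (data.frame au_id, ma_id, overlap_px), `au_only`, `ma_only`, and the
#'   region counts `n_au`, `n_ma`.
#' @export
match_cells <- function(au, ma, overlap_frac = 0.5) {
  au <- as_labeled_regions(au); ma <- as_labeled_regions(ma)
  if (!identical(dim(au$labels), dim(ma$labels)))
    stop("AU and MA label masks have different geometry")
  both <- au$labels > 0L & ma$labels > 0L
  cand <- if (any(both)) {
    df <- data.frame(au_id = au$labels[both], ma_id = ma$labels[both])
    agg <- as.data.frame(table(df$au_id, df$ma_id), stringsAsFactors = FALSE)
    names(agg) <- c("au_id", "ma_id", "overlap_px")
    agg$au_id <- as.integer(agg$au_id); agg$ma_id <- as.integer(agg$ma_id)
    agg <- agg[agg$overlap_px > 0, ]
    smaller <- pmin(au$sizes[agg$au_id], ma$sizes[agg$ma_id])
    agg <- agg[agg$overlap_px > overlap_frac * smaller, ]
    agg[order(-agg$overlap_px, agg$au_id, agg$ma_id), ]
  } else data.frame(au_id = integer(0), ma_id = integer(0),
                    overlap_px = integer(0))
  used_au <- logical(au$n); used_ma <- logical(ma$n)
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    if (!used_au[cand$au_id[r]] && !used_ma[cand$ma_id[r]]) {
      keep[r] <- TRUE
      used_au[cand$au_id[r]] <- TRUE
      used_ma[cand$ma_id[r]] <- TRUE
    }
  }
  matched <- cand[keep, , drop = FALSE]
  matched <- matched[order(matched$au_id), , drop = FALSE]
  rownames(matched) <- NULL
  structure(list(matched = matched,
                 au_only = setdiff(seq_len(au$n), matched$au_id),
                 ma_only = setdiff(seq_len(ma$n), matched$ma_id),
                 n_au = au$n, n_ma = ma$n),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d matched, %d AU-only, %d MA-only (AU %d, MA %d)\n",
              nrow(x$matched), length(x$au_only), length(x$ma_only),
              x$n_au, x$n_ma))
  invisible(x)
}

#' Compare automated and manual per-cell quantifications
#'
#' Attaches per-matched-pair percent differences in Fpol and area (AU
#' minus MA in the numerator) to a pairing, and summarizes each method
#' over all its cells (matched and unmatched).
#'
#' @param au_cells,ma_cells per-cell data.frames from [quantify_sample()].
#' @param pairing a [match_cells()] result whose ids reference the cell
#'   tables.
#' @param digits decimals for reported percent differences (default 1).
#' @return An object of class `compare_result`: list with `matched`
#'   (data.frame au_id, ma_id, overlap_px, delta_fpol_pct,
#'   delta_area_pct), `au_only`, `ma_only`, `summary` (per-method n,
#'   mean, SD of Fpol over all cells), and `selection_excess_pct`.
#' @export
compare_sample <- function(au_cells, ma_cells, pairing, digits = 1) {
  stopifnot(inherits(pairing, "match_result"))
  m <- pairing$matched
  if (nrow(m) > 0) {
    iau <- match(m$au_id, au_cells$cell_id)
    ima <- match(m$ma_id, ma_cells$cell_id)
    if (anyNA(iau) || anyNA(ima))
      stop("pairing references cell ids missing from the cell tables")
    m$delta_fpol_pct <- pct_diff(au_cells$fpol[iau], ma_cells$fpol[ima],
                                 digits = digits)
    m$delta_area_pct <- pct_diff(au_cells$area_um2[iau], ma_cells$area_um2[ima],
                                 digits = digits)
  } else {
    m$delta_fpol_pct <- numeric(0)
    m$delta_area_pct <- numeric(0)
  }
  summ <- data.frame(
    method = c("AU", "MA"),
    n = c(nrow(au_cells), nrow(ma_cells)),
    mean_fpol = c(mean(au_cells$fpol, na.rm = TRUE),
                  mean(ma_cells$fpol, na.rm = TRUE)),
    sd_fpol = c(sd_or_zero(au_cells$fpol), sd_or_zero(ma_cells$fpol)),
    stringsAsFactors = FALSE)
  excess <- if (nrow(ma_cells) > 0)
    selection_excess(nrow(m), length(pairing$au_only), length(pairing$ma_only))
  else NA_real_
  structure(list(matched = m, au_only = pairing$au_only,
                 ma_only = pairing$ma_only, summary = summ,
                 selection_excess_pct = excess),
            class = "compare_result")
}

sd_or_zero <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) 0 else sd(x)
}

#' @export
print.compare_result <- function(x, ...) {
  cat(sprintf("<compare_result> %d matched pairs, %d AU-only, %d MA-only\n",
              nrow(x$matched), length(x$au_only), length(x$ma_only)))
  print(x$summary)
  invisible(x)
}
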