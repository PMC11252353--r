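## Grouped significance testing of per-cell Fpol values.
##
## Cells are grouped by diagnosis class (malignant / benign / normal) and
## processing method (AU / MA). Two-tailed Student's t-tests compare
## groups: paired where a one-to-one cell correspondence exists (AU vs MA
## on matched cells), unpaired (pooled variance) between disjoint cell
## sets (malignant vs benign, malignant vs normal). Significance is
## Bonferroni-corrected at alpha = 0.01.

#' Per-group Fpol summaries
#'
#' @param cells data.frame with columns `method` (AU/MA), `diagnosis`
#'   (malignant/benign/normal) and `fpol`. NA Fpol values are dropped.
#' @return data.frame with one row per (method, diagnosis) group present:
#'   `method, diagnosis, n, mean_fpol, sd_fpol` (sample SD, n-1
#'   denominator). A single-cell group reports SD 0 with a warning.
#' @export
summarize_groups <- function(cells) {
  need <- c("method", "diagnosis", "fpol")
  if (!all(need %in% names(cells)))
    stop("cells must have columns: ", paste(need, collapse = ", "))
  cells <- cells[!is.na(cells$fpol), ]
  if (nrow(cells) == 0) {
    warning("no cells with Fpol values; empty summary")
    return(data.frame(method = character(0), diagnosis = character(0),
                      n = integer(0), mean_fpol = numeric(0),
                      sd_fpol = numeric(0), stringsAsFactors = FALSE))
  }
  key <- interaction(cells$method, cells$diagnosis, drop = TRUE)
  out <- do.call(rbind, lapply(split(cells, key), function(g) {
    if (nrow(g) == 1)
      warning("group ", g$method[1], "/", g$diagnosis[1],
              " has a single cell; SD reported as 0")
    data.frame(method = g$method[1], diagnosis = g$diagnosis[1],
               n = nrow(g), mean_fpol = mean(g$fpol),
               sd_fpol = if (nrow(g) > 1) sd(g$fpol) else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$method, out$diagnosis), ]
}

#' Two-tailed Student's t-test between Fpol groups
#'
#' Classical Student t statistic with a two-tailed p-value. Unpaired mode
#' uses the pooled-variance two-sample test; paired mode requires two
#' equal-length matched sequences and tests their differences against
#' zero.
#'
#' @param x,y numeric vectors of Fpol values.
#' @param mode "unpaired" (default) or "paired".
#' @param label optional comparison label carried into the report.
#' @return An object of class `fpol_test`: list with `label`, `mode`,
#'   `t`, `df`, `p`, `n`.
#' @export
fpol_ttest <- function(x, y, mode = c("unpaired", "paired"), label = NULL) {
  mode <- match.arg(mode)
  x <- x[!is.na(x)]; y0 <- y
  if (mode == "paired") {
    if (length(x) != length(y0))
      stop("paired mode requires equal-length matched sequences")
    ok <- !is.na(x) & !is.na(y0)
    x <- x[ok]; y <- y0[ok]
    if (length(x) < 2) stop("paired test requires at least 2 pairs")
    d <- x - y
    if (sd(d) == 0) {
      warning("zero variance of paired differences; degenerate test")
      res <- list(statistic = c(t = if (mean(d) == 0) 0 else Inf * sign(mean(d))),
                  parameter = c(df = length(d) - 1),
                  p.value = if (mean(d) == 0) 1 else 0)
    } else res <- t.test(x, y, paired = TRUE)
    n <- length(x)
  } else {
    y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2)
      stop("unpaired test requires at least 2 values per group")
    res <- t.test(x, y, var.equal = TRUE)
    n <- c(length(x), length(y))
  }
  structure(list(label = label %||% paste0(mode, " t-test"), mode = mode,
                 t = unname(res$statistic), df = unname(res$parameter),
                 p = res$p.value, n = n),
            class = "fpol_test")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fpol_test <- function(x, ...) {
  cat(sprintf("<fpol_test> %s (%s): t = %.4g, df = %.4g, p = %.4g\n",
              x$label, x$mode, x$t, x$df, x$p))
  invisible(x)
}

#' Bonferroni-corrected significance flags
#'
#' Test i is significant iff `p_i < alpha / m`, where `m` is the family
#' size (by default the number of p-values supplied).
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @param alpha family-wise significance level (default 0.01).
#' @param m family size; defaults to `length(p_values)`.
#' @return Logical vector of significance flags.
#' @export
bonferroni <- function(p_values, alpha = 0.01, m = length(p_values)) {
  if (length(p_values) == 0) stop("empty p-value list")
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  p_values < alpha / m
}

#' Run the grouped analysis on a combined cell table
#'
#' Builds the standard comparison family on a combined AU+MA per-cell
#' table: unpaired malignant-vs-benign and malignant-vs-normal within
#' each method, and paired AU-vs-MA per diagnosis on matched cells (rows
#' sharing a `pair_id`). Applies the Bonferroni correction over the whole
#' family.
#'
#' @param cells data.frame with columns `method`, `diagnosis`, `fpol` and
#'   optionally `pair_id` (non-NA for matched cells).
#' @param alpha family-wise level (default 0.01).
#' @return List with `groups` (from [summarize_groups()]) and `tests`
#'   (data.frame label, mode, t, p, m, significant).
#' @export
run_group_stats <- function(cells, alpha = 0.01) {
  groups <- summarize_groups(cells)
  tests <- list()
  gv <- function(method, diagnosis)
    cells$fpol[cells$method == method & cells$diagnosis == diagnosis &
                 !is.na(cells$fpol)]
  for (meth in intersect(c("AU", "MA"), unique(cells$method))) {
    for (cmp in list(c("malignant", "benign"), c("malignant", "normal"))) {
      a <- gv(meth, cmp[1]); b <- gv(meth, cmp[2])
      if (length(a) >= 2 && length(b) >= 2)
        tests[[length(tests) + 1]] <-
          fpol_ttest(a, b, "unpaired",
                     label = paste0(cmp[1], " vs ", cmp[2], " (", meth, ")"))
    }
  }
  if (!is.null(cells$pair_id)) {
    mt <- cells[!is.na(cells$pair_id), ]
    for (dg in unique(mt$diagnosis)) {
      au <- mt[mt$method == "AU" & mt$diagnosis == dg, ]
      ma <- mt[mt$method == "MA" & mt$diagnosis == dg, ]
      shared <- intersect(au$pair_id, ma$pair_id)
      if (length(shared) >= 2)
        tests[[length(tests) + 1]] <-
          fpol_ttest(au$fpol[match(shared, au$pair_id)],
                     ma$fpol[match(shared, ma$pair_id)], "paired",
                     label = paste0("AU vs MA (", dg, ", matched cells)"))
    }
  }
  if (length(tests) == 0) {
    return(list(groups = groups,
                tests = data.frame(label = character(0), mode = character(0),
                                   t = numeric(0), p = numeric(0),
                                   m = integer(0), significant = logical(0))))
  }
  p <- vapply(tests, function(t) t$p, numeric(1))
  flags <- bonferroni(p, alpha = alpha)
  list(groups = groups,
       tests = data.frame(label = vapply(tests, `[[`, "", "label"),
                          mode = vapply(tests, `[[`, "", "mode"),
                          t = vapply(tests, function(t) t$t, numeric(1)),
                          p = p, m = length(p), significant = flags,
                          stringsAsFactors = FALSE))
}
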