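## End-to-end pipeline orchestration.
##
## For each sample in a manifest: read the image pair, predict class
## probabilities, post-process the high-quality map into labeled cells,
## quantify per-cell Fpol/area, and (when a manual/ground-truth label
## mask is available) match cells and compute agreement metrics. Finally
## pool all cells into the grouped statistical analysis.

#' Pipeline run configuration
#'
#' @param manifest path to a CSV manifest with columns `sample_id, class,
#'   co_path, cross_path` and optionally `mask_path` (manual/ground-truth
#'   label mask enabling the comparison stage).
#' @param model path to a model checkpoint ([save_unet()]), or a `unet`
#'   object.
#' @param out_dir output directory for per-sample tables and the combined
#'   report.
#' @param g_factor calibration factor.
#' @param pixel_size micrometres per pixel.
#' @param threshold binarization threshold for the high-quality map.
#' @param connectivity component connectivity (8 or 4).
#' @param match_overlap minimum overlap fraction for cell matching.
#' @param alpha family-wise significance level.
#' @param seed seed recorded in the run log (the inference pipeline
#'   itself is deterministic).
#' @return An object of class `run_config`.
#' @export
run_config <- function(manifest, model, out_dir = ".",
                       g_factor = FPOL_G_DEFAULT,
                       pixel_size = PIXEL_SIZE_DEFAULT,
                       threshold = 0.5, connectivity = 8,
                       match_overlap = 0.5, alpha = 0.01, seed = 1) {
  stopifnot(threshold >= 0, threshold <= 1, connectivity %in% c(4, 8),
            match_overlap >= 0, match_overlap < 1, alpha > 0, alpha < 1)
  structure(list(manifest = manifest, model = model, out_dir = out_dir,
                 g_factor = g_factor, pixel_size = pixel_size,
                 threshold = threshold, connectivity = connectivity,
                 match_overlap = match_overlap, alpha = alpha,
                 seed = as.integer(seed)),
            class = "run_config")
}

## one pooled-table row per cell; safe for samples with zero cells
pooled_rows <- function(id, method, class, fpol) {
  n <- length(fpol)
  data.frame(sample_id = rep(id, n), method = rep(method, n),
             diagnosis = rep(class, n), fpol = fpol,
             pair_id = rep(NA_character_, n), stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline over a sample manifest
#'
#' Per-sample stages: prediction, morphological post-processing,
#' connected-component labeling, per-cell quantification, and (if the
#' manifest provides a manual label mask) AU-vs-MA matching and percent
#' differences. Samples with missing inputs are skipped with a logged
#' reason. All cells are pooled into group summaries and the Bonferroni
#' corrected t-test family.
#'
#' @param cfg a [run_config()].
#' @param verbose log one line per stage per sample.
#' @return List with `samples` (per-sample results), `cells` (combined
#'   per-cell table), `stats` (from [run_group_stats()]), `log`
#'   (character vector), and `skipped`.
#' @export
run_pipeline <- function(cfg, verbose = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  net <- if (inherits(cfg$model, "unet")) cfg$model else load_unet(cfg$model)
  if (!file.exists(cfg$manifest)) stop("manifest not found: ", cfg$manifest)
  manifest <- read.csv(cfg$manifest, stringsAsFactors = FALSE)
  if (nrow(manifest) == 0) stop("empty manifest: ", cfg$manifest)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  logs <- character(0)
  logline <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    logs <<- c(logs, line)
    if (verbose) message(line)
  }
  logline("run: %d samples, g=%.3g, pixel_size=%.4g um/px, threshold=%.2g, connectivity=%d, seed=%d",
          nrow(manifest), cfg$g_factor, cfg$pixel_size, cfg$threshold,
          cfg$connectivity, cfg$seed)

  results <- list(); skipped <- character(0)
  all_cells <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    id <- as.character(row$sample_id)
    if (!file.exists(row$co_path) || !file.exists(row$cross_path)) {
      logline("%s: SKIP (missing image file)", id)
      skipped <- c(skipped, id)
      next
    }
    t0 <- proc.time()[3]
    pair <- read_pair(row$co_path, row$cross_path, cfg$pixel_size)
    probs <- predict_pair(net, pair)
    logline("%s: predicted %dx%d probability maps", id, nrow(pair$co), ncol(pair$co))
    labels <- postprocess_probability(probs$high_quality,
                                      threshold = cfg$threshold,
                                      connectivity = cfg$connectivity)
    logline("%s: post-processing -> %d regions", id, labels$n)
    au_cells <- quantify_sample(pair, labels, g = cfg$g_factor)
    write_cell_table(au_cells,
                     file.path(cfg$out_dir, paste0(id, "_au_cells.csv")),
                     sample_id = id)
    res <- list(sample_id = id, class = row$class, labels = labels,
                au_cells = au_cells)
    has_ma <- !is.null(row$mask_path) && !is.na(row$mask_path) &&
      nzchar(row$mask_path) && file.exists(row$mask_path)
    if (has_ma) {
      ma_labels <- as_labeled_regions(read_label_tiff(row$mask_path))
      ma_cells <- quantify_sample(pair, ma_labels, g = cfg$g_factor)
      pairing <- match_cells(labels, ma_labels, overlap_frac = cfg$match_overlap)
      cmp <- compare_sample(au_cells, ma_cells, pairing)
      res$ma_cells <- ma_cells
      res$comparison <- cmp
      logline("%s: comparison -> %d matched, %d AU-only, %d MA-only",
              id, nrow(cmp$matched), length(cmp$au_only), length(cmp$ma_only))
      ## pooled cell table with pair ids for paired AU-vs-MA testing
      au_t <- pooled_rows(id, "AU", row$class, au_cells$fpol)
      ma_t <- pooled_rows(id, "MA", row$class, ma_cells$fpol)
      if (nrow(cmp$matched) > 0) {
        au_t$pair_id[match(cmp$matched$au_id, au_cells$cell_id)] <-
          paste0(id, "_", seq_len(nrow(cmp$matched)))
        ma_t$pair_id[match(cmp$matched$ma_id, ma_cells$cell_id)] <-
          paste0(id, "_", seq_len(nrow(cmp$matched)))
      }
      all_cells[[length(all_cells) + 1]] <- rbind(au_t, ma_t)
    } else {
      logline("%s: no manual mask; comparison stage skipped", id)
      all_cells[[length(all_cells) + 1]] <-
        pooled_rows(id, "AU", row$class, au_cells$fpol)
    }
    logline("%s: done in %.2f s", id, proc.time()[3] - t0)
    results[[id]] <- res
  }
  if (length(results) == 0) stop("no sample could be processed")
  cells <- do.call(rbind, all_cells)
  stats <- run_group_stats(cells, alpha = cfg$alpha)
  write.csv(stats$groups, file.path(cfg$out_dir, "group_summary.csv"),
            row.names = FALSE)
  jsonlite::write_json(stats$tests, file.path(cfg$out_dir, "test_report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  writeLines(logs, file.path(cfg$out_dir, "run_log.txt"))
  list(samples = results, cells = cells, stats = stats, log = logs,
       skipped = skipped)
}
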