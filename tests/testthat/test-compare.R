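test_that("symmetric percent difference reproduces reported group differences", {
  expect_equal(pct_diff(0.139, 0.137, digits = 1), 1.4)
  expect_equal(pct_diff(0.176, 0.172, digits = 1), 2.3)
  expect_equal(pct_diff(0.276, 0.267, digits = 1), 3.3)
  expect_equal(pct_diff(5, 5), 0)
  expect_error(pct_diff(1, -1), "undefined")
})

test_that("percent difference is antisymmetric and scale-invariant", {
  set.seed(2)
  a <- runif(20, 0.1, 0.4); b <- runif(20, 0.1, 0.4)
  expect_equal(pct_diff(a, b), -pct_diff(b, a))
  expect_equal(pct_diff(3.7 * a, 3.7 * b), pct_diff(a, b))
})

test_that("rounding for reports is half away from zero", {
  expect_equal(round_half_out(1.45, 1), 1.5)
  expect_equal(round_half_out(-1.45, 1), -1.5)
  expect_equal(round_half_out(2.349, 1), 2.3)
})

test_that("cell-count selection excess matches direct arithmetic", {
  expect_equal(selection_excess(426, 125, 50), 15.8)
  expect_equal(selection_excess(100, 0, 0), 0)
  expect_equal(selection_excess(0, 10, 5), 100)
  expect_error(selection_excess(0, 3, 0), "undefined")
})

toy_labels <- function(...) {
  m <- matrix(0L, 24, 24)
  regions <- list(...)
  for (i in seq_along(regions)) {
    r <- regions[[i]]
    m[r[1]:r[2], r[3]:r[4]] <- i
  }
  m
}

test_that("cell matching pairs by overlap with a >50%-of-smaller rule", {
  ma <- toy_labels(c(2, 9, 2, 9), c(14, 21, 2, 9), c(2, 9, 14, 21))
  ## identical masks: every cell matches itself with overlap = its area
  identical_match <- match_cells(ma, ma)
  expect_equal(nrow(identical_match$matched), 3)
  expect_equal(identical_match$matched$overlap_px,
               as_labeled_regions(ma)$sizes)
  expect_length(identical_match$au_only, 0)
  expect_length(identical_match$ma_only, 0)

  ## empty AU mask: everything is MA-only
  none <- match_cells(matrix(0L, 24, 24), ma)
  expect_equal(nrow(none$matched), 0)
  expect_equal(none$ma_only, 1:3)

  ## equal-size regions overlapping on 40% of their area stay unmatched
  ## (rule: overlap must exceed half of the smaller region)
  ma1 <- matrix(0L, 24, 24); ma1[1:10, 1:10] <- 1L    # 100 px
  au1 <- matrix(0L, 24, 24); au1[1:10, 7:16] <- 1L    # 100 px, 40 shared
  res <- match_cells(au1, ma1)
  expect_equal(nrow(res$matched), 0)
  expect_equal(res$au_only, 1L)
  expect_equal(res$ma_only, 1L)

  ## 60% overlap of the smaller region is accepted
  au2 <- matrix(0L, 24, 24); au2[1:10, 5:14] <- 1L    # 60 shared
  expect_equal(nrow(match_cells(au2, ma1)$matched), 1)

  ## a small region fully inside a large one is 100% of the smaller:
  ## matched even though it covers a minority of the larger region
  au3 <- matrix(0L, 24, 24); au3[1:4, 1:10] <- 1L     # 40 px inside ma1
  expect_equal(nrow(match_cells(au3, ma1)$matched), 1)

  expect_error(match_cells(matrix(0L, 8, 8), ma), "geometry")
})

test_that("matched plus unmatched counts conserve the inputs", {
  set.seed(14)
  for (i in 1:5) {
    au <- label_components(random_mask(48))
    ma <- label_components(random_mask(48))
    r <- match_cells(au, ma)
    expect_equal(nrow(r$matched) + length(r$au_only), au$n)
    expect_equal(nrow(r$matched) + length(r$ma_only), ma$n)
    expect_false(any(duplicated(r$matched$au_id)))
    expect_false(any(duplicated(r$matched$ma_id)))
  }
})

test_that("per-pair percent differences use AU first and summaries cover all cells", {
  au <- matrix(0L, 24, 24); au[2:9, 2:9] <- 1L
  ma <- au
  pairing <- match_cells(au, ma)
  au_cells <- data.frame(cell_id = 1L, area_px = 100L, area_um2 = 100,
                         fpol = 0.30)
  ma_cells <- data.frame(cell_id = 1L, area_px = 200L, area_um2 = 200,
                         fpol = 0.30)
  cmp <- compare_sample(au_cells, ma_cells, pairing)
  expect_equal(cmp$matched$delta_fpol_pct, 0)
  expect_equal(cmp$matched$delta_area_pct, -66.7)

  ## no matched pairs: summaries still computed over all cells
  cmp0 <- compare_sample(au_cells, ma_cells,
                         match_cells(matrix(0L, 24, 24), ma))
  expect_equal(nrow(cmp0$matched), 0)
  expect_equal(cmp0$summary$mean_fpol, c(0.30, 0.30))

  ## AU areas uniformly ~6% smaller -> mean delta area around -6%
  k <- 12
  aus <- data.frame(cell_id = 1:k, area_um2 = 0.94 * (20 + 1:k),
                    fpol = rep(0.25, k))
  mas <- data.frame(cell_id = 1:k, area_um2 = 20 + 1:k, fpol = rep(0.25, k))
  fake <- structure(list(matched = data.frame(au_id = 1:k, ma_id = 1:k,
                                              overlap_px = 1L),
                         au_only = integer(0), ma_only = integer(0),
                         n_au = k, n_ma = k),
                    class = "match_result")
  cmp6 <- compare_sample(aus, mas, fake, digits = NULL)
  expect_equal(mean(cmp6$matched$delta_area_pct), -100 * 0.06 / 0.97,
               tolerance = 1e-10)
})
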