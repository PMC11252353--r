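## construct a sample with exactly the requested moments, so t statistics
## equal their closed-form values
with_moments <- function(n, mean, sd, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  as.vector(scale(x)) * sd + mean
}

test_that("group summaries report sample mean and SD per method/diagnosis", {
  cells <- data.frame(method = c("AU", "AU"), diagnosis = "benign",
                      fpol = c(0.2, 0.3))
  s <- summarize_groups(cells)
  expect_equal(s$mean_fpol, 0.25)
  expect_equal(s$sd_fpol, 0.070711, tolerance = 1e-5)
  expect_equal(s$n, 2)

  ## duplicating every cell keeps the mean; the sample SD shrinks to
  ## sqrt(sum sq / (n - 1)) with n = 4 and sum sq = 0.01
  s2 <- summarize_groups(rbind(cells, cells))
  expect_equal(s2$mean_fpol, s$mean_fpol)
  expect_equal(s2$n, 4)
  expect_equal(s2$sd_fpol, sqrt(0.01 / 3), tolerance = 1e-12)

  ## single-cell group: SD reported as 0 with a warning
  expect_warning(
    s1 <- summarize_groups(data.frame(method = "MA", diagnosis = "normal",
                                      fpol = 0.18)),
    "single cell")
  expect_equal(s1$sd_fpol, 0)
})

test_that("paired and unpaired t-tests behave as Student's classical test", {
  x <- with_moments(30, 0.25, 0.02, seed = 3)
  expect_warning(r0 <- fpol_ttest(x, x, mode = "paired"), "zero variance")
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)

  ## well-separated groups with exact moments: closed-form pooled t
  a <- with_moments(50, 0.28, 0.02, seed = 4)
  b <- with_moments(50, 0.17, 0.02, seed = 5)
  r1 <- fpol_ttest(a, b, mode = "unpaired")
  expect_equal(r1$t, (0.28 - 0.17) / (0.02 * sqrt(2 / 50)), tolerance = 1e-10)
  expect_lt(r1$p, 1e-4)

  ## small paired perturbation (mean 0.005, SD 0.02, n = 100): t = 2.5,
  ## two-tailed p ~ 0.014 -- not significant at the 0.01 level
  au <- with_moments(100, 0.28, 0.02, seed = 6)
  ma <- au - with_moments(100, 0.005, 0.02, seed = 7)
  r2 <- fpol_ttest(au, ma, mode = "paired")
  expect_equal(r2$t, 2.5, tolerance = 1e-10)
  expect_gt(r2$p, 0.01)

  expect_error(fpol_ttest(1:3 / 10, 1:4 / 10, mode = "paired"), "equal-length")
  expect_error(fpol_ttest(0.1, c(0.1, 0.2), mode = "unpaired"), "at least 2")
})

test_that("swapping groups flips t and preserves p", {
  a <- with_moments(40, 0.28, 0.03, seed = 8)
  b <- with_moments(35, 0.17, 0.02, seed = 9)
  r1 <- fpol_ttest(a, b); r2 <- fpol_ttest(b, a)
  expect_equal(r1$t, -r2$t)
  expect_equal(r1$p, r2$p)
})

test_that("Bonferroni correction thresholds at alpha/m and is monotone", {
  expect_true(bonferroni(0.009, alpha = 0.01))
  expect_identical(bonferroni(rep(0.0019, 5), alpha = 0.01),
                   rep(TRUE, 5))                       # threshold 0.002
  expect_identical(bonferroni(rep(0.0021, 5), alpha = 0.01), rep(FALSE, 5))
  expect_identical(bonferroni(c(0.004, 0.02), alpha = 0.01), c(TRUE, FALSE))
  expect_error(bonferroni(numeric(0)), "empty")
  expect_error(bonferroni(1.2), "\\[0, 1\\]")

  set.seed(10)
  p <- runif(20)
  for (m in 1:3) {
    hi <- bonferroni(p, alpha = 0.01 * m)
    lo <- bonferroni(p, alpha = 0.005 * m)
    expect_true(all(hi | !lo))    # lowering alpha never adds a rejection
  }
})

test_that("the combined group analysis builds the comparison family", {
  set.seed(11)
  mk <- function(method, diagnosis, n, mean, pair_ids = NA) {
    data.frame(method = method, diagnosis = diagnosis,
               fpol = rnorm(n, mean, 0.02),
               pair_id = pair_ids, stringsAsFactors = FALSE)
  }
  cells <- rbind(mk("AU", "malignant", 40, 0.28, paste0("m", 1:40)),
                 mk("MA", "malignant", 40, 0.28, paste0("m", 1:40)),
                 mk("AU", "benign", 40, 0.17, paste0("b", 1:40)),
                 mk("MA", "benign", 40, 0.17, paste0("b", 1:40)),
                 mk("AU", "normal", 30, 0.18),
                 mk("MA", "normal", 30, 0.18))
  res <- run_group_stats(cells, alpha = 0.01)
  expect_equal(nrow(res$groups), 6)
  ## 4 unpaired between-diagnosis + 2 paired AU-vs-MA (matched diagnoses)
  expect_equal(nrow(res$tests), 6)
  expect_true(all(res$tests$m == 6))
  between <- grepl("malignant vs", res$tests$label)
  expect_true(all(res$tests$significant[between]))
  expect_false(any(res$tests$significant[!between]))
})
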