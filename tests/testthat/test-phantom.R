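test_that("cross-channel inversion reproduces the Fpol formula", {
  expect_equal(fpol_to_cross_intensity(200, 0.30, 0.75), 143.59, tolerance = 1e-4)
  expect_equal(fpol_to_cross_intensity(150, 0, 1.0), 150)
  expect_equal(fpol_to_cross_intensity(100, 1.0, 0.75), 0)
  ## substituting back recovers the target exactly
  for (f in c(-0.5, 0, 0.17, 0.28, 0.9)) {
    ic <- fpol_to_cross_intensity(123.4, f, 0.75)
    expect_equal(fpol_from_means(123.4, ic, 0.75), f, tolerance = 1e-12)
  }
  expect_error(fpol_to_cross_intensity(100, -1, 0.75), "division by zero")
  expect_error(fpol_to_cross_intensity(100, 0.2, 0), "positive")
  expect_error(fpol_to_cross_intensity(-5, 0.2, 0.75), "non-negative")
})

test_that("cross intensity strictly decreases as target Fpol increases", {
  f <- seq(-0.9, 1, by = 0.05)
  ix <- fpol_to_cross_intensity(200, f, 0.75)
  expect_true(all(diff(ix) < 0))
})

test_that("phantom spec validates its invariants", {
  expect_error(phantom_spec(fpol_targets = c(0.2, -1.2)), "\\(-1, 1\\]")
  expect_error(phantom_spec(base_co_intensity = 300), "\\[3, 254\\]")
  expect_error(phantom_spec(image_size = 40, cell_radius_range = c(15, 35)),
               "twice the maximum cell radius")
  expect_error(phantom_spec(background_level = 5), "validity threshold")
})

test_that("phantom with no cells is empty; disjoint placement gives one component per cell", {
  ph0 <- generate_phantom(phantom_spec(image_size = 64, n_cells = 0,
                                       cell_radius_range = c(4, 8), seed = 1))
  expect_false(any(ph0$masks$high_quality))
  expect_equal(nrow(ph0$truth), 0)

  ph12 <- generate_phantom(phantom_spec(image_size = 256, n_cells = 12,
                                        cluster_fraction = 0, noise_sd = 0,
                                        ambiguous_fraction = 0,
                                        cell_radius_range = c(6, 12), seed = 2))
  expect_equal(label_components(ph12$masks$high_quality)$n, 12)
})

test_that("ground-truth quantification recovers each specified Fpol", {
  fpols <- seq(0.10, 0.33, length.out = 6)
  sp <- phantom_spec(image_size = 192, n_cells = 6, fpol_targets = fpols,
                     cell_radius_range = c(6, 14), cluster_fraction = 0,
                     ambiguous_fraction = 0, noise_sd = 0, seed = 5)
  ph <- generate_phantom(sp)
  q <- quantify_sample(ph$pair, ph$labels)
  expect_equal(nrow(q), 6)
  expect_true(all(abs(q$fpol - ph$truth$fpol) < 0.01))   # 8-bit quantization bound

  spn <- phantom_spec(image_size = 192, n_cells = 6, fpol_targets = fpols,
                      cell_radius_range = c(6, 14), cluster_fraction = 0,
                      ambiguous_fraction = 0, noise_sd = 0, quantize = FALSE,
                      seed = 5)
  phn <- generate_phantom(spn)
  qn <- quantify_sample(phn$pair, phn$labels)
  expect_true(all(abs(qn$fpol - phn$truth$fpol) <= 1e-12))
})

test_that("phantoms are deterministic in their spec and seed", {
  sp <- desk_phantom_spec(9)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$pair$co, b$pair$co)
  expect_identical(a$pair$cross, b$pair$cross)
  expect_identical(a$labels, b$labels)
  c <- generate_phantom(desk_phantom_spec(10))
  expect_false(identical(a$pair$co, c$pair$co))
})

test_that("the three masks partition intent and truth regions are connected", {
  ph <- generate_phantom(desk_phantom_spec(4))
  m <- ph$masks
  expect_false(any(m$high_quality & m$background))
  expect_false(any(m$ambiguous & m$high_quality))
  expect_true(all(m$background | m$ambiguous | m$high_quality))
  ## every truth pixel set is connected and inside the high-quality mask
  expect_true(all(ph$labels[!m$high_quality] == 0L))
  for (id in ph$truth$cell_id) {
    comp <- label_components(ph$labels == id)
    expect_equal(comp$n, 1)
  }
})

test_that("fixture sets round-trip through disk and are byte-identical on rewrite", {
  dir1 <- withr::local_tempdir()
  specs <- list(desk_phantom_spec(21, image_size = 64, n_cells = 2,
                                  fpols = c(0.15, 0.3)),
                desk_phantom_spec(22, image_size = 64, n_cells = 2,
                                  fpols = c(0.2, 0.25)))
  man <- write_fixture_set(specs, dir1, classes = c("malignant", "benign"))
  expect_equal(nrow(man), 2)
  expect_true(all(file.exists(man$co_path, man$cross_path, man$mask_path)))
  expect_identical(man$class, c("malignant", "benign"))

  ## reading back reproduces the generated sample
  ph <- generate_phantom(specs[[1]])
  pair <- read_pair(man$co_path[1], man$cross_path[1])
  expect_equal(pair$co, ph$pair$co, ignore_attr = TRUE)
  expect_equal(read_label_tiff(man$mask_path[1]), ph$labels, ignore_attr = TRUE)

  ## determinism contract: same specs written twice -> byte-identical files
  dir2 <- withr::local_tempdir()
  man2 <- write_fixture_set(specs, dir2, classes = c("malignant", "benign"))
  for (i in 1:2) {
    expect_identical(readBin(man$co_path[i], "raw", file.size(man$co_path[i])),
                     readBin(man2$co_path[i], "raw", file.size(man2$co_path[i])))
  }

  ## empty spec list -> empty manifest, no image files
  dir3 <- withr::local_tempdir()
  man3 <- write_fixture_set(list(), dir3)
  expect_equal(nrow(man3), 0)
  expect_equal(length(list.files(dir3, pattern = "[.]tif$")), 0)
})
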