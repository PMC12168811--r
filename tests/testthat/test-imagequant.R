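test_that("maximum projection equals the per-pixel loop maximum", {
  m <- matrix(1:6, 2, 3)
  expect_identical(max_project(m), m)
  two <- array(c(3, 9), dim = c(1, 1, 2))
  expect_equal(max_project(two)[1, 1], 9)
  set.seed(12)
  st <- array(runif(5 * 4 * 3), dim = c(5, 4, 3))
  proj <- max_project(st)
  for (i in 1:5) for (j in 1:4) {
    mx <- -Inf
    for (k in 1:3) if (st[i, j, k] > mx) mx <- st[i, j, k]
    expect_identical(proj[i, j], mx)
  }
  expect_error(max_project(array(0, dim = c(2, 2, 0))), "plane")
})

test_that("binarisation separates bimodal pixel populations", {
  expect_identical(binarize(matrix(c(50, 150), 1), "fixed", threshold = 100),
                   matrix(c(FALSE, TRUE), 1))
  expect_false(any(binarize(matrix(5, 10, 10), "fixed", threshold = 100)))
  expect_error(binarize(matrix(7, 10, 10), "otsu"), "constant")
  set.seed(8)
  truth <- matrix(runif(100 * 100) < 0.3, 100, 100)
  img <- matrix(rnorm(1e4, mean = 20, sd = 8), 100, 100)
  img[truth] <- rnorm(sum(truth), mean = 200, sd = 10)
  mask <- binarize(img)
  expect_lt(mean(mask != truth), 0.01)
})

test_that("the area-to-count rule maps component areas with strict bounds", {
  rule <- area_rule()
  expect_identical(area_to_count(c(25, 80, 150, 250), rule), c(0L, 1L, 2L, 3L))
  expect_identical(sum(area_to_count(c(25, 80, 150, 250), rule)), 6L)
  # "above" is strict: 130 is one nucleus, 200 is two; 30 is kept
  expect_identical(area_to_count(c(130, 200, 30, 29.999), rule),
                   c(1L, 2L, 1L, 0L))
  # monotone non-decreasing in area
  areas <- sort(runif(200, 0, 400))
  expect_true(all(diff(area_to_count(areas, rule)) >= 0))
  expect_error(area_rule(exclude_below_um2 = 150), "exclude_below")
})

test_that("nucleus counting applies the rule to 8-connected components", {
  # two diagonal pixels form one component under 8-connectivity
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE
  res <- count_nuclei(m, pixel_size_um = 7, rule = area_rule())
  expect_identical(nrow(res$components), 1L)
  expect_equal(res$components$area_um2, 98)
  expect_identical(res$count, 1L)
  expect_identical(count_nuclei(matrix(FALSE, 4, 4), 1)$count, 0L)

  slide <- gen_if_image(image_sim_config(n_nuclei = 50, purity_fraction = 1,
                                         n_debris = 10, seed = 6))
  mask <- binarize(slide$image[, , 1])
  res <- count_nuclei(mask, 0.62)
  expect_identical(res$count, 50L)  # debris never counts
})

test_that("counts are invariant under translation and rotation", {
  slide <- gen_if_image(image_sim_config(n_nuclei = 20, n_merged_pairs = 2,
                                         seed = 9))
  mask <- binarize(slide$image[, , 1])
  n0 <- count_nuclei(mask, 0.62)$count
  rot <- t(mask)[ncol(mask):1, ]
  expect_identical(count_nuclei(rot, 0.62)$count, n0)
  shifted <- matrix(FALSE, nrow(mask) + 10, ncol(mask) + 10)
  shifted[11:(10 + nrow(mask)), 11:(10 + ncol(mask))] <- mask
  expect_identical(count_nuclei(shifted, 0.62)$count, n0)
})

test_that("colocalization is the symmetric mask intersection", {
  a <- matrix(FALSE, 40, 40); b <- matrix(FALSE, 40, 40)
  a[2:10, 2:10] <- TRUE
  b[20:30, 20:30] <- TRUE
  expect_identical(coloc_count(a, b, 1)$count, 0L)
  disk <- matrix(FALSE, 40, 40)
  for (i in 1:40) for (j in 1:40) {
    if ((i - 20)^2 + (j - 20)^2 <= 25) disk[i, j] <- TRUE
  }
  expect_identical(coloc_count(disk, disk, 1)$count, 1L)
  set.seed(4)
  ra <- matrix(runif(1600) < 0.4, 40, 40)
  rb <- matrix(runif(1600) < 0.4, 40, 40)
  expect_identical(coloc_count(ra, rb, 2)$count, coloc_count(rb, ra, 2)$count)
  expect_error(coloc_count(a, matrix(FALSE, 10, 10), 1), "shape")
})

test_that("merged pairs count as two nuclei and debris as zero", {
  cfg <- image_sim_config(n_nuclei = 20, purity_fraction = 1,
                          n_merged_pairs = 3, n_debris = 8, seed = 13)
  slide <- gen_if_image(cfg)
  expect_identical(slide$n_dapi_true, 26L)  # 20 + 2 * 3
  expect_identical(sum(slide$truth$n_nuclei), slide$n_dapi_true)
  mask <- binarize(slide$image[, , 1])
  res <- count_nuclei(mask, cfg$pixel_size_um)
  expect_identical(res$count, 26L)
  pair_areas <- res$components$area_um2[res$components$n_nuclei == 2L]
  expect_identical(length(pair_areas), 3L)
  expect_true(all(pair_areas > 130 & pair_areas <= 200))
})

test_that("purity recovers the configured double-positive fraction", {
  all_pos <- gen_if_image(image_sim_config(n_nuclei = 30, purity_fraction = 1,
                                           seed = 2))
  p <- compute_purity(all_pos$image)
  expect_equal(p$purity_pct, 100)

  cfg <- image_sim_config(n_nuclei = 100, purity_fraction = 0.9, seed = 3)
  slide <- gen_if_image(cfg)
  p <- compute_purity(slide$image, pixel_size_um = cfg$pixel_size_um)
  expect_equal(p$purity_pct, 90)
  expect_identical(p$n_dapi, 100L)
  expect_identical(p$n_double_positive, 90L)

  blank <- array(0, dim = c(64, 64, 3))
  blank[1, 1, ] <- 1  # non-constant so thresholding is defined
  expect_error(compute_purity(blank), "purity")
})

test_that("image generator validates its config and is deterministic", {
  expect_error(image_sim_config(nucleus_radius_um = 2), "30 um")
  expect_error(image_sim_config(purity_fraction = 1.4), "\\[0, 1\\]")
  a <- gen_if_image(image_sim_config(n_nuclei = 15, seed = 5))
  b <- gen_if_image(image_sim_config(n_nuclei = 15, seed = 5))
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
})
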