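# Calibration, masking, augmentation, normalisation, cropping, patches

make_cube <- function(data, wl = NULL) {
  if (is.null(wl)) wl <- seq(400, 1000, length.out = dim(data)[3])
  reflectance_cube(data, wl)
}

test_that("reflectance calibration satisfies its identities", {
  d <- c(6, 5, 4)
  white <- array(runif(prod(d), 3000, 4000), d)
  black <- array(runif(prod(d), 90, 110), d)
  wl <- seq(400, 1000, length.out = 4)
  expect_equal(calibrate_reflectance(white, white, black, wl)$data,
               array(1, d))
  expect_equal(calibrate_reflectance(black, white, black, wl)$data,
               array(0, d))
  raw <- array(60, d); b <- array(10, d); w <- array(110, d)
  expect_equal(calibrate_reflectance(raw, w, b, wl)$data, array(0.5, d))
  expect_error(calibrate_reflectance(raw, w[1:3, , ], b, wl), "shape")
})

test_that("dead reference pixels are zeroed with a warning", {
  d <- c(3, 3, 2)
  raw <- array(50, d); black <- array(10, d)
  white <- array(110, d); white[1, 1, 1] <- 10
  expect_warning(out <- calibrate_reflectance(raw, white, black,
                                              c(500, 600)),
                 "white == black")
  expect_equal(out$data[1, 1, 1], 0)
  expect_equal(out$data[2, 2, 2], 0.4)
})

test_that("ratio mask follows the inclusive threshold and keeps the
           largest component", {
  wl <- c(500, 525.54, 715.16, 800)
  d <- array(1, c(4, 4, 4))
  # pixel ratios at the two mask bands: build a 2x2 fruit block with ratio
  # 2.0, one boundary pixel at exactly 1.6, and a lone stray pixel
  num <- matrix(1, 4, 4); den <- matrix(1, 4, 4)
  num[1:2, 1:2] <- 2.0
  num[3, 2] <- 1.6   # touches the fruit block: included at the boundary
  num[4, 4] <- 3.0   # isolated stray pixel: removed as a small component
  d[, , 2] <- den; d[, , 3] <- num
  cube <- reflectance_cube(d, wl)
  m <- compute_ratio_mask(cube)
  expect_true(all(m$mask[1:2, 1:2]))
  expect_true(m$mask[3, 2])
  expect_false(m$mask[4, 4])
  expect_equal(sum(m$mask), 5)

  uniform <- reflectance_cube(array(1, c(4, 4, 4)), wl)
  expect_error(compute_ratio_mask(uniform), "no ROI found")
  expect_error(compute_ratio_mask(cube, band_num_nm = 1200), "wavelength")
})

test_that("mask equals the synthetic truth disk exactly on noiseless cubes", {
  p <- scene_params(noise_sd = 0)
  for (seed in c(1, 7)) {
    lc <- generate_cube(p, 14, seed = seed)
    cube <- calibrate_reflectance(lc)
    m <- compute_ratio_mask(cube)
    expect_identical(unname(m$mask), unname(lc$truth_mask))
  }
})

test_that("mean spectrum equals an explicit loop average", {
  set.seed(3)
  d <- array(runif(5 * 5 * 4), c(5, 5, 4))
  cube <- make_cube(d)
  mask <- matrix(runif(25) > 0.5, 5, 5)
  if (!any(mask)) mask[2, 2] <- TRUE
  oracle <- numeric(4)
  for (b in 1:4) {
    acc <- 0; cnt <- 0
    for (i in 1:5) for (j in 1:5) if (mask[i, j]) {
      acc <- acc + d[i, j, b]; cnt <- cnt + 1
    }
    oracle[b] <- acc / cnt
  }
  expect_equal(extract_mean_spectrum(cube, mask), oracle, tolerance = 1e-12)

  single <- matrix(FALSE, 5, 5); single[4, 2] <- TRUE
  expect_equal(extract_mean_spectrum(cube, single), d[4, 2, ])
  const <- make_cube(array(0.3, c(5, 5, 4)))
  expect_equal(extract_mean_spectrum(const, mask), rep(0.3, 4))
  expect_error(extract_mean_spectrum(cube, matrix(FALSE, 5, 5)), "empty")
})

test_that("augmentation yields exactly five cubes with the original first", {
  set.seed(4)
  cube <- make_cube(array(runif(15 * 15 * 3), c(15, 15, 3)))
  aug <- augment_cube(cube, seed = 2)
  expect_length(aug, 5)
  expect_identical(aug[[1]]$data, cube$data)
  for (a in aug) expect_identical(dim(a$data), dim(cube$data))
  # same seed, same angles
  aug2 <- augment_cube(cube, seed = 2)
  expect_identical(aug[[3]]$data, aug2[[3]]$data)
  expect_error(augment_cube(make_cube(array(1, c(4, 6, 3)))), "square")
})

test_that("left-right mirroring is an involution", {
  cube <- make_cube(array(rnorm(9 * 9 * 2), c(9, 9, 2)))
  m1 <- augment_cube(cube, seed = 1)[[5]]
  m2 <- augment_cube(m1, seed = 1)[[5]]
  expect_identical(m2$data, cube$data)
})

test_that("180-degree rotation preserves a centrally symmetric disk", {
  # odd-sized raster with a disk about the exact centre
  n <- 33
  r <- outer(1:n, rep(1, n)) - 17
  c <- t(r)
  disk <- 0.1 + 0.6 * (r^2 + c^2 <= 10^2)
  data <- array(disk, c(n, n, 2))
  rot <- hyperbrix:::rotate_cube_data(data, 180)
  expect_equal(rot, data, tolerance = 1e-8)
})

test_that("normalisation maps to [0, 1] and flags constant cubes", {
  d <- array(runif(60, 0.2, 0.7), c(5, 4, 3))
  d[1] <- 0.2; d[60] <- 0.7
  out <- normalize_cube(make_cube(d))
  expect_equal(range(out$data), c(0, 1))

  already <- array(seq(0, 1, length.out = 24), c(4, 3, 2))
  expect_equal(normalize_cube(make_cube(already))$data, already)

  expect_warning(z <- normalize_cube(make_cube(array(2, c(3, 3, 2)))),
                 "constant")
  expect_equal(z$data, array(0, c(3, 3, 2)))
})

test_that("cropping centres the window on the ROI centroid", {
  set.seed(8)
  d <- array(runif(300 * 300 * 2), c(300, 300, 2))
  cube <- make_cube(d)
  mask <- matrix(FALSE, 300, 300)
  mask[101:160, 141:200] <- TRUE # centroid (130.5, 170.5)
  out <- crop_to(cube, mask, size = 224)
  expect_identical(dim(out$cube$data)[1:2], c(224L, 224L))
  cen <- c(mean(row(out$mask)[out$mask]), mean(col(out$mask)[out$mask]))
  expect_true(all(abs(cen - (224 + 1) / 2) <= 1))

  small <- make_cube(array(runif(64 * 64 * 2), c(64, 64, 2)))
  smask <- matrix(TRUE, 64, 64)
  expect_identical(crop_to(small, smask, size = 64)$cube$data, small$data)
  expect_error(crop_to(small, smask, size = 16), ">= 31")
})

test_that("patch pairs have the contract shapes and centre values", {
  p <- scene_params(n_rows = 40, n_cols = 40, n_bands = 8,
                    informative_bands = c(680, 880))
  lc <- generate_cube(p, 12, seed = 3)
  cube <- calibrate_reflectance(lc)
  ps <- extract_patch_pairs(cube, lc$truth_mask, k_centers = 4, seed = 5,
                            sample_id = "f1", label = 12)
  expect_length(ps, 4)
  for (pp in ps) {
    expect_identical(dim(pp$spectral_patch), c(3L, 3L, 8L))
    expect_identical(dim(pp$spatial_patch), c(31L, 31L, 8L))
    expect_true(lc$truth_mask[pp$center[1], pp$center[2]])
    expect_equal(pp$spectral_patch[2, 2, ],
                 cube$data[pp$center[1], pp$center[2], ])
    expect_equal(pp$spatial_patch[16, 16, ],
                 cube$data[pp$center[1], pp$center[2], ])
  }
  expect_error(extract_patch_pairs(cube, lc$truth_mask, k_centers = 0),
               "k_centers")
})

test_that("border patches match an explicit reflect-pad oracle", {
  set.seed(10)
  d <- array(rnorm(5 * 5 * 2), c(5, 5, 2))
  cube <- make_cube(d)
  mask <- matrix(FALSE, 5, 5); mask[1, 1] <- TRUE
  pp <- extract_patch_pairs(cube, mask, k_centers = 1, seed = 1,
                            spectral_size = 3L, spatial_size = 5L)[[1]]
  # mirror reflection without border duplication: index 0 -> 2, -1 -> 3
  pad_idx <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 2 - i
      if (i > n) i <- 2 * n - i
    }
    i
  }
  oracle <- array(0, c(5, 5, 2))
  for (r in -1:3) for (cl in -1:3) for (b in 1:2) {
    oracle[r + 2, cl + 2, b] <- d[pad_idx(r, 5), pad_idx(cl, 5), b]
  }
  expect_equal(pp$spatial_patch, oracle)
})

test_that("augmenting training folds never touches validation identities", {
  p <- scene_params(n_rows = 40, n_cols = 40, n_bands = 8,
                    informative_bands = c(680, 880))
  ds <- generate_dataset(p, 8, seed = 2)
  labels <- ds$labels
  prepped <- hyperbrix:::prepare_cubes(ds, labels$sample_id)
  ids <- labels$sample_id
  tr_ids <- ids[1:5]; va_ids <- ids[6:8]
  tr <- hyperbrix:::collect_patches(prepped, tr_ids, labels, 2, seed = 1,
                                    augment = TRUE)
  va <- hyperbrix:::collect_patches(prepped, va_ids, labels, 2, seed = 1,
                                    augment = FALSE)
  tr_seen <- unique(vapply(tr, function(x) x$sample_id, character(1)))
  va_seen <- unique(vapply(va, function(x) x$sample_id, character(1)))
  expect_setequal(tr_seen, tr_ids)
  expect_setequal(va_seen, va_ids)
  expect_length(intersect(tr_seen, va_seen), 0)
  # five augmented copies per training fruit
  expect_length(tr, 5 * 2 * length(tr_ids))
})
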