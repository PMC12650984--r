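# Synthetic hyperspectral scene generator

test_that("sample_ssc reproduces the reference distribution", {
  p0 <- scene_params(ssc_sd = 0)
  expect_equal(sample_ssc(p0, 3), rep(11.76, 3))

  p <- scene_params()
  draws <- sample_ssc(p, 10000, seed = 123)
  expect_true(abs(mean(draws) - 11.76) < 0.1)
  expect_true(abs(sd(draws) - 1.92) < 0.1)
  expect_true(all(draws >= 7.2 & draws <= 18.1))

  expect_identical(sample_ssc(p, 1, seed = 9), sample_ssc(p, 1, seed = 9))
  expect_error(sample_ssc(p, 0), "positive")
})

test_that("scene parameter invariants are enforced", {
  expect_error(scene_params(n_bands = 4), "n_bands")
  expect_error(scene_params(fruit_radius_frac = 0.6), "fruit_radius_frac")
  expect_error(scene_params(informative_bands = c(680, 1200)),
               "informative band")
  expect_error(generate_cube(scene_params(), ssc = 25), "outside")
})

test_that("fruit disk size matches the rasterised-circle oracle", {
  p <- scene_params()
  lc <- generate_cube(p, 12, seed = 1)
  r <- p$fruit_radius_frac * min(p$n_rows, p$n_cols)
  expect_lt(abs(sum(lc$truth_mask) - pi * r^2) / (pi * r^2), 0.05)
  expect_identical(dim(lc$raw), dim(lc$white_ref))
  expect_identical(dim(lc$raw), dim(lc$black_ref))
  expect_true(all(lc$black_ref[lc$truth_mask] < lc$white_ref[lc$truth_mask]))
})

test_that("noiseless cubes have spatially constant calibrated fruit pixels", {
  p <- scene_params(noise_sd = 0, illumination_cv = 0)
  lc <- generate_cube(p, 10, seed = 4)
  cube <- calibrate_reflectance(lc)
  for (b in c(1, 10, 25)) {
    vals <- cube$data[, , b][lc$truth_mask]
    expect_lt(diff(range(vals)), 1e-12)
  }
})

test_that("fruit reflectance at informative bands decreases with SSC", {
  p <- scene_params(noise_sd = 0)
  grid <- seq(8, 17, length.out = 5)
  bands <- vapply(p$informative_bands, function(nm) {
    which.min(abs(seq(p$wavelength_min, p$wavelength_max,
                      length.out = p$n_bands) - nm))
  }, integer(1))
  means <- sapply(grid, function(ssc) {
    lc <- generate_cube(p, ssc, seed = 99)
    cube <- calibrate_reflectance(lc)
    vapply(bands, function(b) mean(cube$data[, , b][lc$truth_mask]),
           numeric(1))
  })
  for (i in seq_along(bands)) {
    expect_true(all(diff(means[i, ]) < 0))
  }
})

test_that("generate_dataset is deterministic and seed-sensitive", {
  p <- scene_params(n_rows = 24, n_cols = 24, n_bands = 8,
                    informative_bands = c(680, 880))
  ds <- generate_dataset(p, 10, seed = 5)
  expect_length(ds$cubes, 10)
  expect_equal(nrow(ds$labels), 10)
  expect_setequal(ds$labels$split, c("calibration", "prediction"))

  ds2 <- generate_dataset(p, 10, seed = 5)
  expect_identical(ds$labels, ds2$labels)
  expect_identical(ds$cubes[[3]]$raw, ds2$cubes[[3]]$raw)

  ds3 <- generate_dataset(p, 10, seed = 6)
  expect_false(identical(ds$labels$ssc_brix, ds3$labels$ssc_brix))
  expect_error(generate_dataset(p, 1), ">= 2")
})

test_that("ENVI round-trip preserves cubes and wavelengths", {
  p <- scene_params(n_rows = 12, n_cols = 10, n_bands = 8,
                    informative_bands = c(680, 880))
  lc <- generate_cube(p, 11, seed = 2)
  prefix <- file.path(withr::local_tempdir(), "cube")
  write_envi(lc$raw, lc$wavelengths, prefix)
  back <- read_envi(prefix)
  # written as 32-bit floats, so round-trip at single precision
  expect_equal(back$data, lc$raw, tolerance = 1e-6)
  expect_equal(back$wavelengths, lc$wavelengths, tolerance = 1e-6)
})

test_that("write_dataset emits per-sample ENVI files and a label CSV", {
  p <- scene_params(n_rows = 10, n_cols = 10, n_bands = 8,
                    informative_bands = c(680, 880))
  ds <- generate_dataset(p, 6, seed = 8)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "labels.csv")))
  labs <- read.csv(file.path(dir, "labels.csv"))
  expect_equal(labs$sample_id, ds$labels$sample_id)
  expect_true(all(file.exists(file.path(
    dir, paste0(ds$labels$sample_id, "_raw.hdr")))))
})
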