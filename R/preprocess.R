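#' Construct a reflectance cube
#'
#' A calibrated hyperspectral raster: a rows x cols x bands array of
#' dimensionless reflectance (nominally in \[0, 1\]) with a strictly
#' increasing wavelength axis in nm.
#'
#' @param data 3-D numeric array, rows x cols x bands, finite.
#' @param wavelengths Numeric vector, length bands, strictly increasing nm.
#' @return An object of class `reflectance_cube`.
#' @export
reflectance_cube <- function(data, wavelengths) {
  if (length(dim(data)) != 3) {
    stop("data must be a rows x cols x bands array", call. = FALSE)
  }
  if (length(wavelengths) != dim(data)[3]) {
    stop("wavelengths length (", length(wavelengths),
         ") must equal the number of bands (", dim(data)[3], ")",
         call. = FALSE)
  }
  if (any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (!all(is.finite(data))) stop("data must be finite", call. = FALSE)
  structure(list(data = data, wavelengths = wavelengths),
            class = "reflectance_cube")
}

#' @export
print.reflectance_cube <- function(x, ...) {
  d <- dim(x$data)
  cat("<reflectance_cube> ", d[1], "x", d[2], "x", d[3], " (",
      round(min(x$wavelengths), 1), "-", round(max(x$wavelengths), 1),
      " nm), range [", signif(min(x$data), 3), ", ",
      signif(max(x$data), 3), "]\n", sep = "")
  invisible(x)
}

#' Reflectance calibration against white and black references
#'
#' Converts raw sensor counts to reflectance with the standard two-point
#' correction `(raw - black) / (white - black)`, which removes uneven
#' illumination baked into the white reference and dark-current offset.
#' Pixels where `white == black` (dead reference pixels) are set to 0 and
#' counted in a warning.
#'
#' @param raw 3-D count array, or a `labeled_cube` (in which case the
#'   references and wavelengths are taken from it).
#' @param white,black 3-D reference count arrays, same shape as `raw`.
#' @param wavelengths Band centres in nm (required when `raw` is an array).
#' @return A [reflectance_cube()].
#' @export
calibrate_reflectance <- function(raw, white = NULL, black = NULL,
                                  wavelengths = NULL) {
  if (inherits(raw, "labeled_cube")) {
    white <- raw$white_ref; black <- raw$black_ref
    wavelengths <- raw$wavelengths; raw <- raw$raw
  }
  if (!identical(dim(raw), dim(white)) || !identical(dim(raw), dim(black))) {
    stop("raw, white and black must share the same shape", call. = FALSE)
  }
  denom <- white - black
  bad <- denom == 0
  denom[bad] <- 1
  out <- (raw - black) / denom
  if (any(bad)) {
    out[bad] <- 0
    warning(sum(bad), " pixel(s) with white == black set to 0",
            call. = FALSE)
  }
  reflectance_cube(out, wavelengths)
}

nearest_band <- function(wavelengths, nm) which.min(abs(wavelengths - nm))

#' Band-ratio region-of-interest mask
#'
#' Segments the fruit by thresholding the ratio of two reflectance bands
#' chosen where fruit and background differ most (defaults 715.16 nm over
#' 525.54 nm): a pixel enters the mask iff its ratio is at least
#' `threshold` (the comparison is inclusive at the boundary). The nearest
#' available band to each requested wavelength is used. Pixels with a zero
#' denominator are excluded, and only the largest connected component of
#' above-threshold pixels is retained so stray background pixels cannot
#' corrupt the ROI.
#'
#' @param cube A [reflectance_cube()].
#' @param band_num_nm,band_den_nm Numerator/denominator band centres, nm.
#' @param threshold Minimum ratio (default 1.6).
#' @return An object of class `roi_mask`: list with `mask` (logical
#'   rows x cols), `threshold`, `band_num_nm`, `band_den_nm`.
#' @export
compute_ratio_mask <- function(cube, band_num_nm = 715.16,
                               band_den_nm = 525.54, threshold = 1.6) {
  stopifnot(inherits(cube, "reflectance_cube"))
  wl <- cube$wavelengths
  if (band_num_nm < min(wl) || band_num_nm > max(wl) ||
      band_den_nm < min(wl) || band_den_nm > max(wl)) {
    stop("ratio bands must lie within the cube's wavelength range [",
         min(wl), ", ", max(wl), "] nm", call. = FALSE)
  }
  num <- cube$data[, , nearest_band(wl, band_num_nm)]
  den <- cube$data[, , nearest_band(wl, band_den_nm)]
  ok <- den != 0
  ratio <- matrix(0, nrow(num), ncol(num))
  ratio[ok] <- num[ok] / den[ok]
  mask <- ok & ratio >= threshold
  if (!any(mask)) {
    stop("no ROI found: no pixel reaches the band-ratio threshold ",
         threshold, call. = FALSE)
  }
  labels <- EBImage::bwlabel(mask)
  counts <- tabulate(labels[labels > 0])
  mask <- labels == which.max(counts)
  structure(
    list(mask = mask, threshold = threshold,
         band_num_nm = band_num_nm, band_den_nm = band_den_nm),
    class = "roi_mask"
  )
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("<roi_mask> ", sum(x$mask), "/", length(x$mask), " pixels (ratio ",
      x$band_num_nm, "/", x$band_den_nm, " nm >= ", x$threshold, ")\n",
      sep = "")
  invisible(x)
}

as_mask_matrix <- function(mask) {
  if (inherits(mask, "roi_mask")) mask$mask else mask
}

#' Mean spectrum over a region of interest
#'
#' @param cube A [reflectance_cube()].
#' @param mask An `roi_mask` or logical matrix with at least one `TRUE`.
#' @return Numeric vector, one mean reflectance per band.
#' @export
extract_mean_spectrum <- function(cube, mask) {
  stopifnot(inherits(cube, "reflectance_cube"))
  m <- as_mask_matrix(mask)
  if (!any(m)) stop("mask is empty", call. = FALSE)
  idx <- which(m)
  apply(cube$data, 3, function(plane) mean(plane[idx]))
}

# Bilinear rotation of one band about the raster centre; angle in degrees,
# out-of-frame samples take `fill`.
rotate_band <- function(m, angle, fill) {
  nr <- nrow(m); nc <- ncol(m)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  th <- angle * pi / 180
  co <- cos(th); si <- sin(th)
  r <- matrix(seq_len(nr), nr, nc) - cr
  c <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cc
  # inverse mapping: output pixel samples the input at the back-rotated point
  rs <- co * r - si * c + cr
  cs <- si * r + co * c + cc
  r0 <- floor(rs); c0 <- floor(cs)
  fr <- rs - r0; fc <- cs - c0
  at <- function(ri, ci) {
    v <- matrix(fill, nr, nc)
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    v[ok] <- m[cbind(ri[ok], ci[ok])]
    v
  }
  (1 - fr) * (1 - fc) * at(r0, c0) +
    (1 - fr) * fc * at(r0, c0 + 1) +
    fr * (1 - fc) * at(r0 + 1, c0) +
    fr * fc * at(r0 + 1, c0 + 1)
}

rotate_cube_data <- function(data, angle, mask = NULL) {
  out <- data
  for (b in seq_len(dim(data)[3])) {
    plane <- data[, , b]
    # fill with the band's background level so rotation does not smear the
    # fruit into a black frame
    fill <- if (is.null(mask)) stats::median(plane) else
      stats::median(plane[!mask])
    out[, , b] <- rotate_band(plane, angle, fill)
  }
  out
}

mirror_lr_data <- function(data) data[, rev(seq_len(dim(data)[2])), , drop = FALSE]

#' Rotation and mirroring augmentation
#'
#' Expands one cube into exactly five: the original, three rotated copies
#' with angles drawn uniformly from 0-30, 150-180 and 180-210 degrees, and
#' a left-right mirrored copy of the original. Small-angle and near-180
#' rotations emulate the tilt variation of fruit placed on a stage;
#' rotation is bilinear per band with the band's background median as fill.
#' All five outputs share the input's shape and label.
#'
#' @param cube A [reflectance_cube()] with square spatial dims (reflect-pad
#'   first if needed, e.g. via [crop_to()]).
#' @param seed Integer seed for the three rotation angles.
#' @param mask Optional logical matrix marking fruit pixels; if supplied,
#'   the rotation fill value is the median over background pixels only.
#' @return List of 5 `reflectance_cube`s, the first identical to the input.
#' @export
augment_cube <- function(cube, seed = 1L, mask = NULL) {
  stopifnot(inherits(cube, "reflectance_cube"))
  d <- dim(cube$data)
  if (d[1] != d[2]) {
    stop("augment_cube() needs square spatial dims; crop or pad first",
         call. = FALSE)
  }
  if (!is.null(mask)) mask <- as_mask_matrix(mask)
  angles <- withr::with_seed(seed, c(
    stats::runif(1, 0, 30),
    stats::runif(1, 150, 180),
    stats::runif(1, 180, 210)
  ))
  rotated <- lapply(angles, function(a) {
    reflectance_cube(rotate_cube_data(cube$data, a, mask), cube$wavelengths)
  })
  out <- c(list(cube), rotated,
           list(reflectance_cube(mirror_lr_data(cube$data), cube$wavelengths)))
  attr(out, "angles") <- c(0, angles, NA) # NA marks the mirrored copy
  out
}

#' Min-max normalisation of a cube to \[0, 1\]
#'
#' Scales the whole cube by its global minimum and maximum. A constant
#' cube has no range; it maps to all zeros with a warning.
#'
#' @param cube A [reflectance_cube()].
#' @return A [reflectance_cube()] with values in \[0, 1\].
#' @export
normalize_cube <- function(cube) {
  stopifnot(inherits(cube, "reflectance_cube"))
  lo <- min(cube$data); hi <- max(cube$data)
  if (hi == lo) {
    warning("constant cube: normalising to all zeros", call. = FALSE)
    return(reflectance_cube(array(0, dim(cube$data)), cube$wavelengths))
  }
  reflectance_cube((cube$data - lo) / (hi - lo), cube$wavelengths)
}

# Map possibly out-of-range indices into 1..n by mirror reflection
# (border not duplicated: 0 -> 2, n+1 -> n-1).
reflect_index <- function(idx, n) {
  if (n == 1) return(rep(1L, length(idx)))
  period <- 2L * (n - 1L)
  m <- (idx - 1L) %% period
  m <- ifelse(m < 0, m + period, m)
  as.integer(ifelse(m < n, m + 1L, period - m + 1L))
}

#' Crop a cube to a square window centred on the ROI
#'
#' Takes a `size` x `size` window centred on the ROI centroid; indices
#' falling outside the raster are mirror-reflected, so a cube smaller than
#' `size` is reflect-padded up to it. The mask is cropped identically.
#'
#' @param cube A [reflectance_cube()].
#' @param mask An `roi_mask` or logical matrix.
#' @param size Window side in pixels (>= 31 so a spatial patch still fits).
#' @return List with `cube` (cropped [reflectance_cube()]) and `mask`
#'   (cropped logical matrix).
#' @export
crop_to <- function(cube, mask, size = 224L) {
  stopifnot(inherits(cube, "reflectance_cube"))
  if (size < 31) {
    stop("size must be >= 31 (the spatial patch would not fit)",
         call. = FALSE)
  }
  size <- as.integer(size)
  m <- as_mask_matrix(mask)
  if (!any(m)) stop("mask is empty", call. = FALSE)
  cen <- round(c(mean(row(m)[m]), mean(col(m)[m])))
  half <- (size - 1L) %/% 2L
  ridx <- reflect_index(seq(cen[1] - half, length.out = size), nrow(m))
  cidx <- reflect_index(seq(cen[2] - half, length.out = size), ncol(m))
  list(
    cube = reflectance_cube(cube$data[ridx, cidx, , drop = FALSE],
                            cube$wavelengths),
    mask = m[ridx, cidx, drop = FALSE]
  )
}

#' Extract pixel-centred spectral/spatial patch pairs
#'
#' Samples `k_centers` pixels uniformly without replacement from the ROI
#' (all of them if the ROI is smaller) and cuts, for each, a small
#' spectral patch (default 3 x 3 x bands) and a larger spatial patch
#' (default 31 x 31 x bands) sharing that centre pixel. Patches crossing
#' the raster border are mirror-reflect padded. Labels are per fruit, so
#' every pair carries the fruit's `sample_id` and SSC label.
#'
#' @param cube A [reflectance_cube()].
#' @param mask An `roi_mask` or logical matrix.
#' @param k_centers Number of centre pixels to sample (>= 1).
#' @param seed Integer seed for centre sampling.
#' @param sample_id Identifier attached to every pair.
#' @param label SSC label in degrees Brix attached to every pair.
#' @param spectral_size,spatial_size Patch sides (odd).
#' @return An object of class `patch_set`: a list of `patch_pair` objects,
#'   each with `spectral_patch`, `spatial_patch`, `center`, `sample_id`,
#'   `label`.
#' @export
extract_patch_pairs <- function(cube, mask, k_centers, seed = 1L,
                                sample_id = "s1", label = NA_real_,
                                spectral_size = 3L, spatial_size = 31L) {
  stopifnot(inherits(cube, "reflectance_cube"))
  if (k_centers < 1) stop("k_centers must be >= 1", call. = FALSE)
  m <- as_mask_matrix(mask)
  if (!any(m)) stop("mask is empty", call. = FALSE)
  idx <- which(m)
  take <- min(length(idx), as.integer(k_centers))
  chosen <- withr::with_seed(seed, {
    if (take == length(idx)) idx else sample(idx, take)
  })
  nr <- nrow(m)
  pairs <- lapply(chosen, function(i) {
    rc <- c((i - 1L) %% nr + 1L, (i - 1L) %/% nr + 1L)
    structure(
      list(
        spectral_patch = cut_patch(cube$data, rc, spectral_size),
        spatial_patch = cut_patch(cube$data, rc, spatial_size),
        center = rc,
        sample_id = sample_id,
        label = label
      ),
      class = "patch_pair"
    )
  })
  structure(pairs, class = "patch_set")
}

cut_patch <- function(data, center, size) {
  half <- (size - 1L) %/% 2L
  ridx <- reflect_index(seq(center[1] - half, length.out = size), dim(data)[1])
  cidx <- reflect_index(seq(center[2] - half, length.out = size), dim(data)[2])
  data[ridx, cidx, , drop = FALSE]
}

#' @export
print.patch_set <- function(x, ...) {
  d1 <- dim(x[[1]]$spectral_patch); d2 <- dim(x[[1]]$spatial_patch)
  cat("<patch_set> ", length(x), " pairs, spectral ", d1[1], "x", d1[2],
      "x", d1[3], ", spatial ", d2[1], "x", d2[2], "x", d2[3], "\n",
      sep = "")
  invisible(x)
}

#' Combine patch sets
#'
#' @param ... `patch_set` objects.
#' @return A single `patch_set`.
#' @export
c.patch_set <- function(...) {
  structure(NextMethod(), class = "patch_set")
}

# Stack a patch_set into batched arrays for the network:
# spectral [s, s, B, N], spatial [S, S, B, N], plus labels and ids.
stack_patch_pairs <- function(patches) {
  stopifnot(length(patches) >= 1)
  d1 <- dim(patches[[1]]$spectral_patch)
  d2 <- dim(patches[[1]]$spatial_patch)
  n <- length(patches)
  xs <- array(0, c(d1, n))
  xp <- array(0, c(d2, n))
  for (i in seq_len(n)) {
    xs[, , , i] <- patches[[i]]$spectral_patch
    xp[, , , i] <- patches[[i]]$spatial_patch
  }
  list(
    spectral = xs,
    spatial = xp,
    labels = vapply(patches, function(p) p$label, numeric(1)),
    sample_ids = vapply(patches, function(p) p$sample_id, character(1))
  )
}
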