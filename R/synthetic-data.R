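#' Parameters of the synthetic hyperspectral scene generator
#'
#' Describes the statistical structure of a simulated benchtop acquisition:
#' an approximately circular bright fruit on a dark background, smooth
#' reflectance baselines with absorption features whose depth grows
#' linearly with the latent soluble-solids content (SSC), a multiplicative
#' illumination field, and additive sensor noise, digitised through a
#' white/black reference model so that reflectance calibration is
#' non-trivial.
#'
#' The default SSC distribution (mean 11.76, SD 1.92, range 7.2-18.1
#' degrees Brix) matches the reference statistics of a 570-apple 'Fuji'
#' SSC survey; the default raster is desk-scale (64 x 64 x 32) rather than
#' full sensor scale, which exercises the same arithmetic at a fraction of
#' the cost.
#'
#' @param n_rows,n_cols Spatial size in pixels.
#' @param n_bands Number of spectral bands (>= 8).
#' @param wavelength_min,wavelength_max Spectral range in nm.
#' @param fruit_radius_frac Fruit disk radius as a fraction of
#'   `min(n_rows, n_cols)`; must be in (0, 0.5).
#' @param informative_bands Band centres (nm) where absorption depth is
#'   linear in SSC; all must lie inside the wavelength range.
#' @param absorption_slope Absorption depth per degree Brix (reflectance
#'   units), applied as `absorption_slope * (ssc - ssc_min)`.
#' @param baseline_smoothness Correlation length, in bands, of the smooth
#'   per-sample baseline perturbation.
#' @param illumination_cv Coefficient of variation of the multiplicative
#'   illumination field (spectrally flat, spatially smooth).
#' @param noise_sd Additive sensor noise SD in reflectance units.
#' @param ssc_mean,ssc_sd,ssc_min,ssc_max SSC distribution in degrees
#'   Brix: Normal(ssc_mean, ssc_sd^2) rejection-clipped to
#'   `[ssc_min, ssc_max]`.
#' @param seed Integer seed used by generators that derive per-sample seeds.
#' @return An object of class `scene_params` (a validated list).
#' @export
scene_params <- function(n_rows = 64L, n_cols = 64L, n_bands = 32L,
                         wavelength_min = 400, wavelength_max = 1000,
                         fruit_radius_frac = 0.35,
                         informative_bands = c(680, 880, 960),
                         absorption_slope = 0.02,
                         baseline_smoothness = 4,
                         illumination_cv = 0.05,
                         noise_sd = 0.01,
                         ssc_mean = 11.76, ssc_sd = 1.92,
                         ssc_min = 7.2, ssc_max = 18.1,
                         seed = 1L) {
  p <- list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    n_bands = as.integer(n_bands),
    wavelength_min = wavelength_min, wavelength_max = wavelength_max,
    fruit_radius_frac = fruit_radius_frac,
    informative_bands = informative_bands,
    absorption_slope = absorption_slope,
    baseline_smoothness = baseline_smoothness,
    illumination_cv = illumination_cv,
    noise_sd = noise_sd,
    ssc_mean = ssc_mean, ssc_sd = ssc_sd,
    ssc_min = ssc_min, ssc_max = ssc_max,
    seed = as.integer(seed)
  )
  if (p$n_bands < 8) stop("n_bands must be >= 8", call. = FALSE)
  if (p$fruit_radius_frac <= 0 || p$fruit_radius_frac >= 0.5) {
    stop("fruit_radius_frac must be in (0, 0.5)", call. = FALSE)
  }
  if (!(p$ssc_min <= p$ssc_mean && p$ssc_mean <= p$ssc_max) ||
      p$ssc_min >= p$ssc_max) {
    stop("need ssc_min < ssc_mean < ssc_max (or ssc_mean at a bound with ",
         "ssc_min < ssc_max)", call. = FALSE)
  }
  if (any(p$informative_bands < p$wavelength_min |
          p$informative_bands > p$wavelength_max)) {
    stop("every informative band must lie within [",
         p$wavelength_min, ", ", p$wavelength_max, "] nm", call. = FALSE)
  }
  structure(p, class = "scene_params")
}

#' @export
print.scene_params <- function(x, ...) {
  cat("<scene_params> ", x$n_rows, "x", x$n_cols, "x", x$n_bands,
      " (", x$wavelength_min, "-", x$wavelength_max, " nm), SSC ~ N(",
      x$ssc_mean, ", ", x$ssc_sd, "^2) in [", x$ssc_min, ", ", x$ssc_max,
      "] Brix\n", sep = "")
  invisible(x)
}

#' Draw SSC reference values
#'
#' Samples `n` latent SSC values from Normal(ssc_mean, ssc_sd^2),
#' rejection-clipped to `[ssc_min, ssc_max]` (out-of-range draws are
#' redrawn, so the bounds truncate rather than pile up mass at the edges).
#'
#' @param params A [scene_params()] object.
#' @param n Number of samples (>= 1).
#' @param seed Integer seed; defaults to `params$seed`.
#' @return Numeric vector of length `n`, degrees Brix.
#' @export
sample_ssc <- function(params, n, seed = params$seed) {
  stopifnot(inherits(params, "scene_params"))
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("n must be a positive integer", call. = FALSE)
  }
  n <- as.integer(n)
  withr::with_seed(seed, {
    if (params$ssc_sd == 0) {
      rep(params$ssc_mean, n)
    } else {
      out <- numeric(0)
      while (length(out) < n) {
        draw <- stats::rnorm(n, params$ssc_mean, params$ssc_sd)
        out <- c(out, draw[draw >= params$ssc_min & draw <= params$ssc_max])
      }
      out[seq_len(n)]
    }
  })
}

# Gaussian profile in wavelength, unit peak
gauss_profile <- function(wl, center, sd) exp(-0.5 * ((wl - center) / sd)^2)

# Smooth a white-noise vector to the given correlation length (in samples)
# and rescale to unit SD; returns zeros for zero-variance input.
smooth_noise_1d <- function(z, corlen) {
  if (corlen <= 0) return(z)
  half <- max(1L, min(ceiling(3 * corlen), length(z) - 1L))
  k <- exp(-0.5 * ((-half:half) / corlen)^2)
  k <- k / sum(k)
  zp <- c(rev(z[seq_len(half)]), z, z[length(z) - seq_len(half) + 1])
  s <- stats::filter(zp, k, sides = 2)[half + seq_along(z)]
  s <- as.numeric(s)
  if (stats::sd(s) > 0) s / stats::sd(s) else s
}

# Smooth, unit-SD random field on an n_rows x n_cols grid (separable
# Gaussian smoothing of white noise).
smooth_field_2d <- function(n_rows, n_cols, corlen) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  zs <- apply(z, 2, smooth_noise_1d, corlen = corlen)
  zs <- t(apply(zs, 1, smooth_noise_1d, corlen = corlen))
  if (stats::sd(zs) > 0) zs / stats::sd(zs) else zs
}

# Fruit reflectance spectrum for one sample: broad-Gaussian baseline with
# random amplitudes, a smooth per-sample perturbation, minus SSC-dependent
# absorption dips (FWHM ~ 30 nm) at the informative bands.
fruit_spectrum <- function(params, ssc, wl) {
  a_green <- stats::runif(1, 0.02, 0.06)
  a_red   <- stats::runif(1, 0.30, 0.45)
  a_nir   <- stats::runif(1, 0.15, 0.30)
  base <- 0.18 +
    a_green * gauss_profile(wl, 560, 60) +
    a_red   * gauss_profile(wl, 760, 90) +
    a_nir   * gauss_profile(wl, 950, 120)
  pert <- 0.01 * smooth_noise_1d(stats::rnorm(length(wl)),
                                 params$baseline_smoothness)
  depth <- params$absorption_slope * (ssc - params$ssc_min)
  dip_sd <- 30 / (2 * sqrt(2 * log(2))) # FWHM 30 nm
  dips <- rowSums(vapply(params$informative_bands,
                         function(b) gauss_profile(wl, b, dip_sd),
                         numeric(length(wl))))
  pmax(base + pert - depth * dips, 0.02)
}

#' Generate one labelled synthetic cube
#'
#' Builds a raw count cube together with its white and black reference
#' cubes and the ground-truth fruit mask. The scene is a centred disk of
#' fruit spectrum on a flat dark background (reflectance 0.05), modulated
#' by a smooth multiplicative illumination field, digitised as
#' `counts = dark + reflectance * illumination * gain` plus additive
#' Gaussian noise. The white reference is a flat 0.999 reflector under
#' nominal illumination, the black reference is the dark level; both are
#' frame-averaged (noise-free) as in routine practice. The fruit spectrum
#' is constructed so that the 715/525 nm band ratio exceeds the masking
#' threshold on the fruit and stays near 1 on the background, and so that
#' calibrated fruit reflectance at each informative band decreases
#' strictly with SSC.
#'
#' @param params A [scene_params()] object.
#' @param ssc SSC value in degrees Brix, within `[ssc_min, ssc_max]`.
#' @param seed Integer seed for this cube's randomness.
#' @return An object of class `labeled_cube`: list with `raw`, `white_ref`,
#'   `black_ref` (rows x cols x bands count arrays), `wavelengths` (nm),
#'   `ssc`, `truth_mask` (logical rows x cols).
#' @export
generate_cube <- function(params, ssc, seed = params$seed) {
  stopifnot(inherits(params, "scene_params"))
  if (ssc < params$ssc_min || ssc > params$ssc_max) {
    stop("ssc = ", ssc, " outside [", params$ssc_min, ", ",
         params$ssc_max, "] Brix", call. = FALSE)
  }
  nr <- params$n_rows; nc <- params$n_cols; nb <- params$n_bands
  wl <- seq(params$wavelength_min, params$wavelength_max, length.out = nb)
  gain <- 4000; dark <- 100; white_refl <- 0.999

  withr::with_seed(seed, {
    spec_fruit <- fruit_spectrum(params, ssc, wl)
    spec_bg <- rep(0.05, nb)

    cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
    radius <- params$fruit_radius_frac * min(nr, nc)
    rowg <- matrix(seq_len(nr), nr, nc)
    colg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    mask <- (rowg - cr)^2 + (colg - cc)^2 <= radius^2

    illum <- matrix(1, nr, nc)
    if (params$illumination_cv > 0) {
      illum <- 1 + params$illumination_cv *
        smooth_field_2d(nr, nc, min(nr, nc) / 8)
      illum <- pmax(illum, 0.2)
    }

    refl <- array(rep(spec_bg, each = nr * nc), dim = c(nr, nc, nb))
    fruit_idx <- which(mask)
    for (b in seq_len(nb)) {
      plane <- refl[, , b]
      plane[fruit_idx] <- spec_fruit[b]
      refl[, , b] <- plane * illum
    }

    raw <- dark + refl * gain
    if (params$noise_sd > 0) {
      raw <- raw + stats::rnorm(length(raw), 0, params$noise_sd * gain)
    }
    white <- array(dark + white_refl * gain, dim = c(nr, nc, nb))
    black <- array(dark, dim = c(nr, nc, nb))

    structure(
      list(raw = raw, white_ref = white, black_ref = black,
           wavelengths = wl, ssc = ssc, truth_mask = mask),
      class = "labeled_cube"
    )
  })
}

#' @export
print.labeled_cube <- function(x, ...) {
  d <- dim(x$raw)
  cat("<labeled_cube> ", d[1], "x", d[2], "x", d[3], ", SSC ",
      round(x$ssc, 2), " Brix, fruit pixels ", sum(x$truth_mask),
      "\n", sep = "")
  invisible(x)
}

#' Generate a labelled synthetic dataset
#'
#' Draws `n` SSC values, generates one cube per value with an independent
#' derived seed, and assigns a 5:1 calibration/prediction split at the
#' fruit level.
#'
#' @param params A [scene_params()] object.
#' @param n Number of cubes (>= 2).
#' @param seed Master seed; per-cube seeds are derived from it.
#' @return A list with `cubes` (list of [generate_cube()] results) and
#'   `labels`, a tibble with columns `sample_id`, `ssc_brix`, `split`.
#' @export
generate_dataset <- function(params, n, seed = params$seed) {
  stopifnot(inherits(params, "scene_params"))
  if (!is.numeric(n) || length(n) != 1 || n < 2) {
    stop("n must be >= 2", call. = FALSE)
  }
  n <- as.integer(n)
  ssc <- sample_ssc(params, n, seed = seed)
  cube_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  cubes <- purrr::map2(ssc, cube_seeds,
                       function(s, sd) generate_cube(params, s, seed = sd))
  ids <- sprintf("s%04d", seq_len(n))
  plan <- split_samples(ids, ratio = c(5, 1), seed = seed)
  labels <- tibble::tibble(
    sample_id = ids,
    ssc_brix = ssc,
    split = ifelse(ids %in% plan$calibration_ids, "calibration", "prediction")
  )
  names(cubes) <- ids
  list(cubes = cubes, labels = labels)
}
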