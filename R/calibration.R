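## Grey-card calibration of hyperspectral cubes: dark correction, between-day
## gain, conversion to relative reflectance, and Gaussian spectral smoothing.

#' Subtract the sensor dark frame from a cube
#'
#' Per-band dark offsets are subtracted from every pixel and the result is
#' clipped at zero. A cube without a dark frame passes through unchanged with
#' a warning (many line-scan cameras subtract dark noise at acquisition).
#'
#' @param cube A [spectral_cube()].
#' @return The dark-corrected cube; masks and grid unchanged.
#' @export
dark_correct <- function(cube) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (is.null(cube$dark_frame)) {
    warnf("cube '%s' has no dark frame; returning it unchanged",
          cube$specimen_id)
    return(cube)
  }
  corrected <- sweep(cube$pixels, 2L, cube$dark_frame, "-")
  cube$pixels <- pmax(corrected, 0)
  cube$dark_frame <- NULL
  cube
}

#' Average grey-card spectrum of a cube
#'
#' Per-band arithmetic mean over the pixels in the `grey_card` mask: the
#' image's record of the scene illumination via the 18% reference card.
#'
#' @param cube A [spectral_cube()].
#' @param mask_name Name of the grey-card mask. Default `"grey_card"`.
#' @return A `grey_card_profile`: wavelengths, mean spectrum, day label.
#' @export
grey_card_profile <- function(cube, mask_name = "grey_card") {
  stopifnot(inherits(cube, "spectral_cube"))
  idx <- cube$masks[[mask_name]]
  if (is.null(idx) || length(idx) == 0L) {
    stopf("cube '%s' has no pixels in mask '%s'", cube$specimen_id, mask_name)
  }
  m <- colMeans(cube$pixels[idx, , drop = FALSE])
  if (any(m <= 0)) {
    stopf("grey-card profile of '%s' is non-positive at %d band(s); cannot calibrate",
          cube$specimen_id, sum(m <= 0))
  }
  structure(list(wavelengths = cube$wavelengths, mean_spectrum = m,
                 day = cube$day),
            class = "grey_card_profile")
}

#' Between-day illumination gain from two grey-card profiles
#'
#' Element-wise division of the reference-day card profile by the target-day
#' profile, averaged over bands, gives a single multiplicative gain that maps
#' target-day signal onto the reference day's illumination.
#'
#' @param reference Card profile of the reference day.
#' @param target Card profile of the day to correct.
#' @return A positive scalar gain.
#' @export
compute_gain <- function(reference, target) {
  stopifnot(inherits(reference, "grey_card_profile"),
            inherits(target, "grey_card_profile"))
  if (length(reference$wavelengths) != length(target$wavelengths) ||
      any(abs(reference$wavelengths - target$wavelengths) > 1e-9)) {
    stopf("reference and target profiles are on different wavelength grids")
  }
  if (any(target$mean_spectrum <= 0)) {
    stopf("target card profile has non-positive bands; gain undefined")
  }
  mean(reference$mean_spectrum / target$mean_spectrum)
}

#' Apply a multiplicative gain to every pixel of a cube
#'
#' @param cube A [spectral_cube()].
#' @param gain Positive scalar from [compute_gain()].
#' @return The rescaled cube.
#' @export
apply_gain <- function(cube, gain) {
  stopifnot(inherits(cube, "spectral_cube"))
  assert_scalar_pos(gain, "gain")
  cube$pixels <- cube$pixels * gain
  cube
}

#' Convert a cube to relative reflectance against its grey card
#'
#' Each pixel band is divided by the card's mean spectrum at that band and
#' rescaled by the card's nominal reflectance, so a pixel spectrally identical
#' to the card maps to a flat spectrum at `card_reflectance`. With
#' `card_reflectance = 1` this is plain card-relative normalisation.
#'
#' @param cube A [spectral_cube()].
#' @param card A `grey_card_profile` on the same grid.
#' @param card_reflectance Nominal card reflectance; default 0.18 (an 18%
#'   photographic grey card).
#' @return The cube in relative-reflectance units.
#' @export
to_relative_reflectance <- function(cube, card, card_reflectance = 0.18) {
  stopifnot(inherits(cube, "spectral_cube"),
            inherits(card, "grey_card_profile"))
  assert_scalar_pos(card_reflectance, "card_reflectance")
  if (length(cube$wavelengths) != length(card$wavelengths) ||
      any(abs(cube$wavelengths - card$wavelengths) > 1e-9)) {
    stopf("cube and card profile are on different wavelength grids")
  }
  cube$pixels <- sweep(cube$pixels, 2L, card$mean_spectrum / card_reflectance,
                       "/")
  cube
}

## Discrete Gaussian kernel: weights proportional to exp(-k^2 / (2 sigma^2))
## at integer offsets, renormalised to sum 1.
gaussian_kernel <- function(kernel_length = 9L, sigma = 1.6) {
  if (kernel_length %% 2L != 1L) stopf("kernel length must be odd")
  assert_scalar_pos(sigma, "sigma")
  k <- seq.int(-(kernel_length %/% 2L), kernel_length %/% 2L)
  w <- exp(-k^2 / (2 * sigma^2))
  w / sum(w)
}

#' Gaussian smoothing of pixel spectra along the wavelength axis
#'
#' Each spectrum (row) is convolved with a discrete Gaussian kernel
#' (default: 9 taps, sigma 1.6 samples), normalised to sum 1 so constant
#' spectra are preserved. Boundaries use reflect padding: the spectrum is
#' mirrored about its end samples without repeating them, which avoids
#' darkening at the 330 and 800 nm extremes.
#'
#' @param x A [pixel_spectra()] object or a pixels-x-bands matrix.
#' @param kernel_length Odd number of kernel taps, at most the band count.
#' @param sigma Kernel standard deviation in band-index units.
#' @return Object of the same type as `x`, smoothed.
#' @export
smooth_spectra <- function(x, kernel_length = 9L, sigma = 1.6) {
  m <- as_spectra_matrix(x)
  nb <- ncol(m)
  if (kernel_length > nb) {
    stopf("kernel length %d exceeds the %d-band spectrum", kernel_length, nb)
  }
  w <- gaussian_kernel(kernel_length, sigma)
  half <- kernel_length %/% 2L
  out <- matrix(0, nrow(m), nb)
  for (j in seq_along(w)) {
    k <- j - half - 1L            # offset -half..half
    cols <- seq_len(nb) + k
    cols <- ifelse(cols < 1L, 2L - cols, cols)       # mirror, edge not doubled
    cols <- ifelse(cols > nb, 2L * nb - cols, cols)
    out <- out + w[j] * m[, cols, drop = FALSE]
  }
  if (inherits(x, "pixel_spectra")) {
    x$spectra <- out
    x
  } else {
    out
  }
}

#' Stack masked pixels from several cubes into one spectra table
#'
#' @param cubes List of [spectral_cube()] objects on a shared grid.
#' @param mask_name Mask to extract (default `"specimen"`).
#' @return A [pixel_spectra()] with per-row specimen/day provenance.
#' @export
extract_masked_pixels <- function(cubes, mask_name = "specimen") {
  if (inherits(cubes, "spectral_cube")) cubes <- list(cubes)
  if (!length(cubes)) stopf("no cubes supplied")
  grid <- cubes[[1L]]$wavelengths
  rows <- list()
  prov <- list()
  for (cube in cubes) {
    if (length(cube$wavelengths) != length(grid) ||
        any(abs(cube$wavelengths - grid) > 1e-9)) {
      stopf("cube '%s' is on a different wavelength grid", cube$specimen_id)
    }
    idx <- cube$masks[[mask_name]]
    if (is.null(idx) || length(idx) == 0L) {
      stopf("cube '%s' has no mask '%s'", cube$specimen_id, mask_name)
    }
    rows[[length(rows) + 1L]] <- cube$pixels[idx, , drop = FALSE]
    prov[[length(prov) + 1L]] <- data.frame(
      specimen = rep(cube$specimen_id, length(idx)),
      day = rep(cube$day, length(idx)))
  }
  pixel_spectra(grid, do.call(rbind, rows), do.call(rbind, prov))
}

#' Full grey-card calibration of a set of cubes
#'
#' Runs the calibration chain over cubes from one or more acquisition days:
#' optional dark correction, a single between-day gain per non-reference day
#' (card profiles averaged within day), conversion to relative reflectance
#' against each cube's own card, masked-pixel extraction, and Gaussian
#' spectral smoothing.
#'
#' @param cubes List of [spectral_cube()] objects.
#' @param reference_day Day label used as the illumination reference; default
#'   the day of the first cube.
#' @param card_reflectance Nominal grey-card reflectance (default 0.18).
#' @param kernel_length,sigma Smoothing parameters, see [smooth_spectra()].
#' @param mask_name Pixel mask to retain (default `"specimen"`).
#' @param dark Apply [dark_correct()] to cubes that carry a dark frame.
#' @return A [pixel_spectra()] of calibrated, smoothed spectra. The computed
#'   per-day gains are attached as attribute `"gains"`.
#' @export
calibrate_cubes <- function(cubes, reference_day = NULL,
                            card_reflectance = 0.18, kernel_length = 9L,
                            sigma = 1.6, mask_name = "specimen", dark = TRUE) {
  if (inherits(cubes, "spectral_cube")) cubes <- list(cubes)
  if (dark) {
    cubes <- lapply(cubes, function(cb) {
      if (is.null(cb$dark_frame)) cb else dark_correct(cb)
    })
  }
  days <- vapply(cubes, function(cb) cb$day, character(1))
  reference_day <- reference_day %||% days[[1L]]
  if (!reference_day %in% days) {
    stopf("reference day '%s' matches no cube", reference_day)
  }
  day_profile <- function(day) {
    profs <- lapply(cubes[days == day], grey_card_profile)
    p <- profs[[1L]]
    p$mean_spectrum <- rowMeans(vapply(profs, `[[`, p$mean_spectrum,
                                       "mean_spectrum"))
    p$day <- day
    p
  }
  ref_profile <- day_profile(reference_day)
  gains <- setNames(rep(1, length(unique(days))), unique(days))
  for (day in setdiff(unique(days), reference_day)) {
    gains[[day]] <- compute_gain(ref_profile, day_profile(day))
  }
  cubes <- lapply(cubes, function(cb) apply_gain(cb, gains[[cb$day]]))
  ## after gain correction all days share the reference illumination, so one
  ## card profile (the reference day's average) references every cube
  cubes <- lapply(cubes, function(cb) {
    to_relative_reflectance(cb, ref_profile, card_reflectance)
  })
  spectra <- extract_masked_pixels(cubes, mask_name)
  spectra <- smooth_spectra(spectra, kernel_length, sigma)
  attr(spectra, "gains") <- gains
  spectra
}
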