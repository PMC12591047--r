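## Tetrachromatic visual systems: cone sensitivity curves from the
## Govardovskii A1 visual-pigment nomogram (alpha + beta bands), unit-area
## normalisation, and the built-in avian and lacertid receivers.

#' Cone sensitivity curve from the A1 visual-pigment nomogram
#'
#' Generates an absorbance spectrum from the peak wavelength alone using the
#' A1 template: an alpha band
#' `S_a(l) = 1 / (exp(A(a-x)) + exp(B(b-x)) + exp(C(c-x)) + D)` with
#' `x = lambda_max / lambda`, constants `A = 69.7`, `B = 28`, `C = -14.9`,
#' `D = 0.674`, `b = 0.922`, `c = 1.104` and
#' `a = 0.8795 + 0.0459 exp(-(lambda_max - 300)^2 / 11940)`, plus a beta band
#' `S_b(l) = 0.26 exp(-((l - l_mb)/b_b)^2)` with
#' `l_mb = 189 + 0.315 lambda_max` and `b_b = -40.5 + 0.195 lambda_max`.
#' The returned curve is un-normalised (peak near 1).
#'
#' @param lambda_max Peak wavelength in nm, within [330, 800].
#' @param wavelengths Band centres the curve is evaluated on.
#' @param channel Channel label (`"UVS"`, `"SWS"`, `"MWS"`, `"LWS"` or other).
#' @return A `cone_sensitivity`: wavelengths, curve, `lambda_max`, `channel`.
#' @export
pigment_template <- function(lambda_max, wavelengths, channel = "custom") {
  w <- wavelength_grid(wavelengths)
  if (lambda_max < 330 || lambda_max > 800) {
    stopf("lambda_max must lie within [330, 800] nm")
  }
  if (lambda_max < min(w) || lambda_max > max(w)) {
    warnf("lambda_max %g nm is outside the grid [%g, %g]; curve is truncated",
          lambda_max, min(w), max(w))
  }
  x <- lambda_max / w
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  s_alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                    exp(-14.9 * (1.104 - x)) + 0.674)
  l_mb <- 189 + 0.315 * lambda_max
  b_b <- -40.5 + 0.195 * lambda_max
  s_beta <- 0.26 * exp(-((w - l_mb) / b_b)^2)
  structure(list(wavelengths = w, curve = s_alpha + s_beta,
                 lambda_max = lambda_max, channel = channel),
            class = "cone_sensitivity")
}

#' Normalise a cone sensitivity curve to unit area
#'
#' Divides the curve by its trapezoidal integral over the grid, so every
#' receptor integrates the same total sensitivity and quantum catches of a
#' flat unit spectrum are 1 in every channel.
#'
#' @param cone A `cone_sensitivity`.
#' @return The cone with unit trapezoidal area.
#' @export
unit_area_normalise <- function(cone) {
  stopifnot(inherits(cone, "cone_sensitivity"))
  area <- pracma::trapz(cone$wavelengths, cone$curve)
  if (area <= 0) stopf("cone curve has non-positive area; cannot normalise")
  cone$curve <- cone$curve / area
  cone
}

new_visual_system <- function(name, cones, densities, weber) {
  stopifnot(length(cones) == 4L, length(densities) == 4L)
  if (any(densities <= 0)) stopf("cone densities must be positive")
  assert_scalar_pos(weber, "weber")
  grid <- cones[[1L]]$wavelengths
  for (cn in cones) {
    if (length(cn$wavelengths) != length(grid) ||
        any(abs(cn$wavelengths - grid) > 1e-9)) {
      stopf("all cones of a visual system must share one wavelength grid")
    }
  }
  structure(list(name = name, cones = cones,
                 densities = as.numeric(densities), weber = weber,
                 wavelengths = grid),
            class = "visual_system")
}

#' @export
print.visual_system <- function(x, ...) {
  peaks <- vapply(x$cones, `[[`, numeric(1), "lambda_max")
  cat(sprintf("<visual_system> %s: peaks %s nm, densities %s, Weber %.3g\n",
              x$name, paste(peaks, collapse = "/"),
              paste(x$densities, collapse = ":"), x$weber))
  invisible(x)
}

#' Lacertid (reptile) tetrachromatic visual system
#'
#' Template cones at peak sensitivities 362, 447, 492 and 586 nm (UVS, SWS,
#' MWS, LWS — lacertid values measured in wall and viviparous lizards), unit
#' area each, with relative cone densities 1:2:6:6.
#'
#' @param wavelengths Band centres; must span the 330--800 nm working range.
#' @param weber Weber fraction of the long-wave reference cone (default 0.1).
#' @return A `visual_system`.
#' @export
build_reptile_system <- function(wavelengths, weber = 0.1) {
  peaks <- c(362, 447, 492, 586)
  channels <- c("UVS", "SWS", "MWS", "LWS")
  cones <- Map(function(p, ch) {
    unit_area_normalise(pigment_template(p, wavelengths, ch))
  }, peaks, channels)
  new_visual_system("reptile", unname(cones), c(1, 2, 6, 6), weber)
}

#' Average UV-type avian tetrachromatic visual system
#'
#' Template cones at the conventional average ultraviolet-sensitive avian
#' peaks (372, 456, 544, 609 nm), truncated to the working grid and
#' unit-area normalised there, with relative cone densities 1:2:4:3. Users
#' with measured sensitivity spectra can build an equivalent system from a
#' CSV via [read_visual_system_csv()].
#'
#' @inheritParams build_reptile_system
#' @return A `visual_system`.
#' @export
build_avian_system <- function(wavelengths, weber = 0.1) {
  peaks <- c(372, 456, 544, 609)
  channels <- c("UVS", "SWS", "MWS", "LWS")
  cones <- Map(function(p, ch) {
    unit_area_normalise(pigment_template(p, wavelengths, ch))
  }, peaks, channels)
  new_visual_system("avian", unname(cones), c(1, 2, 4, 3), weber)
}

#' Build a visual system from measured sensitivity curves
#'
#' Reads a CSV with a `wavelength` column followed by four cone sensitivity
#' columns ordered UVS, SWS, MWS, LWS; curves are interpolated onto the
#' requested grid and unit-area normalised.
#'
#' @param path CSV path.
#' @param wavelengths Target grid; default the file's own wavelengths.
#' @param densities Relative cone densities (UVS, SWS, MWS, LWS).
#' @param weber Weber fraction of the reference cone.
#' @param name System name.
#' @return A `visual_system`.
#' @export
read_visual_system_csv <- function(path, wavelengths = NULL,
                                   densities = c(1, 2, 4, 3), weber = 0.1,
                                   name = "custom") {
  tab <- read.csv(path)
  if (ncol(tab) < 5L) stopf("sensitivity CSV needs wavelength + 4 cone columns")
  w <- wavelengths %||% tab[[1L]]
  w <- wavelength_grid(w)
  channels <- c("UVS", "SWS", "MWS", "LWS")
  cones <- lapply(1:4, function(i) {
    curve <- stats::approx(tab[[1L]], tab[[i + 1L]], xout = w, rule = 2)$y
    curve <- pmax(curve, 0)
    cone <- structure(list(wavelengths = w, curve = curve,
                           lambda_max = w[which.max(curve)],
                           channel = channels[i]),
                      class = "cone_sensitivity")
    unit_area_normalise(cone)
  })
  new_visual_system(name, cones, densities, weber)
}
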