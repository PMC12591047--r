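## Containers for hyperspectral line-scan data: a cube is a pixels x bands
## matrix of reflectance on a shared wavelength grid, with named pixel-index
## masks (e.g. "specimen", "grey_card") and an acquisition-day tag.

#' Validate a wavelength grid
#'
#' Band centres must be strictly increasing, lie within the 330--800 nm range
#' of a near-UV--VIS line-scan camera, and provide at least 9 bands (the
#' length of the default spectral smoothing kernel).
#'
#' @param wavelengths Numeric vector of band centres in nm.
#' @return The validated wavelength vector, invisibly usable downstream.
#' @export
wavelength_grid <- function(wavelengths) {
  w <- as.numeric(wavelengths)
  if (length(w) < 9L) {
    stopf("wavelength grid needs at least 9 bands, got %d", length(w))
  }
  if (any(!is.finite(w))) stopf("wavelength grid contains non-finite values")
  if (any(w < 330 - 1e-9) || any(w > 800 + 1e-9)) {
    stopf("wavelength grid must lie within [330, 800] nm")
  }
  if (any(diff(w) <= 0)) stopf("wavelength grid must be strictly increasing")
  w
}

#' Construct a hyperspectral cube
#'
#' @param wavelengths Band centres in nm (see [wavelength_grid()]).
#' @param pixels Numeric matrix, one row per pixel, one column per band;
#'   reflectance values, finite and non-negative.
#' @param masks Named list of integer pixel-index vectors (1-based). Typical
#'   names: `"specimen"`, `"grey_card"`.
#' @param day Acquisition-day label (e.g. `"day1"`).
#' @param specimen_id Specimen identifier.
#' @param dark_frame Optional per-band sensor offset to subtract (see
#'   [dark_correct()]).
#' @return An object of class `spectral_cube`.
#' @export
spectral_cube <- function(wavelengths, pixels, masks = list(), day = "day1",
                          specimen_id = "specimen", dark_frame = NULL) {
  w <- wavelength_grid(wavelengths)
  pixels <- as.matrix(pixels)
  if (ncol(pixels) != length(w)) {
    stopf("pixels has %d columns but the grid has %d bands",
          ncol(pixels), length(w))
  }
  if (any(!is.finite(pixels))) stopf("pixel values must be finite")
  if (!is.list(masks)) stopf("`masks` must be a named list of index vectors")
  for (nm in names(masks)) {
    idx <- as.integer(masks[[nm]])
    if (length(idx) && (min(idx) < 1L || max(idx) > nrow(pixels))) {
      stopf("mask '%s' indexes pixels outside 1..%d", nm, nrow(pixels))
    }
    masks[[nm]] <- idx
  }
  if (!is.null(dark_frame)) {
    dark_frame <- as.numeric(dark_frame)
    if (length(dark_frame) != length(w)) {
      stopf("dark frame length %d does not match the %d-band grid",
            length(dark_frame), length(w))
    }
  }
  structure(
    list(wavelengths = w, pixels = pixels, masks = masks,
         day = as.character(day), specimen_id = as.character(specimen_id),
         dark_frame = dark_frame),
    class = "spectral_cube"
  )
}

#' @export
print.spectral_cube <- function(x, ...) {
  cat(sprintf("<spectral_cube> %s (%s): %d pixels x %d bands [%g-%g nm]\n",
              x$specimen_id, x$day, nrow(x$pixels), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  if (length(x$masks)) {
    cat("  masks:",
        paste(sprintf("%s (%d px)", names(x$masks), lengths(x$masks)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Calibrated pixel spectra with per-row provenance
#'
#' Holds row-stacked pixel spectra together with a provenance table (specimen
#' and day per row). Clustering consumes the spectra matrix only, so the
#' pixels are effectively anonymised; provenance is re-joined downstream when
#' summarising per-specimen cluster frequencies.
#'
#' @param wavelengths Band centres in nm.
#' @param spectra Numeric matrix, pixels x bands.
#' @param provenance Data frame with columns `specimen` and `day`, one row per
#'   pixel row.
#' @return An object of class `pixel_spectra`.
#' @export
pixel_spectra <- function(wavelengths, spectra, provenance = NULL) {
  w <- wavelength_grid(wavelengths)
  spectra <- as.matrix(spectra)
  if (ncol(spectra) != length(w)) stopf("spectra/grid band mismatch")
  if (any(!is.finite(spectra))) stopf("spectra must be finite")
  if (is.null(provenance)) {
    provenance <- data.frame(specimen = rep(NA_character_, nrow(spectra)),
                             day = rep(NA_character_, nrow(spectra)))
  }
  if (nrow(provenance) != nrow(spectra)) {
    stopf("provenance has %d rows for %d spectra", nrow(provenance),
          nrow(spectra))
  }
  structure(list(wavelengths = w, spectra = spectra,
                 provenance = provenance),
            class = "pixel_spectra")
}

#' @export
print.pixel_spectra <- function(x, ...) {
  cat(sprintf("<pixel_spectra> %d pixels x %d bands, %d specimen(s)\n",
              nrow(x$spectra), ncol(x$spectra),
              length(unique(x$provenance$specimen))))
  invisible(x)
}

## Accept a pixel_spectra object or a plain matrix wherever only the numeric
## spectra are needed (generic clustering works on any n x d matrix).
as_spectra_matrix <- function(x) {
  if (inherits(x, "pixel_spectra")) return(x$spectra)
  as.matrix(x)
}

# ---- portable cube directory I/O --------------------------------------------

#' Write a cube to a portable directory layout
#'
#' The layout is plain text: `bands.csv` (wavelengths), `pixels.csv`
#' (pixels x bands), `masks.json` (name to 1-based index list) and
#' `meta.json` (day, specimen id, optional dark frame).
#'
#' @param cube A [spectral_cube()].
#' @param path Directory to create/write.
#' @return `path`, invisibly.
#' @export
write_cube_dir <- function(cube, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write.csv(data.frame(wavelength = cube$wavelengths),
            file.path(path, "bands.csv"), row.names = FALSE)
  write.csv(as.data.frame(cube$pixels), file.path(path, "pixels.csv"),
            row.names = FALSE)
  jsonlite::write_json(cube$masks, file.path(path, "masks.json"))
  meta <- list(day = cube$day, specimen_id = cube$specimen_id)
  if (!is.null(cube$dark_frame)) meta$dark_frame <- cube$dark_frame
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cube from a portable directory layout
#'
#' @param path Directory written by [write_cube_dir()] (or assembled by hand
#'   from exported text files).
#' @return A [spectral_cube()].
#' @export
read_cube_dir <- function(path) {
  bands <- read.csv(file.path(path, "bands.csv"))
  pixels <- as.matrix(read.csv(file.path(path, "pixels.csv")))
  masks <- lapply(jsonlite::read_json(file.path(path, "masks.json")),
                  function(v) as.integer(unlist(v)))
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  spectral_cube(bands$wavelength, pixels, masks,
                day = meta$day %||% "day1",
                specimen_id = meta$specimen_id %||% basename(path),
                dark_frame = meta$dark_frame)
}
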