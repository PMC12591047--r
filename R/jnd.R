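## Receptor-noise-limited colour discrimination: quantum catches, channel
## noise from relative cone densities, and noise-weighted (JND) distances.

#' Quantum catches of a reflectance spectrum
#'
#' Photon catch of each receptor: the trapezoidal integral of cone
#' sensitivity x reflectance x illuminant over the wavelength grid. With
#' unit-area cones and a flat unit illuminant, a flat unit reflectance gives
#' a catch of exactly 1 in every channel.
#'
#' @param system A `visual_system`.
#' @param spectrum Per-band reflectance on the system's grid; non-negative.
#' @param illuminant Per-band irradiance; default flat (ideal) illuminant.
#' @param spectrum_id Label carried into results.
#' @return A `quantum_catches`: positive catch vector `q` (UVS, SWS, MWS,
#'   LWS) and `spectrum_id`.
#' @export
quantum_catches <- function(system, spectrum, illuminant = NULL,
                            spectrum_id = "spectrum") {
  stopifnot(inherits(system, "visual_system"))
  w <- system$wavelengths
  spectrum <- as.numeric(spectrum)
  if (length(spectrum) != length(w)) {
    stopf("spectrum has %d bands but the system's grid has %d",
          length(spectrum), length(w))
  }
  if (any(spectrum < 0)) stopf("reflectance must be non-negative")
  if (all(spectrum == 0)) stopf("spectrum is identically zero")
  illuminant <- if (is.null(illuminant)) rep(1, length(w)) else
    as.numeric(illuminant)
  if (length(illuminant) != length(w)) stopf("illuminant/grid band mismatch")
  q <- vapply(system$cones, function(cone) {
    pracma::trapz(w, cone$curve * spectrum * illuminant)
  }, numeric(1))
  if (any(q <= 0)) {
    stopf("zero quantum catch in channel %s for '%s'; log contrast undefined",
          paste(c("UVS", "SWS", "MWS", "LWS")[q <= 0], collapse = ","),
          spectrum_id)
  }
  structure(list(q = q, spectrum_id = spectrum_id), class = "quantum_catches")
}

#' Per-channel noise of a visual system
#'
#' Receptor noise scales inversely with the square root of relative cone
#' abundance: `e_i = weber * sqrt(eta_ref / eta_i)`, with the long-wave (LWS)
#' channel as the reference whose noise equals the Weber fraction.
#'
#' @param system A `visual_system`.
#' @return Numeric noise vector (UVS, SWS, MWS, LWS).
#' @export
receptor_noise <- function(system) {
  stopifnot(inherits(system, "visual_system"))
  eta <- system$densities
  system$weber * sqrt(eta[4L] / eta)
}

## General n-channel receptor-noise-limited distance from channel contrasts
## df and noises e:
##   dS^2 = sum_{i<j} (prod_{k not in {i,j}} e_k)^2 (df_i - df_j)^2
##        / sum_i (prod_{k != i} e_k)^2
rnl_from_contrasts <- function(df, e) {
  n <- length(df)
  num <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      num <- num + prod(e[-c(i, j)])^2 * (df[i] - df[j])^2
    }
  }
  den <- sum(vapply(seq_len(n), function(i) prod(e[-i])^2, numeric(1)))
  sqrt(num / den)
}

#' Receptor-noise-limited colour distance between two stimuli
#'
#' Channel contrasts are log (Fechner) contrasts `df_i = ln(q_i^a / q_i^b)`;
#' the tetrachromatic distance combines contrast differences weighted by the
#' channel noises from [receptor_noise()]. The result is in just-noticeable
#' differences (JND): a uniform intensity scaling of either stimulus leaves
#' the distance unchanged, and distances of 1 or more are conventionally
#' discriminable.
#'
#' @param a,b `quantum_catches` of the two stimuli under the same system.
#' @param system The `visual_system` used for both.
#' @param contrast `"log"` (default) or `"linear"` (`df = (q_a - q_b)/q_b`).
#' @return The JND distance (non-negative scalar).
#' @export
rnl_distance <- function(a, b, system, contrast = c("log", "linear")) {
  stopifnot(inherits(a, "quantum_catches"), inherits(b, "quantum_catches"),
            inherits(system, "visual_system"))
  contrast <- match.arg(contrast)
  if (any(a$q <= 0) || any(b$q <= 0)) stopf("quantum catches must be positive")
  df <- switch(contrast,
               log = log(a$q / b$q),
               linear = (a$q - b$q) / b$q)
  rnl_from_contrasts(df, receptor_noise(system))
}

#' Pairwise JND matrix of labelled spectra
#'
#' @param spectra Matrix with one column per colour (e.g. cluster centroids
#'   from [cluster_centroids()]); rows follow the system's wavelength grid.
#' @param system A `visual_system`.
#' @param illuminant Optional per-band irradiance (default flat).
#' @param contrast Passed to [rnl_distance()].
#' @return A `jnd_matrix`: symmetric `distances` matrix with zero diagonal,
#'   `ids`, and the system's name.
#' @export
pairwise_jnd <- function(spectra, system, illuminant = NULL,
                         contrast = "log") {
  spectra <- as.matrix(spectra)
  if (ncol(spectra) < 2L) stopf("need at least 2 spectra")
  ids <- colnames(spectra) %||% paste0("colour_", seq_len(ncol(spectra)))
  catches <- lapply(seq_len(ncol(spectra)), function(i) {
    quantum_catches(system, spectra[, i], illuminant, spectrum_id = ids[i])
  })
  n <- length(catches)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <- rnl_distance(catches[[i]], catches[[j]], system,
                                         contrast)
    }
  }
  structure(list(ids = ids, distances = m, system = system$name),
            class = "jnd_matrix")
}

#' @export
print.jnd_matrix <- function(x, ...) {
  cat(sprintf("<jnd_matrix> %d colours under the %s system\n",
              length(x$ids), x$system))
  print(round(x$distances, 3))
  invisible(x)
}

#' Discriminability table from a JND matrix
#'
#' One row per unordered colour pair with its JND distance and a flag marking
#' it discriminable when the distance reaches the threshold (`>=`, so a pair
#' at exactly 1 JND counts as distinguishable).
#'
#' @param m A `jnd_matrix`.
#' @param threshold Discrimination threshold in JND (default 1).
#' @return Data frame with columns `colour_a`, `colour_b`, `jnd`,
#'   `distinguishable`.
#' @export
discriminability_report <- function(m, threshold = 1) {
  stopifnot(inherits(m, "jnd_matrix"))
  n <- length(m$ids)
  pairs <- which(upper.tri(m$distances), arr.ind = TRUE)
  data.frame(
    colour_a = m$ids[pairs[, "row"]],
    colour_b = m$ids[pairs[, "col"]],
    jnd = m$distances[pairs],
    distinguishable = m$distances[pairs] >= threshold
  )
}

#' Read centroid reflectance spectra from CSV
#'
#' Expects a wavelength column (first, or named `wavelength`) followed by one
#' column per colour — the layout of deposited dominant-colour centroid
#' tables.
#'
#' @param path CSV path.
#' @return List with `wavelengths` and a bands x colours `spectra` matrix.
#' @export
read_centroid_spectra <- function(path) {
  tab <- read.csv(path)
  wcol <- if ("wavelength" %in% names(tab)) "wavelength" else names(tab)[1L]
  w <- wavelength_grid(tab[[wcol]])
  spectra <- as.matrix(tab[setdiff(names(tab), wcol)])
  list(wavelengths = w, spectra = spectra)
}
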