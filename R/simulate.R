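## Synthetic-data generators for both analysis arms: hyperspectral cubes
## with latent colour classes, a grey-card patch and a between-day
## illumination gain; and forced-exploration trial tables with censored
## exponential (optionally Weibull) alert/attack latencies.

#' Specification for a synthetic hyperspectral cube pair
#'
#' Class mean reflectance curves are sums of Gaussian bumps over the
#' wavelength grid (smooth, bounded, with controllable separation -- a
#' stand-in for real lizard reflectance shapes). Pixel noise is Gaussian
#' around the class mean, either independent per band or band-correlated
#' through a squared-exponential kernel. Day-2 pixels are generated from the
#' same process divided by `day2_gain`, emulating a dimmer acquisition day
#' whose gain the calibration must recover.
#'
#' @param wavelengths Band centres in nm (default 40 bands over 330--800).
#' @param classes List of class definitions; each a list with `baseline`
#'   (flat reflectance offset) and `bumps`, a data frame with columns
#'   `centre` (nm), `width` (nm) and `amplitude`. Defaults to six
#'   well-separated colour classes.
#' @param pixels_per_class Pixels drawn per class and day.
#' @param grey_patch_pixels Pixels in the 18% grey-card patch.
#' @param grey_reflectance Card reflectance (default 0.18).
#' @param day2_gain Multiplicative gain the second day's signal is divided
#'   by (default 1.25).
#' @param noise_sd Pixel noise standard deviation.
#' @param band_correlation_length If positive, noise covariance is the
#'   squared-exponential kernel `noise_sd^2 exp(-(li - lj)^2 / (2 L^2))`;
#'   0 (default) gives independent band noise.
#' @param seed Integer seed; a fixed seed reproduces the cubes exactly.
#' @return A `cube_sim_spec`.
#' @export
cube_sim_spec <- function(wavelengths = seq(330, 800, length.out = 40),
                          classes = default_cube_classes(),
                          pixels_per_class = 120L,
                          grey_patch_pixels = 200L,
                          grey_reflectance = 0.18,
                          day2_gain = 1.25,
                          noise_sd = 0.01,
                          band_correlation_length = 0,
                          seed = 1L) {
  w <- wavelength_grid(wavelengths)
  assert_scalar_pos(day2_gain, "day2_gain")
  assert_scalar_pos(grey_reflectance, "grey_reflectance")
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  for (cl in classes) {
    if (any(cl$bumps$amplitude < 0)) stopf("bump amplitudes must be >= 0")
    mu <- class_mean_curve(cl, w)
    if (any(mu < 0) || any(mu > 1)) {
      stopf("a class mean reflectance leaves [0, 1]; adjust bumps/baseline")
    }
  }
  structure(list(wavelengths = w, classes = classes,
                 pixels_per_class = as.integer(pixels_per_class),
                 grey_patch_pixels = as.integer(grey_patch_pixels),
                 grey_reflectance = grey_reflectance, day2_gain = day2_gain,
                 noise_sd = noise_sd,
                 band_correlation_length = band_correlation_length,
                 seed = as.integer(seed)),
            class = "cube_sim_spec")
}

class_mean_curve <- function(class_def, wavelengths) {
  mu <- rep(class_def$baseline %||% 0, length(wavelengths))
  b <- class_def$bumps
  if (!is.null(b)) {
    for (i in seq_len(nrow(b))) {
      mu <- mu + b$amplitude[i] *
        exp(-((wavelengths - b$centre[i]) / b$width[i])^2)
    }
  }
  mu
}

#' Default six-class colour palette for cube simulation
#'
#' Six smooth reflectance curves with well-separated shapes (UV-bright,
#' blue, green, yellow-brown, red-brown, dark), loosely spanning the kinds
#' of dominant colours found on lizard dorsa and painted models.
#'
#' @return List of class definitions for [cube_sim_spec()].
#' @export
default_cube_classes <- function() {
  bump <- function(centre, width, amplitude) {
    data.frame(centre = centre, width = width, amplitude = amplitude)
  }
  list(
    list(name = "uv_bright",  baseline = 0.05, bumps = bump(360, 40, 0.55)),
    list(name = "blue",       baseline = 0.05, bumps = bump(455, 45, 0.50)),
    list(name = "green",      baseline = 0.06, bumps = bump(540, 50, 0.45)),
    list(name = "yellow",     baseline = 0.08, bumps = bump(610, 70, 0.50)),
    list(name = "red_brown",  baseline = 0.04, bumps = bump(700, 90, 0.55)),
    list(name = "dark",       baseline = 0.12, bumps = bump(550, 200, 0.05))
  )
}

draw_class_pixels <- function(n, mu, spec) {
  d <- length(mu)
  if (spec$noise_sd == 0) {
    return(matrix(mu, n, d, byrow = TRUE))
  }
  if (spec$band_correlation_length > 0) {
    w <- spec$wavelengths
    K <- spec$noise_sd^2 *
      exp(-outer(w, w, "-")^2 / (2 * spec$band_correlation_length^2))
    L <- chol(K + diag(1e-12, d))
    noise <- matrix(rnorm(n * d), n, d) %*% L
  } else {
    noise <- matrix(rnorm(n * d, sd = spec$noise_sd), n, d)
  }
  pmax(sweep(noise, 2L, mu, "+"), 0)
}

#' Simulate a matched pair of day-1/day-2 hyperspectral cubes
#'
#' Day-1 pixels are drawn per class around the class mean curves; the grey
#' patch is flat at `grey_reflectance`. Day-2 pixels come from the same
#' generative process divided by `day2_gain`, so running the calibration with
#' day 1 as reference must recover `day2_gain`. Ground-truth class labels
#' are returned for clustering validation.
#'
#' @param spec A [cube_sim_spec()].
#' @return List with `day1` and `day2` ([spectral_cube()]s, masks
#'   `"specimen"` and `"grey_card"`) and `labels` (per specimen-pixel class
#'   index, identical for both days).
#' @export
simulate_cube <- function(spec) {
  stopifnot(inherits(spec, "cube_sim_spec"))
  with_seed(spec$seed, {
    w <- spec$wavelengths
    n_classes <- length(spec$classes)
    labels <- rep(seq_len(n_classes), each = spec$pixels_per_class)
    make_day <- function(scale) {
      specimen <- do.call(rbind, lapply(spec$classes, function(cl) {
        draw_class_pixels(spec$pixels_per_class, class_mean_curve(cl, w), spec)
      }))
      grey <- draw_class_pixels(spec$grey_patch_pixels,
                                rep(spec$grey_reflectance, length(w)), spec)
      pixels <- rbind(specimen, grey) * scale
      spectral_cube(
        w, pixels,
        masks = list(specimen = seq_len(nrow(specimen)),
                     grey_card = nrow(specimen) + seq_len(nrow(grey))),
        day = if (scale == 1) "day1" else "day2",
        specimen_id = sprintf("synthetic_%s",
                              if (scale == 1) "day1" else "day2"))
    }
    list(day1 = make_day(1), day2 = make_day(1 / spec$day2_gain),
         labels = labels)
  })
}

# ---- behavioural trials -----------------------------------------------------

#' Specification for synthetic forced-exploration trials
#'
#' Latencies are exponential by default (constant hazard, so proportional
#' hazards holds exactly); a Weibull shape other than 1 introduces a
#' time-varying hazard ratio for proportional-hazards power checks. Trials
#' are administratively censored at `censor_s`, and an attack ends the trial
#' (the alert endpoint is then censored at the attack time). Defaults mirror
#' the study design: 330 adult and 150 juvenile lizard-model trials, a
#' juvenile/adult alert hazard ratio of 2.77 and attack hazard ratio of
#' 1.66, and baseline rates implied by the reported survival fractions
#' (adult alert 0.82 by 570 s; ~5% attack events overall).
#'
#' @param n_adult,n_juvenile Trials per pheasant age class.
#' @param alert_rate_adult Adult alert hazard (events/s).
#' @param alert_hr_juvenile Juvenile/adult alert hazard ratio.
#' @param attack_rate_adult Adult attack hazard (events/s).
#' @param attack_hr_juvenile Juvenile/adult attack hazard ratio.
#' @param morph_effects Named per-morph hazard multipliers applied to both
#'   endpoints (default all 1).
#' @param weibull_shape Shape of the latency law (1 = exponential, the
#'   default). Length 2 gives age-class-specific shapes (adult, juvenile);
#'   unequal shapes make the hazard ratio time-varying, i.e. a controlled
#'   proportional-hazards violation for diagnostic power checks.
#' @param censor_s Administrative censoring time (default 600 s).
#' @param seed Integer seed.
#' @return A `trial_sim_spec`.
#' @export
trial_sim_spec <- function(n_adult = 330L, n_juvenile = 150L,
                           alert_rate_adult = 3.5e-4,
                           alert_hr_juvenile = 2.77,
                           attack_rate_adult = 8.5e-5,
                           attack_hr_juvenile = 1.66,
                           morph_effects = c(typica = 1, concolor = 1,
                                             erythronotus = 1),
                           weibull_shape = 1,
                           censor_s = 600,
                           seed = 1L) {
  for (nm in c("alert_rate_adult", "alert_hr_juvenile", "attack_rate_adult",
               "attack_hr_juvenile", "censor_s")) {
    assert_scalar_pos(get(nm), nm)
  }
  if (!length(weibull_shape) %in% 1:2 || any(weibull_shape <= 0)) {
    stopf("weibull_shape must be 1 or 2 positive values")
  }
  weibull_shape <- rep(weibull_shape, length.out = 2L)
  if (any(morph_effects <= 0)) stopf("morph hazard multipliers must be > 0")
  structure(list(n_adult = as.integer(n_adult),
                 n_juvenile = as.integer(n_juvenile),
                 alert_rate_adult = alert_rate_adult,
                 alert_hr_juvenile = alert_hr_juvenile,
                 attack_rate_adult = attack_rate_adult,
                 attack_hr_juvenile = attack_hr_juvenile,
                 morph_effects = morph_effects,
                 weibull_shape = weibull_shape,
                 censor_s = censor_s, seed = as.integer(seed)),
            class = "trial_sim_spec")
}

## Weibull with proportional-hazards parameterisation: h(t) = rate * shape *
## t^(shape-1); shape 1 reduces to Exponential(rate).
rweibull_ph <- function(n, rate, shape) {
  u <- runif(n)
  (-log(u) / rate)^(1 / shape)
}

#' Simulate a forced-exploration trial table
#'
#' @param spec A [trial_sim_spec()].
#' @return A `latency_table` with one row per trial in the canonical schema.
#' @export
simulate_trials <- function(spec) {
  stopifnot(inherits(spec, "trial_sim_spec"))
  with_seed(spec$seed, {
    n <- spec$n_adult + spec$n_juvenile
    age <- c(rep("adult", spec$n_adult), rep("juvenile", spec$n_juvenile))
    morphs <- names(spec$morph_effects)
    morph <- sample(morphs, n, replace = TRUE)
    model_sex <- sample(c("M", "F"), n, replace = TRUE)
    pheasant_sex <- sample(c("M", "F"), n, replace = TRUE)
    disturbance <- runif(n) < 0.15
    juv <- age == "juvenile"
    mmult <- spec$morph_effects[morph]
    alert_rate <- spec$alert_rate_adult *
      ifelse(juv, spec$alert_hr_juvenile, 1) * mmult
    attack_rate <- spec$attack_rate_adult *
      ifelse(juv, spec$attack_hr_juvenile, 1) * mmult
    shape <- ifelse(juv, spec$weibull_shape[2L], spec$weibull_shape[1L])
    alert_lat <- rweibull_ph(n, alert_rate, shape)
    attack_lat <- rweibull_ph(n, attack_rate, shape)

    attack_event <- attack_lat <= spec$censor_s
    attack_time <- pmin(attack_lat, spec$censor_s)
    obs_end <- attack_time                      # attack ends the trial
    alert_event <- alert_lat <= obs_end
    alert_time <- pmin(alert_lat, obs_end)

    tab <- data.frame(
      trial_id = sprintf("T%04d", seq_len(n)),
      pheasant_id = sprintf("P%04d", seq_len(n)),
      age_class = age,
      pheasant_sex = pheasant_sex,
      stimulus_class = "lizard",
      morph = morph,
      model_sex = model_sex,
      control_colour = "none",
      disturbance_prior_day = disturbance,
      alert_time_s = alert_time,
      alert_event = as.integer(alert_event),
      attack_time_s = attack_time,
      attack_event = as.integer(attack_event)
    )
    build_latency_table(tab, trial_limit_s = spec$censor_s)
  })
}
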