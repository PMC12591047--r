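## End-to-end orchestration of the two analysis arms, with a manifest that
## records parameters, seeds and content hashes for reproducibility.

#' Pipeline configuration with full defaulting
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A `pipeline_config` list: calibration (`reference_day`,
#'   `card_reflectance`, `kernel_length`, `sigma`), clustering (`k_values`,
#'   `regularisation`, `tol`, `max_iter`, `n_restarts`, `seed`, `pin_k`),
#'   visual model (`weber`, `threshold`, `contrast`), survival (`endpoints`,
#'   `predictors`, `strata`, `conf_level`, `ties`, `ph_transform`).
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    reference_day = NULL, card_reflectance = 0.18,
    kernel_length = 9L, sigma = 1.6,
    k_values = 3:15, regularisation = 0.01, tol = 1e-6, max_iter = 1000L,
    n_restarts = 5L, seed = 1L, pin_k = NULL, decimate = 1L,
    weber = 0.1, threshold = 1, contrast = "log",
    endpoints = c("alert", "attack"), predictors = "age_class",
    strata = NULL, conf_level = 0.95, ties = "efron", ph_transform = "km")
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stopf("unknown configuration field(s): %s", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file of configuration overrides.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

write_manifest <- function(out_dir, stage, config, files, seed = NULL) {
  files <- files[file.exists(files)]
  manifest <- list(
    stage = stage,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("morphspec")),
    seed = seed,
    parameters = config[!vapply(config, is.null, logical(1))],
    outputs = lapply(files, function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest
}

#' Run the colour-congruence arm end to end
#'
#' Calibrates the cubes (gain correction, relative reflectance, smoothing),
#' clusters the anonymised pixel spectra by EM over the configured range of
#' K with AIC elbow selection, summarises per-specimen cluster frequencies,
#' and evaluates the cluster centroids under the avian and reptile visual
#' systems in JND units.
#'
#' @param cubes List of [spectral_cube()] objects, or paths to cube
#'   directories readable by [read_cube_dir()].
#' @param out_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @return The run manifest, invisibly; outputs (`spectra.csv`,
#'   `aic_scan.csv`, `gmm.json`, `assignments.csv`,
#'   `frequency_profiles.csv`, `centroids.csv`, `jnd_avian.csv`,
#'   `jnd_reptile.csv`, `discriminability_*.csv`, `run_manifest.json`) are
#'   written under `out_dir`.
#' @export
run_colour_pipeline <- function(cubes, out_dir, config = pipeline_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (length(cubes) && is.character(cubes[[1L]])) {
    cubes <- lapply(cubes, read_cube_dir)
  }
  stage_wrap <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stopf("colour pipeline failed at stage '%s': %s", stage,
            conditionMessage(e))
    })
  }

  spectra <- stage_wrap("calibrate", calibrate_cubes(
    cubes, reference_day = config$reference_day,
    card_reflectance = config$card_reflectance,
    kernel_length = config$kernel_length, sigma = config$sigma))
  spectra_df <- data.frame(row_id = seq_len(nrow(spectra$spectra)),
                           spectra$spectra, spectra$provenance)
  names(spectra_df)[2:(1 + length(spectra$wavelengths))] <-
    sprintf("nm_%g", spectra$wavelengths)
  write.csv(spectra_df, file.path(out_dir, "spectra.csv"), row.names = FALSE)

  cl_spectra <- decimate_bands(spectra, config$decimate)
  scan <- stage_wrap("cluster", scan_k(
    cl_spectra, k_values = config$k_values, n_restarts = config$n_restarts,
    seed = config$seed, pin_k = config$pin_k,
    regularisation = config$regularisation, tol = config$tol,
    max_iter = config$max_iter))
  model <- scan$models[[match(scan$selected_k, scan$k_values)]]
  assignment <- assign_pixels(model, cl_spectra)
  freq <- frequency_profiles(assignment, cl_spectra$provenance$specimen)

  write.csv(data.frame(K = scan$k_values, AIC = scan$aic,
                       log_likelihood = scan$log_likelihoods,
                       selected = scan$k_values == scan$selected_k),
            file.path(out_dir, "aic_scan.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(K = model$K, weights = model$weights, means = model$means,
         covariances = model$covariances, log_likelihood = model$log_likelihood,
         converged = model$converged, seed = model$seed),
    file.path(out_dir, "gmm.json"), digits = NA, auto_unbox = TRUE,
    matrix = "rowmajor")
  write.csv(data.frame(row_id = seq_along(assignment$labels),
                       label = assignment$labels,
                       max_responsibility = apply(assignment$responsibilities,
                                                  1L, max)),
            file.path(out_dir, "assignments.csv"), row.names = FALSE)
  write.csv(data.frame(specimen = freq$specimen_ids, freq$frequencies),
            file.path(out_dir, "frequency_profiles.csv"), row.names = FALSE)

  centroids <- cluster_centroids(model, cl_spectra$wavelengths)
  write.csv(data.frame(wavelength = cl_spectra$wavelengths, centroids),
            file.path(out_dir, "centroids.csv"), row.names = FALSE)

  jnd <- list()
  for (sysname in c("avian", "reptile")) {
    system <- stage_wrap("vismodel", switch(sysname,
      avian = build_avian_system(cl_spectra$wavelengths, config$weber),
      reptile = build_reptile_system(cl_spectra$wavelengths, config$weber)))
    jm <- stage_wrap("vismodel",
                     pairwise_jnd(centroids, system, contrast = config$contrast))
    jnd[[sysname]] <- jm
    write.csv(as.data.frame(jm$distances),
              file.path(out_dir, sprintf("jnd_%s.csv", sysname)),
              row.names = TRUE)
    write.csv(discriminability_report(jm, config$threshold),
              file.path(out_dir, sprintf("discriminability_%s.csv", sysname)),
              row.names = FALSE)
  }

  files <- file.path(out_dir, c(
    "spectra.csv", "aic_scan.csv", "gmm.json", "assignments.csv",
    "frequency_profiles.csv", "centroids.csv", "jnd_avian.csv",
    "jnd_reptile.csv", "discriminability_avian.csv",
    "discriminability_reptile.csv"))
  manifest <- write_manifest(out_dir, "colour", unclass(config), files,
                             seed = config$seed)
  invisible(list(manifest = manifest, scan = scan, model = model,
                 gains = attr(spectra, "gains"), assignment = assignment,
                 frequencies = freq, centroids = centroids, jnd = jnd))
}

#' Run the behavioural-survival arm end to end
#'
#' For each configured endpoint: Kaplan-Meier curves per predictor
#' (optionally stratified), a Cox proportional hazards fit on the first
#' predictor, and the Schoenfeld proportional-hazards test.
#'
#' @param table A `latency_table` (or path to its CSV).
#' @param out_dir Output directory.
#' @param config A [pipeline_config()].
#' @return The run manifest plus fitted objects, invisibly.
#' @export
run_survival_pipeline <- function(table, out_dir,
                                  config = pipeline_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(table)) table <- read_latency_table(table)
  stopifnot(inherits(table, "latency_table"))

  files <- character(0)
  fits <- list()
  for (endpoint in config$endpoints) {
    time <- table[[paste0(endpoint, "_time_s")]]
    event <- table[[paste0(endpoint, "_event")]]
    for (pred in config$predictors) {
      lv <- unique(table[[pred]])
      if (length(lv) < 2L) {
        stopf("predictor '%s' has a single level ('%s'); nothing to compare",
              pred, lv)
      }
      strata_lab <- table[[pred]]
      if (!is.null(config$strata)) {
        strata_lab <- paste(strata_lab, table[[config$strata]], sep = "/")
      }
      km <- km_estimate(time, event, strata = strata_lab,
                        conf_level = config$conf_level)
      f <- file.path(out_dir, sprintf("km_%s_%s.csv", endpoint, pred))
      write.csv(km_table(km), f, row.names = FALSE)
      files <- c(files, f)
      fits[[sprintf("km_%s_%s", endpoint, pred)]] <- km
    }
    cox <- cox_fit(table, time, event, covariates = config$predictors[1L],
                   ties = config$ties, conf_level = config$conf_level)
    ph <- schoenfeld_ph_test(cox, transform = config$ph_transform)
    f <- file.path(out_dir, sprintf("cox_%s.json", endpoint))
    jsonlite::write_json(
      list(endpoint = endpoint, covariate = names(cox$coef),
           coef = cox$coef, se = cox$se, z = cox$z, p = cox$p, hr = cox$hr,
           hr_ci = cox$hr_ci, loglik_null = cox$loglik_null,
           loglik = cox$loglik, ties = cox$ties,
           ph_test = list(chi2 = ph$chi2, df = ph$df, p = ph$p,
                          transform = ph$transform)),
      f, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
    files <- c(files, f)
    fits[[paste0("cox_", endpoint)]] <- cox
    fits[[paste0("ph_", endpoint)]] <- ph
  }
  manifest <- write_manifest(out_dir, "survival", unclass(config), files,
                             seed = config$seed)
  invisible(c(list(manifest = manifest), fits))
}
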