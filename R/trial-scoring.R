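## Scoring of forced-exploration predation trials: first alert and first
## attack latencies, right-censored at the 600 s trial limit; an attack ends
## the trial, so observation of the alert endpoint stops there too.

canonical_trial_columns <- c(
  "trial_id", "pheasant_id", "age_class", "pheasant_sex", "stimulus_class",
  "morph", "model_sex", "control_colour", "disturbance_prior_day",
  "alert_time_s", "alert_event", "attack_time_s", "attack_event")

#' Score one trial's event log into censored latencies
#'
#' The alert latency is the time of the first alert event; the attack latency
#' the time of the first attack. An attack terminates the trial, so a trial
#' with no alert before an attack at time `t` is alert-censored at `t`
#' (`censor_alert_at = "attack"`, the default) rather than at the trial
#' limit (`censor_alert_at = "limit"`, for sensitivity analysis).
#'
#' @param events Data frame with columns `time_s` and `kind`
#'   (`"alert"`/`"attack"`), times in seconds from trial start,
#'   non-decreasing. May have zero rows.
#' @param covariates Named list or one-row data frame of trial covariates
#'   (must include `trial_id`; other canonical fields default to `NA`/none).
#' @param trial_limit_s Trial duration limit in seconds (default 600).
#' @param censor_alert_at `"attack"` or `"limit"`, see above.
#' @return One-row data frame in the canonical latency-table schema.
#' @export
score_trial <- function(events, covariates, trial_limit_s = 600,
                        censor_alert_at = c("attack", "limit")) {
  censor_alert_at <- match.arg(censor_alert_at)
  covariates <- as.list(covariates)
  if (is.null(covariates$trial_id)) stopf("covariates must include trial_id")
  if (nrow(events) > 0) {
    if (!all(c("time_s", "kind") %in% names(events))) {
      stopf("event log needs columns time_s and kind")
    }
    if (any(events$time_s < 0) || any(events$time_s > trial_limit_s)) {
      stopf("trial %s: event outside [0, %g] s", covariates$trial_id,
            trial_limit_s)
    }
    if (is.unsorted(events$time_s)) {
      stopf("trial %s: event times must be non-decreasing",
            covariates$trial_id)
    }
    if (!all(events$kind %in% c("alert", "attack"))) {
      stopf("trial %s: unknown event kind", covariates$trial_id)
    }
    first_attack_row <- match("attack", events$kind)
    if (!is.na(first_attack_row) && first_attack_row < nrow(events)) {
      stopf("trial %s: events recorded after the attack that ends the trial",
            covariates$trial_id)
    }
  }
  alert_t <- if (nrow(events)) events$time_s[events$kind == "alert"] else
    numeric(0)
  attack_t <- if (nrow(events)) events$time_s[events$kind == "attack"] else
    numeric(0)
  attack_event <- length(attack_t) > 0
  attack_time <- if (attack_event) attack_t[1L] else trial_limit_s
  obs_end <- min(attack_time, trial_limit_s)
  alert_event <- length(alert_t) > 0
  alert_time <- if (alert_event) {
    alert_t[1L]
  } else if (censor_alert_at == "attack") {
    obs_end
  } else {
    trial_limit_s
  }
  rec <- data.frame(
    trial_id = as.character(covariates$trial_id),
    pheasant_id = as.character(covariates$pheasant_id %||% NA_character_),
    age_class = as.character(covariates$age_class %||% NA_character_),
    pheasant_sex = as.character(covariates$pheasant_sex %||% NA_character_),
    stimulus_class = as.character(covariates$stimulus_class %||% "lizard"),
    morph = as.character(covariates$morph %||% "none"),
    model_sex = as.character(covariates$model_sex %||% "none"),
    control_colour = as.character(covariates$control_colour %||% "none"),
    disturbance_prior_day = as.logical(covariates$disturbance_prior_day %||%
                                         FALSE),
    alert_time_s = as.numeric(alert_time),
    alert_event = as.integer(alert_event),
    attack_time_s = as.numeric(attack_time),
    attack_event = as.integer(attack_event)
  )
  validate_trial_record(rec, trial_limit_s)
  rec
}

validate_trial_record <- function(rec, trial_limit_s = 600) {
  if (rec$stimulus_class == "control" && rec$morph != "none") {
    stopf("trial %s: control trials must not carry a morph", rec$trial_id)
  }
  if (rec$stimulus_class == "control" && rec$control_colour == "none") {
    stopf("trial %s: control trials need a control colour", rec$trial_id)
  }
  obs_end <- min(rec$attack_time_s, trial_limit_s)
  ## a censored alert at the trial limit is also legal in attack-terminated
  ## trials (the "censor at limit" sensitivity convention)
  alert_ok <- rec$alert_time_s <= obs_end + 1e-9 ||
    (rec$alert_event == 0L && rec$alert_time_s == trial_limit_s)
  if (!alert_ok) {
    stopf("trial %s: alert latency exceeds the observation end", rec$trial_id)
  }
  if (rec$attack_event == 1L && rec$attack_time_s > trial_limit_s) {
    stopf("trial %s: attack event after the trial limit", rec$trial_id)
  }
  invisible(rec)
}

#' Assemble trial records into a validated latency table
#'
#' @param records List of one-row records from [score_trial()], or a data
#'   frame already in the canonical schema.
#' @param trial_limit_s Trial limit used for validation (default 600).
#' @return A `latency_table` (data frame subclass) with one row per trial;
#'   per-stratum trial counts are attached as attribute `"stratum_counts"`.
#' @export
build_latency_table <- function(records, trial_limit_s = 600) {
  tab <- if (is.data.frame(records)) records else do.call(rbind, records)
  missing <- setdiff(canonical_trial_columns, names(tab))
  if (length(missing)) {
    stopf("latency table is missing column(s): %s",
          paste(missing, collapse = ", "))
  }
  if (!nrow(tab)) stopf("latency table is empty")
  dup <- tab$trial_id[duplicated(tab$trial_id)]
  if (length(dup)) {
    stopf("duplicate trial_id: %s", paste(unique(dup), collapse = ", "))
  }
  for (i in seq_len(nrow(tab))) validate_trial_record(tab[i, ], trial_limit_s)
  tab <- tab[canonical_trial_columns]
  attr(tab, "stratum_counts") <- table(tab$stimulus_class, tab$age_class)
  class(tab) <- c("latency_table", "data.frame")
  tab
}

#' Write a latency table to CSV
#'
#' @param table A `latency_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_latency_table <- function(table, path) {
  write.csv(as.data.frame(table)[canonical_trial_columns], path,
            row.names = FALSE)
  invisible(path)
}

#' Read a latency table from CSV, optionally mapping foreign column names
#'
#' `mapping` adapts arbitrary headers (e.g. of a deposited behavioural
#' dataset) to the canonical schema; it is a named list or a YAML file of
#' `canonical_name: foreign_name` pairs. Unmapped canonical columns must be
#' present under their own names; absent optional covariates may be mapped to
#' constants via `defaults`.
#'
#' @param path CSV path.
#' @param mapping Named list, or path to a YAML file of name pairs.
#' @param defaults Named list of values for canonical columns the file lacks.
#' @return A validated `latency_table`.
#' @export
read_latency_table <- function(path, mapping = NULL, defaults = list()) {
  ## read everything as text first: sex codes like "F" must not become FALSE
  tab <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (is.character(mapping) && length(mapping) == 1L) {
    mapping <- yaml::read_yaml(mapping)
  }
  for (canonical in names(mapping)) {
    foreign <- mapping[[canonical]]
    if (!foreign %in% names(tab)) {
      stopf("mapped column '%s' not found in %s", foreign, path)
    }
    tab[[canonical]] <- tab[[foreign]]
  }
  for (canonical in names(defaults)) {
    if (!canonical %in% names(tab)) tab[[canonical]] <- defaults[[canonical]]
  }
  for (col in c("alert_time_s", "attack_time_s")) {
    tab[[col]] <- as.numeric(tab[[col]])
  }
  for (col in c("alert_event", "attack_event")) {
    tab[[col]] <- as.integer(tab[[col]])
  }
  tab$disturbance_prior_day <- as.logical(tab$disturbance_prior_day)
  build_latency_table(tab)
}
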