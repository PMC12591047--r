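## Kaplan-Meier product-limit estimation with Greenwood confidence
## intervals, optionally stratified. Written from scratch so that every
## quantity (n at risk, survival steps, CI construction) is inspectable.

km_curve_one <- function(time, event, stratum = "all", conf_level = 0.95,
                         conf_type = c("log", "plain", "log-log")) {
  conf_type <- match.arg(conf_type)
  if (!length(time)) stopf("stratum '%s' has no observations", stratum)
  if (any(time <= 0)) stopf("survival times must be positive")
  event_times <- sort(unique(time[event == 1]))
  n_risk <- vapply(event_times, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(event_times, function(t) sum(time == t & event == 1),
                    numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  ## Greenwood variance of log S(t)
  var_log <- cumsum(ifelse(n_risk > n_event,
                           n_event / (n_risk * (n_risk - n_event)), NA_real_))
  se_log <- sqrt(var_log)
  z <- qnorm(1 - (1 - conf_level) / 2)
  if (conf_type == "log") {
    lo <- exp(log(surv) - z * se_log)
    hi <- pmin(exp(log(surv) + z * se_log), 1)
  } else if (conf_type == "plain") {
    half <- z * surv * se_log
    lo <- pmax(surv - half, 0)
    hi <- pmin(surv + half, 1)
  } else {
    theta <- log(-log(surv))
    se_theta <- se_log / abs(log(surv))
    lo <- exp(-exp(theta + z * se_theta))
    hi <- exp(-exp(theta - z * se_theta))
  }
  zero <- !is.na(surv) & surv == 0
  lo[zero] <- 0; hi[zero] <- 0
  structure(
    list(stratum = stratum, time = event_times, n_risk = n_risk,
         n_event = n_event, survival = surv, se_log = se_log,
         ci_low = lo, ci_high = hi, n = length(time),
         obs_times = sort(time), conf_level = conf_level,
         conf_type = conf_type),
    class = "km_curve")
}

#' Kaplan-Meier survival curves with Greenwood confidence intervals
#'
#' Product-limit estimate `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over the
#' distinct event times, with the Greenwood variance of `log S`,
#' `sigma^2(t) = sum d_i / (n_i (n_i - d_i))`, and log-scale confidence
#' intervals `exp(log S +/- z sigma)` truncated at 1 (plain and log-log
#' variants selectable).
#'
#' @param time Positive observation times (seconds).
#' @param event Event indicators (1 = event, 0 = right-censored).
#' @param strata Optional stratum labels; one independent curve per stratum.
#' @param conf_level Confidence level (default 0.95).
#' @param conf_type `"log"` (default), `"plain"` or `"log-log"`.
#' @return A named list of `km_curve` objects (class `km_fit`), one per
#'   stratum.
#' @export
km_estimate <- function(time, event, strata = NULL, conf_level = 0.95,
                        conf_type = "log") {
  time <- as.numeric(time); event <- as.integer(event)
  if (length(time) != length(event)) stopf("time/event length mismatch")
  strata <- if (is.null(strata)) rep("all", length(time)) else
    as.character(strata)
  curves <- lapply(sort(unique(strata)), function(s) {
    sel <- strata == s
    km_curve_one(time[sel], event[sel], s, conf_level, conf_type)
  })
  names(curves) <- vapply(curves, `[[`, character(1), "stratum")
  structure(curves, class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  for (cv in x) {
    cat(sprintf("stratum %s: n = %d, %d event time(s), final S = %s\n",
                cv$stratum, cv$n, length(cv$time),
                if (length(cv$survival))
                  format(round(cv$survival[length(cv$survival)], 3))
                else "1 (no events)"))
  }
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' Right-continuous step-function evaluation: the value at the largest event
#' time not exceeding `t` (1 before the first event). `n_risk` is the number
#' of subjects still under observation at `t`.
#'
#' @param curve A `km_curve` (one element of a `km_fit`).
#' @param t Evaluation times (seconds), `>= 0`.
#' @return Data frame with `time`, `survival`, `ci_low`, `ci_high`, `n_risk`.
#' @export
km_at_times <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  t <- as.numeric(t)
  if (any(t < 0)) stopf("evaluation times must be non-negative")
  idx <- findInterval(t, curve$time)
  val <- function(v, default) ifelse(idx == 0L, default, v[pmax(idx, 1L)])
  data.frame(
    time = t,
    survival = val(curve$survival, 1),
    ci_low = val(curve$ci_low, 1),
    ci_high = val(curve$ci_high, 1),
    n_risk = vapply(t, function(tt) sum(curve$obs_times >= tt), numeric(1))
  )
}

#' Export a fitted KM curve as a tidy data frame
#'
#' @param fit A `km_fit`.
#' @return Data frame with one row per stratum x event time.
#' @export
km_table <- function(fit) {
  stopifnot(inherits(fit, "km_fit"))
  do.call(rbind, lapply(fit, function(cv) {
    if (!length(cv$time)) return(NULL)
    data.frame(stratum = cv$stratum, time = cv$time, n_risk = cv$n_risk,
               n_event = cv$n_event, survival = cv$survival,
               ci_low = cv$ci_low, ci_high = cv$ci_high)
  }))
}
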