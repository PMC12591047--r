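## Schoenfeld residuals and the proportional-hazards score test: a
## systematic association between the scaled residuals and (transformed)
## event time indicates a time-varying hazard ratio.

#' Schoenfeld residuals of a fitted Cox model
#'
#' One residual vector per event: the covariates of the failing subject
#' minus their risk-set weighted mean at the event time (Efron weights for
#' ties when the model was fitted with Efron).
#'
#' @param model A `cox_model` from [cox_fit()].
#' @return List with `time` (event times, ascending) and `residuals` (one
#'   row per event, one column per coefficient).
#' @export
schoenfeld_residuals <- function(model) {
  stopifnot(inherits(model, "cox_model"))
  time <- model$data$time; event <- model$data$event; X <- model$data$X
  phi <- exp(drop(X %*% model$coef))
  out_t <- numeric(0)
  out_r <- NULL
  for (t in sort(unique(time[event == 1L]))) {
    R <- time >= t
    D <- which(time == t & event == 1L)
    d <- length(D)
    XR <- X[R, , drop = FALSE]; phiR <- phi[R]
    s0 <- sum(phiR); s1 <- colSums(XR * phiR)
    XD <- X[D, , drop = FALSE]; phiD <- phi[D]
    s0d <- sum(phiD); s1d <- colSums(XD * phiD)
    fracs <- if (model$ties == "efron") (seq_len(d) - 1L) / d else rep(0, d)
    xbar <- t(vapply(fracs, function(f) (s1 - f * s1d) / (s0 - f * s0d),
                     numeric(ncol(X))))
    if (ncol(X) == 1L) xbar <- matrix(xbar, ncol = 1L)
    out_t <- c(out_t, rep(t, d))
    out_r <- rbind(out_r, XD - xbar)
  }
  colnames(out_r) <- names(model$coef)
  list(time = out_t, residuals = out_r)
}

## Event-time transforms for the PH test. "km": 1 minus the left-continuous
## Kaplan-Meier estimate of the pooled sample at each event time; "rank":
## rank of the event among events; "identity": the time itself.
ph_time_transform <- function(model, times, transform) {
  switch(transform,
    identity = times,
    rank = rank(times, ties.method = "average"),
    km = {
      km <- km_curve_one(model$data$time, model$data$event)
      ## left-continuous: survival just before t
      s_left <- vapply(times, function(t) {
        idx <- which(km$time < t)
        if (length(idx)) km$survival[max(idx)] else 1
      }, numeric(1))
      1 - s_left
    },
    stopf("unknown transform '%s'", transform))
}

#' Proportional-hazards test on Schoenfeld residuals
#'
#' Score test for a linear association between scaled Schoenfeld residuals
#' and transformed event time. With `d` events, residuals `r_i`, coefficient
#' covariance `C = I(beta)^{-1}` (so `d C` is the inverse of the average
#' per-event information) and transformed times `g_i`, the scaled residuals
#' are `s_i = d C r_i + beta` and the statistic per covariate is
#' `chi2 = (sum (g_i - gbar) s_i)^2 / (d C sum (g_i - gbar)^2)`,
#' referred to a chi-squared distribution with 1 degree of freedom. The
#' default time transform is `"km"` (1 minus the left-continuous pooled
#' Kaplan-Meier estimate); `"rank"` and `"identity"` are selectable.
#'
#' @param model A `cox_model` with at least 2 events.
#' @param transform `"km"` (default), `"rank"` or `"identity"`.
#' @return A `ph_test` data frame: one row per covariate with `chi2`, `df`,
#'   `p` and the transform used.
#' @export
schoenfeld_ph_test <- function(model, transform = c("km", "rank", "identity")) {
  stopifnot(inherits(model, "cox_model"))
  transform <- match.arg(transform)
  if (model$n_event < 2L) stopf("the PH test needs at least 2 events")
  res <- schoenfeld_residuals(model)
  d <- length(res$time)
  g <- ph_time_transform(model, res$time, transform)
  gc <- g - mean(g)
  ## scaled residuals s_i = d vcov r_i (+ beta, which the centring removes);
  ## d * vcov is the inverse of the average per-event information
  scaled <- res$residuals %*% model$vcov * d
  p <- length(model$coef)
  chi2 <- numeric(p)
  for (j in seq_len(p)) {
    num <- sum(gc * scaled[, j])
    chi2[j] <- num^2 / (d * model$vcov[j, j] * sum(gc^2))
  }
  out <- data.frame(
    covariate = names(model$coef),
    chi2 = chi2,
    df = 1L,
    p = pchisq(chi2, df = 1L, lower.tail = FALSE),
    transform = transform,
    row.names = NULL)
  class(out) <- c("ph_test", "data.frame")
  out
}
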