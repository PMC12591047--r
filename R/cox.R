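## Cox proportional hazards regression: Newton-Raphson maximisation of the
## partial likelihood with Efron (default) or Breslow handling of tied event
## times, written from scratch.

## Partial log-likelihood, score vector and observed information at `beta`.
cox_derivatives <- function(beta, time, event, X, ties = "efron") {
  p <- ncol(X)
  eta <- drop(X %*% beta)
  phi <- exp(eta)
  ll <- 0
  U <- numeric(p)
  I <- matrix(0, p, p)
  for (t in sort(unique(time[event == 1L]))) {
    R <- time >= t
    D <- time == t & event == 1L
    d <- sum(D)
    XR <- X[R, , drop = FALSE]; phiR <- phi[R]
    s0 <- sum(phiR)
    s1 <- colSums(XR * phiR)
    s2 <- crossprod(XR * phiR, XR)
    XD <- X[D, , drop = FALSE]; phiD <- phi[D]
    s0d <- sum(phiD)
    s1d <- colSums(XD * phiD)
    s2d <- crossprod(XD * phiD, XD)
    fracs <- if (ties == "efron") (seq_len(d) - 1L) / d else rep(0, d)
    for (f in fracs) {
      S0 <- s0 - f * s0d
      S1 <- s1 - f * s1d
      S2 <- s2 - f * s2d
      ll <- ll - log(S0)
      U <- U - S1 / S0
      I <- I + S2 / S0 - tcrossprod(S1 / S0)
    }
    ll <- ll + sum(eta[D])
    U <- U + colSums(XD)
  }
  list(loglik = ll, score = U, information = I)
}

## Reference-level indicator coding: alphabetically first level is the
## reference unless the column is already a factor with its own ordering.
cox_model_matrix <- function(data, covariates) {
  df <- as.data.frame(data)[covariates]
  for (nm in names(df)) {
    if (is.character(df[[nm]]) || is.logical(df[[nm]])) {
      df[[nm]] <- factor(df[[nm]])
    }
    if (is.factor(df[[nm]]) && nlevels(droplevels(df[[nm]])) < 2L ||
        (is.numeric(df[[nm]]) && length(unique(df[[nm]])) < 2L)) {
      stopf("covariate '%s' is constant; cannot enter a Cox model", nm)
    }
  }
  X <- stats::model.matrix(~ ., df)[, -1L, drop = FALSE]
  X
}

#' Fit a Cox proportional hazards model
#'
#' Newton-Raphson maximisation of the partial likelihood, with the Efron
#' correction for tied event times (Breslow selectable), step-halving to
#' keep the log partial likelihood non-decreasing, and convergence when the
#' largest coefficient update or the score norm falls below `1e-9`.
#' Categorical covariates use reference-level indicator coding with the
#' alphabetically first level as reference (relevel a factor beforehand to
#' change it).
#'
#' @param data Data frame (e.g. a `latency_table`) holding the covariates.
#' @param time Positive observation times, or the name of a column of `data`.
#' @param event 0/1 event indicators, or a column name.
#' @param covariates Character vector of covariate column names.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param conf_level Confidence level for hazard-ratio intervals.
#' @param max_iter Maximum Newton iterations before declaring a monotone
#'   likelihood (e.g. complete separation).
#' @return A `cox_model` with `coef`, `se`, `z`, `p`, `hr`, `hr_ci`,
#'   `loglik_null`, `loglik`, `score_test` (the score chi-squared at beta =
#'   0), `information`, and the fitting data for diagnostics.
#' @export
cox_fit <- function(data, time, event, covariates, ties = c("efron", "breslow"),
                    conf_level = 0.95, max_iter = 50L) {
  ties <- match.arg(ties)
  if (is.character(time) && length(time) == 1L) time <- data[[time]]
  if (is.character(event) && length(event) == 1L) event <- data[[event]]
  time <- as.numeric(time); event <- as.integer(event)
  if (any(time <= 0)) stopf("survival times must be positive")
  if (sum(event) < 1L) stopf("no events; the partial likelihood is undefined")
  X <- cox_model_matrix(data, covariates)
  if (nrow(X) != length(time)) stopf("covariate rows do not match times")
  p <- ncol(X)

  beta <- numeric(p)
  d0 <- cox_derivatives(beta, time, event, X, ties)
  loglik_null <- d0$loglik
  score_test <- drop(t(d0$score) %*% solve(d0$information, d0$score))

  cur <- d0
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    delta <- solve(cur$information, cur$score)
    step <- 1
    repeat {
      cand <- beta + step * delta
      cand_d <- cox_derivatives(cand, time, event, X, ties)
      if (cand_d$loglik >= cur$loglik - 1e-12 || step < 1e-4) break
      step <- step / 2
    }
    beta <- cand
    cur <- cand_d
    if (max(abs(step * delta)) < 1e-9 || sqrt(sum(cur$score^2)) < 1e-9) {
      converged <- TRUE
      break
    }
  }
  if (!converged || any(abs(beta) > 15)) {
    stopf("Cox fit did not converge after %d iterations (possible monotone likelihood / complete separation)",
          iter)
  }
  vcov <- solve(cur$information)
  se <- sqrt(diag(vcov))
  z <- beta / se
  pvals <- 2 * pnorm(-abs(z))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  hr_ci <- cbind(lower = exp(beta - zq * se), upper = exp(beta + zq * se))
  rownames(hr_ci) <- colnames(X)
  structure(
    list(coef = setNames(drop(beta), colnames(X)),
         se = setNames(se, colnames(X)), z = setNames(z, colnames(X)),
         p = setNames(pvals, colnames(X)),
         hr = setNames(exp(drop(beta)), colnames(X)), hr_ci = hr_ci,
         loglik_null = loglik_null, loglik = cur$loglik,
         score_test = score_test, information = cur$information,
         vcov = vcov, ties = ties, n = length(time), n_event = sum(event),
         iter = iter, converged = converged, conf_level = conf_level,
         data = list(time = time, event = event, X = X)),
    class = "cox_model")
}

#' @export
print.cox_model <- function(x, ...) {
  cat(sprintf("<cox_model> n = %d, events = %d, ties = %s\n", x$n, x$n_event,
              x$ties))
  print(data.frame(coef = round(x$coef, 4), `HR` = round(x$hr, 3),
                   se = round(x$se, 4), z = round(x$z, 3),
                   p = signif(x$p, 3)))
  invisible(x)
}
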