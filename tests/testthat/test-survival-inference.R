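test_that("KM matches the hand product-limit on the worked example", {
  time <- c(2, 4, 4, 6, 8)
  event <- c(1, 1, 1, 0, 1)
  fit <- km_estimate(time, event)
  curve <- fit$all
  expect_equal(curve$time, c(2, 4, 8))
  expect_equal(curve$n_risk, c(5, 4, 1))
  expect_equal(curve$n_event, c(1, 2, 1))
  expect_equal(curve$survival, c(0.8, 0.4, 0))
  expect_equal(curve$survival, km_bruteforce(time, event))
})

test_that("KM handles no-event and all-event data correctly", {
  none <- km_estimate(c(3, 5, 7), c(0, 0, 0))$all
  expect_equal(length(none$time), 0L)
  expect_equal(km_at_times(none, c(0, 10))$survival, c(1, 1))

  ## all events: KM equals the empirical survival function
  set.seed(4)
  t_all <- sort(sample(1:100, 20))
  fit <- km_estimate(t_all, rep(1, 20))$all
  emp <- vapply(fit$time, function(t) mean(t_all > t), numeric(1))
  expect_equal(fit$survival, emp)

  ## censoring times after the last event add no steps, and their exact
  ## values are irrelevant to the curve
  fit2 <- km_estimate(c(t_all, 200, 300), c(rep(1, 20), 0, 0))$all
  fit3 <- km_estimate(c(t_all, 150, 999), c(rep(1, 20), 0, 0))$all
  expect_equal(fit2$time, fit3$time)
  expect_equal(fit2$survival, fit3$survival)
  expect_equal(max(fit2$time), max(t_all))
})

test_that("KM curves and Greenwood CIs agree with the survival package", {
  skip_if_not_installed("survival")
  tab <- simulate_trials(trial_sim_spec(seed = 7))
  fit <- km_estimate(tab$alert_time_s, tab$alert_event,
                     strata = tab$age_class)
  for (grp in c("adult", "juvenile")) {
    sub <- tab[tab$age_class == grp, ]
    sf <- survival::survfit(
      survival::Surv(alert_time_s, alert_event) ~ 1, data = sub,
      conf.type = "log")
    sm <- summary(sf, times = fit[[grp]]$time)
    expect_equal(fit[[grp]]$survival, sm$surv, tolerance = 1e-10)
    expect_equal(fit[[grp]]$ci_low, sm$lower, tolerance = 1e-10)
    expect_equal(fit[[grp]]$ci_high, sm$upper, tolerance = 1e-10)
    expect_equal(fit[[grp]]$n_risk, as.numeric(sm$n.risk))
  }
})

test_that("KM step evaluation is right-continuous with n at risk", {
  fit <- km_estimate(c(2, 4, 4, 6, 8), c(1, 1, 1, 0, 1))$all
  at <- km_at_times(fit, c(0, 3, 4, 5, 8, 100))
  expect_equal(at$survival, c(1, 0.8, 0.4, 0.4, 0, 0))
  expect_equal(at$n_risk, c(5, 4, 4, 2, 1, 0))
  expect_true(all(at$ci_high <= 1))
})

test_that("Greenwood CI width shrinks with sample size", {
  width_at <- function(n, seed) {
    set.seed(seed)
    t <- rexp(n, rate = 0.01)
    e <- as.integer(t <= 100)
    fit <- km_estimate(pmin(t, 100), e)$all
    at <- km_at_times(fit, 50)
    at$ci_high - at$ci_low
  }
  w_small <- mean(vapply(1:20, function(s) width_at(40, s), numeric(1)))
  w_big <- mean(vapply(1:20, function(s) width_at(400, s), numeric(1)))
  expect_lt(w_big, w_small)
})

test_that("Cox fit on two identical groups returns a null coefficient", {
  time <- rep(c(5, 10, 15, 20, 30, 40), 2)
  event <- rep(c(1, 1, 0, 1, 0, 1), 2)
  grp <- rep(c("a", "b"), each = 6)
  fit <- cox_fit(data.frame(g = grp), time, event, "g")
  expect_lt(abs(fit$coef), 1e-6)
})

test_that("Cox estimates agree with coxph under both tie methods", {
  skip_if_not_installed("survival")
  tab <- simulate_trials(trial_sim_spec(seed = 11))
  ## introduce ties by rounding to 10 s
  tab$alert_time_s <- pmax(round(tab$alert_time_s, -1), 5)
  for (ties in c("efron", "breslow")) {
    mine <- cox_fit(tab, tab$alert_time_s, tab$alert_event, "age_class",
                    ties = ties)
    ref <- survival::coxph(
      survival::Surv(alert_time_s, alert_event) ~ age_class, data = tab,
      ties = ties)
    expect_equal(unname(mine$coef), unname(coef(ref)), tolerance = 1e-7)
    expect_equal(unname(mine$se), unname(sqrt(diag(vcov(ref)))),
                 tolerance = 1e-7)
    expect_equal(mine$loglik, ref$loglik[2], tolerance = 1e-7)
  }
})

test_that("Cox recovers a known hazard ratio and reports consistent Wald z", {
  spec <- trial_sim_spec(n_adult = 500, n_juvenile = 500,
                         alert_rate_adult = 2e-3, alert_hr_juvenile = 2,
                         seed = 23)
  tab <- simulate_trials(spec)
  fit <- cox_fit(tab, tab$alert_time_s, tab$alert_event, "age_class")
  ci <- log(fit$hr_ci)
  expect_gt(log(2), ci[1]); expect_lt(log(2), ci[2])
  expect_equal(unname(fit$z), unname(fit$coef / fit$se), tolerance = 1e-9)
})

test_that("the Breslow score test equals the log-rank statistic", {
  skip_if_not_installed("survival")
  for (s in c(3, 17)) {
    tab <- simulate_trials(trial_sim_spec(n_adult = 120, n_juvenile = 120,
                                          alert_hr_juvenile = 1.8, seed = s))
    mine <- cox_fit(tab, tab$alert_time_s, tab$alert_event, "age_class",
                    ties = "breslow")
    lr <- survival::survdiff(
      survival::Surv(alert_time_s, alert_event) ~ age_class, data = tab)
    expect_equal(mine$score_test, lr$chisq, tolerance = 1e-8)
  }
})

test_that("degenerate Cox inputs raise clear errors", {
  tab <- simulate_trials(trial_sim_spec(n_adult = 20, n_juvenile = 20,
                                        seed = 2))
  expect_error(cox_fit(tab, tab$alert_time_s, rep(0, nrow(tab)), "age_class"),
               "no events")
  expect_error(cox_fit(tab, tab$alert_time_s, tab$alert_event,
                       "stimulus_class"), "constant")
  ## complete separation: all events in one group before any in the other
  sep <- data.frame(g = rep(c("a", "b"), each = 10))
  t_sep <- c(1:10, 101:110)
  expect_error(cox_fit(sep, t_sep, rep(1, 20), "g"), "converge")
})

test_that("Schoenfeld residuals sum to zero and the PH test is calibrated", {
  tab <- simulate_trials(trial_sim_spec(seed = 31))
  fit <- cox_fit(tab, tab$alert_time_s, tab$alert_event, "age_class")
  res <- schoenfeld_residuals(fit)
  expect_equal(length(res$time), fit$n_event)
  ## at the partial-likelihood maximum the residuals sum to ~0 (score = 0)
  expect_lt(abs(sum(res$residuals)), 1e-6)

  for (tr in c("km", "rank", "identity")) {
    ph <- schoenfeld_ph_test(fit, transform = tr)
    expect_gte(ph$chi2, 0)
    expect_true(ph$p >= 0 && ph$p <= 1)
    expect_equal(ph$df, 1L)
  }
})

test_that("the PH test detects a built-in proportional-hazards violation", {
  ## age-class-specific Weibull shapes make the hazard ratio time-varying
  spec <- trial_sim_spec(n_adult = 400, n_juvenile = 400,
                         alert_rate_adult = 1e-3,
                         weibull_shape = c(1, 0.4), seed = 41)
  tab <- simulate_trials(spec)
  fit <- cox_fit(tab, tab$alert_time_s, tab$alert_event, "age_class")
  ph <- schoenfeld_ph_test(fit)
  expect_lt(ph$p, 0.05)
})

test_that("the PH statistic tracks the survival package's on untied data", {
  skip_if_not_installed("survival")
  tab <- simulate_trials(trial_sim_spec(seed = 7))
  fit <- cox_fit(tab, tab$alert_time_s, tab$alert_event, "age_class")
  ph <- schoenfeld_ph_test(fit, transform = "km")
  ref <- survival::cox.zph(
    survival::coxph(survival::Surv(alert_time_s, alert_event) ~ age_class,
                    data = tab), transform = "km")
  ## same construction up to the reference implementation's newer refinements
  expect_equal(ph$chi2, ref$table[1, "chisq"], tolerance = 0.05)
})
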