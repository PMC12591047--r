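test_that("a single-component fit equals the closed-form Gaussian MLE", {
  skip_if_not_installed("mclust")
  set.seed(21)
  X <- matrix(rnorm(300), 100, 3)
  fit <- fit_gmm_em(X, 1, seed = 1)
  n <- nrow(X)
  ## the sample covariance of this data is far above the eigenvalue floor,
  ## so the regularised fit coincides with the plain maximum-likelihood one
  expect_equal(unname(fit$means[1, ]), unname(colMeans(X)), tolerance = 1e-9)
  S_expect <- cov(X) * (n - 1) / n
  expect_equal(unname(fit$covariances[, , 1]), unname(S_expect),
               tolerance = 1e-9)
  ## log-likelihood agrees with an external density evaluation
  ll_oracle <- sum(mclust::dmvnorm(X, colMeans(X), S_expect, log = TRUE))
  expect_equal(fit$log_likelihood, ll_oracle, tolerance = 1e-6)

  ## on near-degenerate data the floor binds: all eigenvalues >= 0.01
  X2 <- cbind(rnorm(50, sd = 0.01), rnorm(50, sd = 0.01))
  fit2 <- fit_gmm_em(X2, 1, seed = 1)
  expect_true(all(eigen(fit2$covariances[, , 1])$values >= 0.01 - 1e-12))
})

test_that("EM recovers two well-separated spherical clusters", {
  sim <- make_clusters(rbind(c(0, 0), c(10, 10)), n_per = 200, seed = 4)
  fit <- fit_gmm_em(sim$X, 2, seed = 9)
  m <- match_means(fit$means, rbind(c(0, 0), c(10, 10)))
  expect_true(all(m$error < 0.5))
  expect_true(all(abs(fit$weights - 0.5) < 0.05))
  expect_true(fit$converged)
})

test_that("EM log-likelihood is non-decreasing on seeded runs", {
  for (s in 1:10) {
    sim <- make_clusters(rbind(c(0, 0), c(6, 0), c(0, 6)), n_per = 40,
                         seed = s)
    fit <- fit_gmm_em(sim$X, 3, seed = s)
    expect_true(all(diff(fit$ll_history) > -1e-8))
  }
})

test_that("fit_gmm_em rejects impossible K", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_gmm_em(X, 0), "K must")
  expect_error(fit_gmm_em(X, 10), "K must")
})

test_that("AIC uses the full-covariance parameter count", {
  fake <- function(K, d, ll) {
    structure(list(K = K, d = d, log_likelihood = ll), class = "gmm_model")
  }
  expect_equal(compute_aic(fake(3, 4, -100)), 288)  # p = 2 + 12 + 30 = 44
  expect_equal(compute_aic(fake(1, 1, 0)), 4)       # p = 0 + 1 + 1 = 2
  ## strictly increasing in p at fixed log-likelihood
  aics <- vapply(1:5, function(K) compute_aic(fake(K, 3, -50)), numeric(1))
  expect_true(all(diff(aics) > 0))
})

test_that("the AIC elbow is the point of maximum chord distance", {
  scan <- structure(list(k_values = 3:6, aic = c(100, 40, 35, 33)),
                    class = "aic_scan")
  ## chord distances computed by hand: K=4 is farthest from the 3->6 chord
  expect_equal(select_elbow_k(scan), 4L)

  linear <- structure(list(k_values = 3:7, aic = seq(100, 60, by = -10)),
                      class = "aic_scan")
  expect_equal(select_elbow_k(linear), 3L)

  knee <- structure(list(k_values = 2:8,
                         aic = c(200, 150, 100, 50, 48, 46, 44)),
                    class = "aic_scan")
  expect_equal(select_elbow_k(knee), 5L)

  expect_error(select_elbow_k(structure(list(k_values = 1:2, aic = c(2, 1)),
                                        class = "aic_scan")), "at least 3")
})

test_that("scan_k retains the best restart and honours pinning", {
  sim <- make_clusters(rbind(c(0, 0), c(12, 0), c(0, 12), c(12, 12)),
                       n_per = 60, seed = 2)
  single <- scan_k(sim$X, k_values = 4, n_restarts = 2, seed = 1)
  expect_equal(single$selected_k, 4L)

  scan <- scan_k(sim$X, 3:6, n_restarts = 2, seed = 1)
  expect_equal(scan$selected_k, 4L)
  expect_equal(length(scan$models), 4L)

  pinned <- scan_k(sim$X, 3:6, n_restarts = 2, seed = 1, pin_k = 5)
  expect_equal(pinned$selected_k, 5L)
  expect_error(scan_k(sim$X, 3:6, n_restarts = 2, seed = 1, pin_k = 9),
               "not in the scan")
})

test_that("pixel assignment returns normalised posteriors", {
  sim <- make_clusters(rbind(c(0, 0), c(10, 10)), n_per = 100, seed = 8)
  fit <- fit_gmm_em(sim$X, 2, seed = 8)
  asg <- assign_pixels(fit, sim$X)
  expect_true(all(abs(rowSums(asg$responsibilities) - 1) < 1e-9))
  expect_equal(asg$labels, max.col(asg$responsibilities))

  ## a pixel exactly at a component mean takes that component's label
  at_mean <- assign_pixels(fit, fit$means)
  expect_equal(at_mean$labels, 1:2)

  ## symmetric two-component mixture: the midpoint splits 50/50
  sym <- structure(
    list(K = 2L, weights = c(0.5, 0.5),
         means = rbind(c(0, 0), c(4, 0)),
         covariances = array(diag(2), c(2, 2, 2)),
         d = 2L),
    class = "gmm_model")
  mid <- assign_pixels(sym, matrix(c(2, 0), 1))
  expect_equal(unname(mid$responsibilities[1, ]), c(0.5, 0.5),
               tolerance = 1e-12)

  expect_error(assign_pixels(fit, matrix(0, 2, 5)), "dimensions")
})

test_that("frequency profiles are per-specimen cluster proportions", {
  asg <- structure(list(labels = c(2L, 2L, 2L, 1L, 2L, 1L, 2L),
                        responsibilities = matrix(0.5, 7, 2)),
                   class = "cluster_assignment")
  prof <- frequency_profiles(asg, c("a", "a", "a", "b", "b", "b", "b"))
  expect_equal(unname(prof$frequencies["a", ]), c(0, 1))    # one-hot
  expect_equal(unname(prof$frequencies["b", ]), c(0.5, 0.5))
  expect_true(all(abs(rowSums(prof$frequencies) - 1) < 1e-9))
  expect_error(frequency_profiles(asg, c("a", "b")), "entries")
})

test_that("specimen grouping merges the most similar profiles first", {
  prof <- structure(
    list(specimen_ids = c("m1", "m2", "out"),
         frequencies = rbind(m1 = c(0.5, 0.3, 0.2),
                             m2 = c(0.48, 0.32, 0.2),
                             out = c(0.05, 0.05, 0.9))),
    class = "frequency_profile")
  tree <- specimen_grouping(prof)
  ## first merge joins the two near-identical profiles
  expect_equal(sort(-tree$merge[1, ]), c(1, 2))

  ## maximally dissimilar one-hot profiles have Bray-Curtis distance 1
  oh <- structure(list(specimen_ids = c("x", "y"),
                       frequencies = rbind(x = c(1, 0), y = c(0, 1))),
                  class = "frequency_profile")
  tree2 <- specimen_grouping(oh)
  expect_equal(tree2$height, 1)

  single <- structure(list(specimen_ids = "x",
                           frequencies = matrix(c(1, 0), 1)),
                      class = "frequency_profile")
  expect_error(specimen_grouping(single), "at least 2")
})

test_that("band decimation thins the grid consistently", {
  sp <- pixel_spectra(test_grid(30), matrix(runif(60), 2, 30))
  dec <- decimate_bands(sp, 3)
  expect_equal(ncol(dec$spectra), 10L)
  expect_equal(dec$wavelengths, sp$wavelengths[seq(1, 30, by = 3)])
  expect_identical(decimate_bands(sp, 1), sp)
})
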