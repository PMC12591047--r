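## Full-covariance Gaussian mixture fitting by expectation-maximisation, with
## ridge regularisation of the covariance diagonals, AIC model selection over
## a range of K, and elbow-based choice of K.

## Log density of rows of X under N(mu, S), via the Cholesky factor of S.
log_dmvnorm_rows <- function(X, mu, S) {
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  ctr <- sweep(X, 2L, mu, "-")
  y <- backsolve(R, t(ctr), transpose = TRUE)   # solves t(R) y = t(ctr)
  quad <- colSums(y^2)
  -0.5 * (ncol(X) * log(2 * pi) + 2 * sum(log(diag(R))) + quad)
}

## k-means++-style seeding: first centre uniform, later centres sampled with
## probability proportional to squared distance to the nearest chosen centre.
kmeanspp_init <- function(X, K) {
  n <- nrow(X)
  centres <- matrix(NA_real_, K, ncol(X))
  centres[1L, ] <- X[sample.int(n, 1L), ]
  if (K > 1L) {
    d2 <- rowSums(sweep(X, 2L, centres[1L, ], "-")^2)
    for (k in 2L:K) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centres[k, ] <- X[sample.int(n, 1L, prob = p), ]
      d2 <- pmin(d2, rowSums(sweep(X, 2L, centres[k, ], "-")^2))
    }
  }
  centres
}

## Constrained covariance update: the maximiser of the Gaussian M-step
## objective over matrices whose eigenvalues are all >= floor. It shares the
## eigenvectors of the unconstrained update and floors its eigenvalues, so
## the EM remains a generalized EM with a non-decreasing likelihood (a ridge
## added after the M-step would break that guarantee during component
## competition). A cheap Cholesky test skips the eigendecomposition when the
## constraint is inactive.
floor_covariance <- function(S, floor) {
  if (floor <= 0) return(S)
  ok <- tryCatch({chol(S - diag(floor - 1e-12, nrow(S))); TRUE},
                 error = function(e) FALSE)
  if (ok) return(S)
  eg <- eigen(S, symmetric = TRUE)
  eg$vectors %*% (pmax(eg$values, floor) * t(eg$vectors))
}

#' Fit a Gaussian mixture model by expectation-maximisation
#'
#' Full covariance matrices with an eigenvalue floor: every M-step
#' covariance is the maximiser of the expected complete-data log-likelihood
#' subject to all eigenvalues being at least `regularisation` (the
#' unconstrained sample update with its deficient eigenvalues raised to the
#' floor). This guards against degenerate components in high-band-count
#' spectra while keeping the algorithm a generalized EM, so the
#' log-likelihood is non-decreasing at every iteration. Means are seeded
#' k-means++-style from the data, covariances start at the pooled sample
#' covariance and weights start uniform. Iteration stops when the relative
#' log-likelihood change drops below `tol` or after `max_iter` iterations.
#'
#' @param x A [pixel_spectra()] object or numeric matrix (observations x
#'   dimensions).
#' @param K Number of mixture components, `0 < K < n`.
#' @param regularisation Eigenvalue floor applied to each covariance at
#'   every M-step.
#' @param tol Relative log-likelihood termination tolerance.
#' @param max_iter Maximum EM iterations.
#' @param seed Optional integer seed for the initialisation draw.
#' @return A `gmm_model`: `weights`, `means` (K x d), `covariances`
#'   (d x d x K), `log_likelihood`, `ll_history`, `n_iter`, `converged`,
#'   `seed`, `n`, `d`.
#' @export
fit_gmm_em <- function(x, K, regularisation = 0.01, tol = 1e-6,
                       max_iter = 1000L, seed = NULL) {
  X <- as_spectra_matrix(x)
  n <- nrow(X); d <- ncol(X)
  if (K <= 0L || K >= n) stopf("K must satisfy 0 < K < n (= %d); got %d", n, K)
  if (regularisation < 0) stopf("regularisation must be >= 0")

  means <- with_seed(seed, kmeanspp_init(X, K))
  pooled <- floor_covariance(cov(X) * (n - 1) / n, regularisation)
  covs <- array(pooled, dim = c(d, d, K))
  weights <- rep(1 / K, K)

  ll_history <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  resp <- NULL
  for (iter in seq_len(max_iter)) {
    ## E-step
    logdens <- matrix(NA_real_, n, K)
    for (k in seq_len(K)) {
      ld <- log_dmvnorm_rows(X, means[k, ], covs[, , k])
      if (is.null(ld)) {
        stopf("covariance of component %d became singular at iteration %d despite regularisation",
              k, iter)
      }
      logdens[, k] <- log(weights[k]) + ld
    }
    m <- apply(logdens, 1L, max)
    lse <- m + log(rowSums(exp(logdens - m)))
    resp <- exp(logdens - lse)
    ll <- sum(lse)
    ll_history <- c(ll_history, ll)
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) / max(1, abs(ll)) < tol) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
    ## M-step
    Nk <- colSums(resp)
    weights <- Nk / n
    means <- crossprod(resp, X) / Nk
    for (k in seq_len(K)) {
      ctr <- sweep(X, 2L, means[k, ], "-")
      Sk <- crossprod(ctr * sqrt(resp[, k]), ctr * sqrt(resp[, k])) / Nk[k]
      covs[, , k] <- floor_covariance(Sk, regularisation)
    }
  }
  structure(
    list(K = K, weights = weights, means = means, covariances = covs,
         log_likelihood = ll_history[length(ll_history)],
         ll_history = ll_history, n_iter = length(ll_history),
         converged = converged, seed = seed, n = n, d = d,
         regularisation = regularisation),
    class = "gmm_model")
}

#' @export
print.gmm_model <- function(x, ...) {
  cat(sprintf("<gmm_model> K = %d, d = %d, logL = %.4f (%s, %d iterations)\n",
              x$K, x$d, x$log_likelihood,
              if (x$converged) "converged" else "not converged", x$n_iter))
  invisible(x)
}

#' Akaike information criterion of a fitted mixture
#'
#' `AIC = -2 logL + 2p` with `p = (K-1) + K d + K d(d+1)/2` free parameters
#' (mixing weights, means, and symmetric full covariances).
#'
#' @param model A `gmm_model`.
#' @param d Data dimension; defaults to the model's.
#' @return The AIC value.
#' @export
compute_aic <- function(model, d = model$d) {
  K <- model$K
  p <- (K - 1) + K * d + K * d * (d + 1) / 2
  -2 * model$log_likelihood + 2 * p
}

#' Posterior cluster assignment of pixels under a fitted mixture
#'
#' One E-step under the fitted parameters: responsibilities are the posterior
#' component probabilities and labels their argmax.
#'
#' @param model A `gmm_model`.
#' @param x Spectra to assign (matrix or [pixel_spectra()]); dimension must
#'   match the model.
#' @return A `cluster_assignment`: integer `labels` and an n x K
#'   `responsibilities` matrix with unit row sums.
#' @export
assign_pixels <- function(model, x) {
  X <- as_spectra_matrix(x)
  if (ncol(X) != model$d) {
    stopf("spectra have %d dimensions but the model was fitted in %d",
          ncol(X), model$d)
  }
  logdens <- matrix(NA_real_, nrow(X), model$K)
  for (k in seq_len(model$K)) {
    logdens[, k] <- log(model$weights[k]) +
      log_dmvnorm_rows(X, model$means[k, ], model$covariances[, , k])
  }
  m <- apply(logdens, 1L, max)
  resp <- exp(logdens - (m + log(rowSums(exp(logdens - m)))))
  structure(list(labels = max.col(resp, ties.method = "first"),
                 responsibilities = resp),
            class = "cluster_assignment")
}

#' Scan a range of component counts and score each fit by AIC
#'
#' For each K the best of `n_restarts` seeded EM fits (by log-likelihood) is
#' retained. The elbow of the AIC curve selects K (see [select_elbow_k()]),
#' unless `pin_k` overrides the choice for reproduction runs.
#'
#' @param x Spectra (matrix or [pixel_spectra()]).
#' @param k_values Component counts to scan; default 3 to 15.
#' @param n_restarts Restarts per K (best log-likelihood kept).
#' @param seed Base seed; each (K, restart) derives its own child seed.
#' @param pin_k Optional manual override of the selected K.
#' @param ... Passed to [fit_gmm_em()] (`regularisation`, `tol`, `max_iter`).
#' @return An `aic_scan`: `k_values`, `aic`, `log_likelihoods`, `models`
#'   (best fit per K), `selected_k`.
#' @export
scan_k <- function(x, k_values = 3:15, n_restarts = 5L, seed = NULL,
                   pin_k = NULL, ...) {
  if (!length(k_values)) stopf("`k_values` must be non-empty")
  X <- as_spectra_matrix(x)
  models <- vector("list", length(k_values))
  for (i in seq_along(k_values)) {
    K <- k_values[i]
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- tryCatch(
        fit_gmm_em(X, K, seed = child_seed(seed, K, r), ...),
        error = function(e) {
          stopf("GMM fit failed for K = %d (restart %d): %s", K, r,
                conditionMessage(e))
        })
      if (is.null(best) || fit$log_likelihood > best$log_likelihood) best <- fit
    }
    models[[i]] <- best
  }
  scan <- structure(
    list(k_values = as.integer(k_values),
         aic = vapply(models, compute_aic, numeric(1)),
         log_likelihoods = vapply(models, `[[`, numeric(1), "log_likelihood"),
         models = models, selected_k = NA_integer_),
    class = "aic_scan")
  scan$selected_k <- if (!is.null(pin_k)) {
    if (!pin_k %in% scan$k_values) stopf("pinned K = %d is not in the scan", pin_k)
    as.integer(pin_k)
  } else if (length(k_values) < 3L) {
    scan$k_values[which.min(scan$aic)]
  } else {
    select_elbow_k(scan)
  }
  scan
}

#' @export
print.aic_scan <- function(x, ...) {
  cat(sprintf("<aic_scan> K in {%s}; selected K = %d\n",
              paste(x$k_values, collapse = ", "), x$selected_k))
  print(data.frame(K = x$k_values, AIC = round(x$aic, 2)), row.names = FALSE)
  invisible(x)
}

#' Elbow of an AIC curve by maximum chord distance
#'
#' The selected K maximises the perpendicular distance from the point
#' `(K, AIC)` to the chord joining the first and last scan points; ties break
#' toward the smaller K (so an exactly linear decline returns the smallest K).
#'
#' @param scan An `aic_scan` with at least 3 points.
#' @return The elbow K as an integer.
#' @export
select_elbow_k <- function(scan) {
  k <- as.numeric(scan$k_values)
  a <- as.numeric(scan$aic)
  if (length(k) < 3L) stopf("elbow selection needs at least 3 scan points")
  dk <- k[length(k)] - k[1L]
  da <- a[length(a)] - a[1L]
  ## |cross product| of (point - first) with the chord direction
  dist <- abs((k - k[1L]) * da - (a - a[1L]) * dk) / sqrt(dk^2 + da^2)
  scan$k_values[which.max(dist)]   # which.max takes the first (smallest K) tie
}

#' Keep every m-th spectral band
#'
#' Full-covariance mixtures in hundreds of bands are expensive and
#' ill-conditioned (the covariance of each component carries d(d+1)/2
#' parameters); decimation is an optional pre-step that thins the wavelength
#' grid before clustering while calibration stays at full resolution.
#'
#' @param x A [pixel_spectra()] object or matrix.
#' @param m Keep every `m`-th band (1 = no decimation).
#' @return Object of the same type with the thinned band set.
#' @export
decimate_bands <- function(x, m = 1L) {
  m <- as.integer(m)
  if (m < 1L) stopf("decimation factor must be >= 1")
  if (m == 1L) return(x)
  if (inherits(x, "pixel_spectra")) {
    keep <- seq(1L, ncol(x$spectra), by = m)
    pixel_spectra(x$wavelengths[keep], x$spectra[, keep, drop = FALSE],
                  x$provenance)
  } else {
    as.matrix(x)[, seq(1L, ncol(x), by = m), drop = FALSE]
  }
}

#' Extract cluster centroid spectra from a fitted mixture
#'
#' @param model A `gmm_model` fitted to pixel spectra.
#' @param wavelengths Band centres the model was fitted on.
#' @return Matrix with one column per cluster (named `colour_1`, ...), rows
#'   along `wavelengths`.
#' @export
cluster_centroids <- function(model, wavelengths) {
  stopifnot(inherits(model, "gmm_model"))
  w <- wavelength_grid(wavelengths)
  if (length(w) != model$d) stopf("grid length does not match model dimension")
  centroids <- t(model$means)
  colnames(centroids) <- paste0("colour_", seq_len(model$K))
  rownames(centroids) <- NULL
  centroids
}
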