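# Independent oracles, deliberately written as literal transcriptions or
# brute-force enumerations, kept separate from the implementation paths.

# Literal 6-term/4-term transcription of the tetrachromatic receptor-noise
# distance (the implementation uses a general n-channel combinatorial form).
rnl_tetra_bruteforce <- function(df, e) {
  num <- (e[1] * e[2])^2 * (df[4] - df[3])^2 +
    (e[1] * e[3])^2 * (df[4] - df[2])^2 +
    (e[1] * e[4])^2 * (df[3] - df[2])^2 +
    (e[2] * e[3])^2 * (df[4] - df[1])^2 +
    (e[2] * e[4])^2 * (df[3] - df[1])^2 +
    (e[3] * e[4])^2 * (df[2] - df[1])^2
  den <- (e[1] * e[2] * e[3])^2 + (e[1] * e[2] * e[4])^2 +
    (e[1] * e[3] * e[4])^2 + (e[2] * e[3] * e[4])^2
  sqrt(num / den)
}

# Hand product-limit estimator: loop over distinct event times.
km_bruteforce <- function(time, event) {
  s <- 1
  out <- numeric(0)
  for (t in sort(unique(time[event == 1]))) {
    n <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n)
    out <- c(out, s)
  }
  out
}

# Simple well-separated Gaussian clusters in d dimensions for recovery tests.
make_clusters <- function(means, n_per, sd = 1, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(means)), function(k) {
    matrix(rnorm(n_per * ncol(means), mean = rep(means[k, ], each = n_per),
                 sd = sd),
           n_per, ncol(means))
  }))
  list(X = X, labels = rep(seq_len(nrow(means)), each = n_per))
}

# Match estimated component means to true means greedily by distance.
match_means <- function(est, true) {
  err <- numeric(nrow(true))
  used <- integer(0)
  for (k in seq_len(nrow(true))) {
    d <- sqrt(colSums((t(est) - true[k, ])^2))
    d[used] <- Inf
    j <- which.min(d)
    used <- c(used, j)
    err[k] <- d[j]
  }
  list(error = err, perm = used)
}

# Quantum catches with random positive entries, for JND axiom sweeps.
random_catches <- function() {
  q <- exp(rnorm(4, sd = 0.5))
  structure(list(q = q, spectrum_id = "rand"), class = "quantum_catches")
}

test_grid <- function(n = 48) seq(330, 800, length.out = n)
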