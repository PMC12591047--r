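grid <- test_grid(95)   # 5 nm steps over 330-800

test_that("pigment template peaks near 1 at lambda_max and decays long-wave", {
  for (lm in c(362, 447, 492, 586, 609)) {
    cone <- pigment_template(lm, grid)
    peak_val <- cone$curve[which.min(abs(grid - lm))]
    expect_true(abs(peak_val - 1) < 0.02)
    ## long-wave limb is strictly decreasing
    tail_idx <- which(grid > lm + 50)
    expect_true(all(diff(cone$curve[tail_idx]) < 0))
    ## peak location lands within one band step of lambda_max
    expect_lt(abs(grid[which.max(cone$curve)] - lm), diff(grid)[1] + 1e-9)
  }
  expect_error(pigment_template(200, grid), "lambda_max")
  expect_warning(pigment_template(340, test_grid(40)[5:40]), "truncated")
})

test_that("the short-wave beta band raises sensitivity below the alpha peak", {
  ## for a 586 nm pigment the beta band sits near 189 + 0.315 * 586 = 374 nm;
  ## an alpha-only template (beta amplitude removed by construction at long
  ## wavelengths) would be monotone increasing up to the peak
  cone <- pigment_template(586, grid)
  short <- cone$curve[grid >= 350 & grid <= 400]
  expect_true(max(short) > 0.2)   # beta bump, far above the alpha tail there
})

test_that("unit-area normalisation is idempotent and exact", {
  sub_grid <- seq(400, 500, length.out = 11)
  flat <- structure(list(wavelengths = sub_grid,
                         curve = rep(2, 11), lambda_max = 450,
                         channel = "custom"),
                    class = "cone_sensitivity")
  norm <- unit_area_normalise(flat)
  expect_equal(norm$curve, rep(0.01, 11))   # area was 2 * 100
  expect_equal(unit_area_normalise(norm)$curve, norm$curve, tolerance = 1e-12)

  for (lm in c(362, 447, 492, 586)) {
    cone <- unit_area_normalise(pigment_template(lm, grid))
    expect_equal(pracma::trapz(grid, cone$curve), 1, tolerance = 1e-9)
  }
  zero <- flat; zero$curve <- rep(0, 11)
  expect_error(unit_area_normalise(zero), "area")
})

test_that("built-in visual systems carry the stated peaks and densities", {
  rs <- build_reptile_system(grid)
  expect_equal(rs$densities, c(1, 2, 6, 6))
  peaks <- vapply(rs$cones, `[[`, numeric(1), "lambda_max")
  expect_equal(peaks, c(362, 447, 492, 586))
  for (cone in rs$cones) {
    expect_equal(pracma::trapz(grid, cone$curve), 1, tolerance = 1e-9)
    expect_lt(abs(grid[which.max(cone$curve)] - cone$lambda_max),
              diff(grid)[1] + 1e-9)
  }

  as_ <- build_avian_system(grid)
  expect_equal(as_$densities, c(1, 2, 4, 3))
  apeaks <- vapply(as_$cones, function(cn) grid[which.max(cn$curve)],
                   numeric(1))
  expect_true(all(diff(apeaks) > 0))   # UVS < SWS < MWS < LWS
  for (cone in as_$cones) {
    expect_equal(pracma::trapz(grid, cone$curve), 1, tolerance = 1e-9)
  }
})

test_that("quantum catches integrate sensitivity times stimulus", {
  rs <- build_reptile_system(grid)
  flat <- rep(1, length(grid))
  q <- quantum_catches(rs, flat)
  expect_equal(unname(q$q), rep(1, 4), tolerance = 1e-12)

  ## linearity in the stimulus
  set.seed(3)
  s <- runif(length(grid), 0.05, 0.9)
  expect_equal(quantum_catches(rs, 3 * s)$q, 3 * quantum_catches(rs, s)$q,
               tolerance = 1e-12)

  ## a stimulus concentrated at 586 nm is caught mostly by the LWS cone
  gauss <- exp(-((grid - 586) / 30)^2)
  expect_equal(which.max(quantum_catches(rs, gauss)$q), 4L)

  expect_error(quantum_catches(rs, rep(0, length(grid))), "zero")
  expect_error(quantum_catches(rs, -flat), "non-negative")
})

test_that("receptor noise scales inversely with sqrt cone density", {
  as_ <- build_avian_system(grid, weber = 0.1)
  expect_equal(receptor_noise(as_),
               c(0.1 * sqrt(3), 0.1 * sqrt(1.5), 0.1 * sqrt(0.75), 0.1),
               tolerance = 1e-12)
  rs <- build_reptile_system(grid, weber = 0.1)
  expect_equal(receptor_noise(rs),
               c(0.1 * sqrt(6), 0.1 * sqrt(3), 0.1, 0.1), tolerance = 1e-12)

  eq <- build_avian_system(grid, weber = 0.05)
  eq$densities <- c(2, 2, 2, 2)
  expect_equal(receptor_noise(eq), rep(0.05, 4))
})

test_that("the JND distance matches a brute-force transcription", {
  e <- rep(0.1, 4)
  df <- c(0, 0, 0, 0.1)
  expect_equal(morphspec:::rnl_from_contrasts(df, e),
               rnl_tetra_bruteforce(df, e), tolerance = 1e-12)

  set.seed(99)
  rs <- build_reptile_system(grid)
  e_sys <- receptor_noise(rs)
  for (i in 1:200) {
    a <- random_catches(); b <- random_catches()
    df <- log(a$q / b$q)
    expect_equal(rnl_distance(a, b, rs), rnl_tetra_bruteforce(df, e_sys),
                 tolerance = 1e-12)
  }
})

test_that("JND distances satisfy the metric axioms and scale invariance", {
  rs <- build_reptile_system(grid)
  set.seed(17)
  for (i in 1:100) {
    a <- random_catches(); b <- random_catches(); c_ <- random_catches()
    dab <- rnl_distance(a, b, rs)
    expect_gte(dab, 0)
    expect_equal(dab, rnl_distance(b, a, rs), tolerance = 1e-12)
    expect_identical(rnl_distance(a, a, rs), 0)
    ## triangle inequality
    expect_lte(dab, rnl_distance(a, c_, rs) + rnl_distance(c_, b, rs) + 1e-12)
    ## uniform intensity scaling leaves the distance unchanged
    a_scaled <- a; a_scaled$q <- a$q * 3.7
    b_scaled <- b; b_scaled$q <- b$q * 3.7
    expect_equal(rnl_distance(a_scaled, b_scaled, rs), dab, tolerance = 1e-10)
    ## scaling one stimulus uniformly is an achromatic shift: distance 0
    expect_equal(rnl_distance(a, a_scaled, rs), 0, tolerance = 1e-12)
  }
})

test_that("the 4-channel formula degrades to the dichromatic closed form", {
  set.seed(7)
  for (i in 1:20) {
    df <- rnorm(4, sd = 0.3)
    e12 <- runif(2, 0.05, 0.3)
    big <- 1e7
    got <- morphspec:::rnl_from_contrasts(df, c(e12, big, big))
    want <- abs(df[1] - df[2]) / sqrt(sum(e12^2))
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("pairwise JND matrices are symmetric and order-equivariant", {
  rs <- build_reptile_system(grid)
  set.seed(12)
  spectra <- sapply(1:4, function(i) runif(length(grid), 0.05, 0.9))
  colnames(spectra) <- paste0("c", 1:4)
  m <- pairwise_jnd(spectra, rs)
  expect_equal(m$distances, t(m$distances))
  expect_true(all(diag(m$distances) == 0))

  perm <- c(3, 1, 4, 2)
  m2 <- pairwise_jnd(spectra[, perm], rs)
  expect_equal(m2$distances, m$distances[perm, perm])

  dup <- cbind(spectra, c1_copy = spectra[, 1])
  md <- pairwise_jnd(dup, rs)
  expect_equal(md$distances["c1", "c1_copy"], 0)
})

test_that("the discriminability report flags pairs at the threshold", {
  m <- structure(
    list(ids = c("a", "b", "c"),
         distances = matrix(c(0, 1, 0.4, 1, 0, 2, 0.4, 2, 0), 3, 3,
                            dimnames = list(c("a", "b", "c"),
                                            c("a", "b", "c"))),
         system = "reptile"),
    class = "jnd_matrix")
  rep_ <- discriminability_report(m)
  expect_equal(nrow(rep_), 3L)
  expect_equal(rep_$distinguishable[rep_$jnd == 1], TRUE)   # >= convention
  expect_equal(rep_$distinguishable[rep_$jnd == 0.4], FALSE)

  set.seed(2)
  rs <- build_reptile_system(grid)
  six <- sapply(1:6, function(i) runif(length(grid), 0.05, 0.9))
  expect_equal(nrow(discriminability_report(pairwise_jnd(six, rs))), 15L)
})
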