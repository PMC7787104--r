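# Normalization, second moments, French-Wilson detection, outliers.

test_that("sigma curve recovers unit mean and is scale-equivariant", {
  fx <- make_z_fixture(20000, seed = 21)
  st <- estimate_sigma_curve(fx$z, fx$binning, p_cut = NULL)
  # exponential draws with unit mean: Sigma ~ 1 in every bin (3 se)
  for (b in seq_len(fx$binning$nbins)) {
    nb <- sum(fx$binning$bin == b)
    expect_lt(abs(st$Sigma[b] - 1), 3 / sqrt(nb))
  }
  expect_true(st$converged)
  # doubling intensities doubles Sigma, z unchanged
  st2 <- estimate_sigma_curve(2 * fx$z, fx$binning, p_cut = NULL)
  expect_equal(st2$Sigma, 2 * st$Sigma, tolerance = 1e-12)
  expect_equal(st2$z, st$z, tolerance = 1e-12)
})

test_that("z has unit bin means under 422 epsilon factors", {
  set.seed(31)
  cell <- unit_cell(40, 40, 60)
  pg <- point_group("422")
  H <- canonical_asu(grid_hkl(6), pg)
  H <- H[!duplicated(paste(H[, 1], H[, 2], H[, 3])), ]
  eps <- epsilon_factor(H, pg)
  cen <- is_centric(H, pg)
  # symmetry-enhanced variances: acentric exp(mean eps), centric eps * chi2
  z0 <- ifelse(cen, rnorm(nrow(H))^2, rexp(nrow(H)))
  I <- z0 * eps * 50
  s2 <- refltriage:::s2_of(H, cell)
  binning <- make_binning(s2, nbins = 4, min_per_bin = 20)
  st <- estimate_sigma_curve(I, binning, factors = eps, centric = cen)
  for (b in seq_len(binning$nbins)) {
    sel <- binning$bin == b & st$mask
    expect_lt(abs(mean(st$z[sel]) - 1), 4 / sqrt(sum(sel)))
  }
})

test_that("second moments recover the Wilson and perfect-twin values", {
  # acentric untwinned: <z^2>/<z>^2 = 2 (analytic moment of the exponential)
  fa <- make_z_fixture(100000, centric = FALSE, seed = 41)
  ma <- second_moments(fa$z, centric = rep(FALSE, 100000), binning = fa$binning)
  expect_lt(abs(ma$acentric$m2 - 2), 3 * ma$acentric$se)
  expect_null(ma$centric)
  # centric untwinned: fourth moment of the normal gives 3
  fc <- make_z_fixture(100000, centric = TRUE, seed = 42)
  mc <- second_moments(fc$z, centric = rep(TRUE, 100000), binning = fc$binning)
  expect_lt(abs(mc$centric$m2 - 3), 3 * mc$centric$se)
  # perfect twin: acentric 1.5, centric 2.0
  ft <- make_z_fixture(100000, centric = FALSE, alpha = 0.5, seed = 43)
  mt <- second_moments(ft$z, centric = rep(FALSE, 100000), binning = ft$binning)
  expect_lt(abs(mt$acentric$m2 - 1.5), 3 * mt$acentric$se)
  ftc <- make_z_fixture(100000, centric = TRUE, alpha = 0.5, seed = 44)
  mtc <- second_moments(ftc$z, centric = rep(TRUE, 100000), binning = ftc$binning)
  expect_lt(abs(mtc$centric$m2 - 2), 3 * mtc$centric$se)
})

test_that("outlier rejection applies the Wilson tail thresholds", {
  expect_error(reject_outliers(1, FALSE, p_cut = 0.5), "p_cut")
  expect_error(reject_outliers(1, FALSE, p_cut = 0), "p_cut")
  # acentric threshold -ln(1e-6) = 13.8155
  expect_true(reject_outliers(14.0, FALSE, 1e-6))
  expect_false(reject_outliers(10.0, FALSE, 1e-6))
  expect_equal(-log(1e-6), 13.8155, tolerance = 1e-4)
  # centric threshold qnorm(1 - 5e-7)^2
  thr_ce <- qnorm(1 - 1e-6 / 2)^2
  expect_true(reject_outliers(thr_ce + 0.1, TRUE, 1e-6))
  expect_false(reject_outliers(thr_ce - 0.1, TRUE, 1e-6))
  # expected rejection count on 1e6 clean exponential draws ~ 1
  set.seed(51)
  z <- rexp(1e6)
  expect_lt(sum(reject_outliers(z, rep(FALSE, 1e6), 1e-6)), 6)
})

test_that("French-Wilson posterior matches the quadrature oracle", {
  # closed-form truncated-normal intensity moments vs direct quadrature
  cases <- list(c(I = -2, sigI = 1, Sigma = 5), c(I = 3, sigI = 1.5, Sigma = 2),
                c(I = 40, sigI = 2, Sigma = 100))
  for (cs in cases) {
    post <- french_wilson_posterior(cs["I"], cs["sigI"], cs["Sigma"])
    mu <- cs["I"] - cs["sigI"]^2 / cs["Sigma"]
    norm <- integrate(function(J) dnorm(J, mu, cs["sigI"]), 0, Inf, rel.tol = 1e-10)$value
    EJ <- integrate(function(J) J * dnorm(J, mu, cs["sigI"]), 0, Inf, rel.tol = 1e-10)$value / norm
    expect_equal(unname(post$I_post), EJ, tolerance = 1e-6)
    expect_gt(post$I_post, 0)
  }
  # asymptotic shrinkage: I >> sigma gives I_post -> I - sigma^2/Sigma
  post <- french_wilson_posterior(20, 1, 10)       # I/sigma = 20
  expect_equal(unname(post$I_post), 20 - 1 / 10, tolerance = 1e-6)
  # sigma -> 0: likelihood dominates
  post0 <- french_wilson_posterior(5, 1e-4, 10)
  expect_equal(unname(post0$I_post), 5, tolerance = 1e-3)
  expect_error(french_wilson_posterior(1, 1, -2), "Sigma")
})

test_that("French-Wilson treatment is detected after forward simulation", {
  set.seed(61)
  n <- 20000
  s2 <- runif(n, 0.01, 0.2)
  binning <- make_binning(s2)
  Sigma <- 80 * exp(-10 * s2)
  z <- rexp(n)
  sigI <- 0.4 * Sigma
  I_raw <- z * Sigma + rnorm(n, 0, sigI)
  cell <- unit_cell(80, 90, 100)
  H <- generate_grid_unique(cell, "1", n, m = 20)[seq_len(n), ]
  ds_raw <- refl_dataset(H, I_raw, sigI, cell, "1", canonicalize = FALSE)
  st_raw <- estimate_sigma_curve(I_raw, binning)
  det_raw <- detect_french_wilson(I_raw, state = st_raw)
  expect_false(det_raw$suspected)            # negatives present
  expect_gt(det_raw$evidence$frac_negative, 0)
  # push through the posterior, then detect
  post <- french_wilson_posterior(I_raw, sigI, Sigma)
  st_fw <- estimate_sigma_curve(post$I_post, binning)
  det_fw <- detect_french_wilson(post$I_post, state = st_fw)
  expect_true(det_fw$suspected)
  expect_equal(det_fw$evidence$frac_negative, 0)
  expect_gt(det_fw$evidence$low_tail_deficit, 0.5)
  # all-positive raw data with an intact low tail is NOT flagged
  I_clean <- rexp(n)
  st_cl <- estimate_sigma_curve(I_clean, binning)
  det_cl <- detect_french_wilson(I_clean, state = st_cl)
  expect_false(det_cl$suspected)
})

test_that("French-Wilson false-positive rate is under control", {
  # seeded sweep of clean noisy datasets; noise produces negatives, so the
  # detector should almost never fire
  hits <- 0
  for (seed in 1:40) {
    sim <- simulate_wilson_data(4000, 0, seed = seed, noise_frac = 0.1)
    st <- estimate_sigma_curve(sim$I, make_binning(sim$s2))
    if (detect_french_wilson(sim$I, state = st)$suspected) hits <- hits + 1
  }
  expect_lt(hits / 40, 0.05)
})
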