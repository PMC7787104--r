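# Patterson-based TNCS detection and the expected-intensity-factor model.

test_that("interference function limits and closed form", {
  expect_equal(interference_G(0), 1)
  expect_equal(interference_G(pi), 3 / pi^2, tolerance = 1e-12)
  # series/closed-form agreement where the closed form is numerically stable
  # (below ~1e-3 the direct form loses digits to cancellation; the series is
  # the accurate one there)
  x <- c(2e-3, 5e-3, 0.01, 0.1, 1)
  direct <- 3 * (sin(x) - x * cos(x)) / x^3
  expect_equal(interference_G(x), direct, tolerance = 1e-9)
  # continuity across the series/closed-form switch
  expect_lt(abs(interference_G(0.999e-3) - interference_G(1.001e-3)), 1e-9)
  # decay: |G| < 0.01 beyond x = 50
  xs <- seq(50, 200, by = 0.37)
  expect_true(all(abs(interference_G(xs)) < 0.01))
  expect_error(interference_G(-1))
})

test_that("tncs_epsilon reproduces the interference limits", {
  cell <- unit_cell(40, 50, 60)
  H <- grid_hkl(3)
  # f0 = 0: uncorrelated copies, factor identically m raw / 1 normalized
  mod0 <- tncs_model(m = 3, t = c(0.3, 0, 0), f0 = 0)
  expect_equal(tncs_epsilon(H, mod0, cell, normalize = FALSE), rep(3, nrow(H)))
  expect_equal(tncs_epsilon(H, mod0, cell), rep(1, nrow(H)), tolerance = 1e-9)
  # m = 2, rho = 1: raw factor 2 + 2 cos(2 pi h.t)
  mod1 <- tncs_model(m = 2, t = c(0.5, 0, 0), f0 = 1, sigma_rmsd = 0, beta = 0)
  raw <- tncs_epsilon(H, mod1, cell, normalize = FALSE)
  ht <- H %*% c(0.5, 0, 0)
  expect_equal(raw, as.numeric(2 + 2 * cos(2 * pi * ht)), tolerance = 1e-9)
  # destructive h.t = 1/2 -> 0; constructive h.t = 0 -> 4
  expect_equal(raw[ht == 0.5], rep(0, sum(ht == 0.5)))
  expect_equal(raw[ht == 0], rep(4, sum(ht == 0)))
  # m = 1 is the identity
  expect_equal(tncs_epsilon(H, tncs_model(m = 1), cell), rep(1, nrow(H)))
})

test_that("normalized factors have unit shell means", {
  cell <- unit_cell(40, 50, 60)
  H <- generate_grid_unique(cell, "1", 3000, m = 8)
  mod <- tncs_model(m = 2, t = c(0.5, 0, 0), f0 = 0.8, sigma_rmsd = 0.5)
  s2 <- refltriage:::s2_of(H, cell)
  binning <- make_binning(s2, nbins = 8, min_per_bin = 30)
  eps <- tncs_epsilon(H, mod, cell, binning = binning)
  for (b in seq_len(binning$nbins)) {
    expect_lt(abs(mean(eps[binning$bin == b]) - 1), 1e-3)
  }
})

test_that("featureless data give a flat map and no peaks", {
  set.seed(81)
  cell <- unit_cell(40, 44, 48)
  H <- generate_grid_unique(cell, "1", 10000, m = 11)
  s2 <- refltriage:::s2_of(H, cell)
  keep <- s2 <= 1 / 16 & s2 >= 1 / 100
  H <- H[keep, ][seq_len(1500), ]
  # z identically 1: coefficients are exactly zero
  ds <- refl_dataset(H, rep(5, nrow(H)), rep(0.1, nrow(H)), cell, "1",
                     canonicalize = FALSE)
  pm <- patterson_map(ds)
  off <- pm$values; off[1, 1, 1] <- 0
  expect_lt(max(abs(off)), 1e-6 * pm$origin_height)
  expect_length(find_tncs_vectors(pm), 0)
  # threshold above the origin is always empty
  expect_length(find_tncs_vectors(pm, threshold_rel = 1.01), 0)
})

test_that("the map is symmetric under inversion", {
  tr <- simulation_truth(seed = 5, cell = unit_cell(40, 48, 56), laue = "1",
                         n_atoms = 40,
                         tncs = list(m = 2, t = c(0.5, 0, 0), sigma_rmsd = 0.5, f0 = 0.8),
                         d_min = 3)
  ds <- simulate_dataset(tr)$dataset
  pm <- patterson_map(ds)
  v <- pm$values
  d <- dim(v)
  inv <- v[c(1, rev(seq_len(d[1])[-1])), c(1, rev(seq_len(d[2])[-1])), c(1, rev(seq_len(d[3])[-1]))]
  expect_equal(v, inv, tolerance = 1e-9)
  # order-2 translation shows as the dominant off-origin peak
  pk <- find_tncs_vectors(pm)
  expect_gte(length(pk), 1)
  expect_equal(pk[[1]]$u, c(0.5, 0, 0), tolerance = 2 / min(pm$dims))
  hyp <- infer_tncs_orders(pk)
  expect_equal(hyp[[1]]$m, 2)
  expect_equal(hyp[[1]]$t, c(0.5, 0, 0), tolerance = 0.02)
  # the no-TNCS hypothesis is always present
  expect_true(any(vapply(hyp, function(h) h$m == 1, logical(1))))
})

test_that("a window with too few reflections is fatal with advice", {
  ds <- fixture_dataset_50()
  expect_error(patterson_map(ds), "widen")
})

test_that("sevenfold TNCS produces the colinear k/7 family and order 7", {
  tr <- simulation_truth(seed = 9, cell = unit_cell(36, 36, 77), laue = "1",
                         n_atoms = 30,
                         tncs = list(m = 7, t = c(0, 0, 1 / 7), sigma_rmsd = 0.3, f0 = 0.9),
                         d_min = 3.2)
  ds <- simulate_dataset(tr)$dataset
  pm <- patterson_map(ds)
  pk <- find_tncs_vectors(pm)
  expect_gte(length(pk), 3)
  # peaks lie on the c axis at multiples of 1/7 (inversion-deduplicated)
  for (p in pk[1:3]) {
    expect_lt(max(abs(p$u[1:2] - round(p$u[1:2]))), 0.02)
    k7 <- p$u[3] * 7
    expect_lt(abs(k7 - round(k7)), 0.1)
  }
  hyp <- infer_tncs_orders(pk, tol = max(2 / min(pm$dims), 0.01))
  expect_equal(hyp[[1]]$m, 7)
  # empty peak list proposes only m = 1
  expect_equal(infer_tncs_orders(list()), list(list(m = 1L, t = c(0, 0, 0), score = 0)))
})

test_that("Patterson peak height grows with the TNCS fraction", {
  heights <- vapply(c(0.2, 0.5, 0.8), function(f0) {
    tr <- simulation_truth(seed = 17, cell = unit_cell(40, 48, 56), laue = "1",
                           n_atoms = 40,
                           tncs = list(m = 2, t = c(0.5, 0, 0), sigma_rmsd = 0.3, f0 = f0),
                           d_min = 3.4)
    ds <- simulate_dataset(tr)$dataset
    pm <- patterson_map(ds)
    pk <- find_tncs_vectors(pm, threshold_rel = 0.05)
    if (!length(pk)) return(0)
    pk[[1]]$height_rel
  }, numeric(1))
  expect_true(all(diff(heights) > 0))
})

test_that("TNCS refinement recovers the generating parameters", {
  tr <- simulation_truth(seed = 5, cell = unit_cell(40, 48, 56), laue = "1",
                         n_atoms = 40,
                         tncs = list(m = 2, t = c(0.5, 0, 0), sigma_rmsd = 0.5, f0 = 0.8),
                         d_min = 3)
  ds <- simulate_dataset(tr)$dataset
  mod <- refine_tncs(ds, list(m = 2, t = c(0.5, 0, 0)))
  expect_equal(mod$flag, "")
  expect_lt(abs(mod$f0 - 0.8), 0.1)
  expect_lt(max(abs(mod$t - c(0.5, 0, 0))), 4 / 3 / 40)   # one grid step
  expect_gt(mod$loglik, mod$loglik_m1)
  # m = 1 input returns the identity model
  id <- refine_tncs(ds, list(m = 1))
  expect_equal(id$epsilon, rep(1, n_refl(ds)))
})

test_that("a forced TNCS fit on clean data is flagged unsupported", {
  tr <- simulation_truth(seed = 6, cell = unit_cell(40, 48, 56), laue = "1",
                         n_atoms = 40, d_min = 3)
  ds <- simulate_dataset(tr)$dataset
  expect_warning(mod <- refine_tncs(ds, list(m = 2, t = c(0.5, 0, 0))),
                 "worse|not")
  expect_equal(mod$flag, "tncs_not_supported")
})

test_that("dividing by the refined factors restores the second moment", {
  tr <- simulation_truth(seed = 5, cell = unit_cell(40, 48, 56), laue = "1",
                         n_atoms = 40,
                         tncs = list(m = 2, t = c(0.5, 0, 0), sigma_rmsd = 0.5, f0 = 0.8),
                         d_min = 3)
  ds <- simulate_dataset(tr)$dataset
  s2 <- refltriage:::s2_of(ds$hkl, ds$cell)
  cen <- is_centric(ds$hkl, ds$pg)
  binning <- make_binning(s2)
  m_before <- second_moments(estimate_sigma_curve(ds$I, binning, centric = cen), cen)
  expect_gt(m_before$acentric$m2, 2.2)
  mod <- refine_tncs(ds, list(m = 2, t = c(0.5, 0, 0)))
  corr <- apply_tncs_correction(ds, mod)
  m_after <- second_moments(estimate_sigma_curve(corr$I, binning, centric = cen), cen)
  expect_lt(abs(m_after$acentric$m2 - 2), 3 * m_after$acentric$se)
  expect_true("tncs:2" %in% corr$provenance)
})
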