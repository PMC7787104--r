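# Point-group algebra against brute-force oracles.

test_that("point groups close to the expected orders", {
  expected <- c("1" = 1, "2" = 2, "222" = 4, "4" = 4, "422" = 8,
                "3" = 3, "32" = 6, "6" = 6, "622" = 12, "23" = 12, "432" = 24)
  for (sym in names(expected)) {
    pg <- point_group(sym)
    expect_equal(length(pg$rotations), unname(expected[sym]), info = sym)
    # closure by brute-force multiplication table
    keys <- vapply(pg$rotations, function(R) paste(R, collapse = ","), character(1))
    for (a in pg$rotations) for (b in pg$rotations) {
      expect_true(paste(a %*% b, collapse = ",") %in% keys, info = sym)
    }
    # every element has finite order dividing the group order
    for (R in pg$rotations) {
      P <- R; ord <- 1
      while (!all(P == diag(3L))) { P <- P %*% R; ord <- ord + 1 }
      expect_equal(length(pg$rotations) %% ord, 0, info = sym)
    }
  }
  expect_error(point_group("icosahedral"), "unsupported")
})

test_that("Laue and space-group symbols normalize to the rotation groups", {
  expect_equal(point_group("4/mmm")$symbol, "422")
  expect_equal(point_group("P41212")$symbol, "422")
  expect_equal(point_group("mmm")$symbol, "222")
  expect_equal(point_group("P21")$symbol, "2")
  expect_equal(point_group("m-3m")$symbol, "432")
})

test_that("epsilon factors match brute force on a grid", {
  H <- grid_hkl(3)
  for (sym in c("2", "222", "422", "32", "622", "23")) {
    pg <- point_group(sym)
    eps <- epsilon_factor(H, pg)
    idx <- seq(1, nrow(H), by = 7)     # spot-check a deterministic subsample
    for (i in idx) expect_equal(eps[i], brute_epsilon(H[i, ], pg), info = sym)
    # epsilon divides the group order, epsilon >= 1
    expect_true(all(eps >= 1))
    expect_true(all(length(pg$rotations) %% eps == 0))
  }
  expect_equal(epsilon_factor(c(1, 2, 3), point_group("422")), 1L)
  expect_equal(epsilon_factor(c(0, 0, 5), point_group("422")), 4L)
  expect_equal(epsilon_factor(c(0, 3, 0), point_group("2")), 2L)
})

test_that("centricity matches brute force and the classic cases", {
  expect_false(any(is_centric(grid_hkl(2), point_group("1"))))
  expect_true(is_centric(c(3, 0, 2), point_group("2")))   # h0l in b-unique 2
  H <- grid_hkl(4)
  pg <- point_group("422")
  cen <- is_centric(H, pg)
  brute <- vapply(seq_len(nrow(H)), function(i) brute_centric(H[i, ], pg), logical(1))
  expect_equal(cen, brute)
})

test_that("epsilon is constant on orbits and orbit size times epsilon is the group order", {
  H <- grid_hkl(3)
  for (sym in c("222", "422", "622")) {
    pg <- point_group(sym)
    eps <- epsilon_factor(H, pg)
    for (R in pg$rotations) {
      expect_equal(epsilon_factor(H %*% t(R), pg), eps, info = sym)
    }
    idx <- seq(1, nrow(H), by = 11)
    for (i in idx) {
      expect_equal(brute_orbit_size(H[i, ], pg) * eps[i], length(pg$rotations),
                   info = sym)
    }
  }
})

test_that("canonicalization is idempotent and orbit-invariant", {
  H <- grid_hkl(4)
  for (sym in c("2", "422", "32")) {
    pg <- point_group(sym)
    can <- canonical_asu(H, pg)
    expect_equal(canonical_asu(can, pg), can, info = sym)
    # the representative is identical across the orbit, Friedel included
    expect_equal(canonical_asu(-H, pg), can, info = sym)
    R <- pg$rotations[[length(pg$rotations)]]
    expect_equal(canonical_asu(H %*% t(R), pg), can, info = sym)
  }
})

test_that("subgroup enumeration agrees with the all-subsets oracle", {
  # literal all-subsets closure oracle for orders <= 12
  for (sym in c("222", "4", "32", "422")) {
    pg <- point_group(sym)
    oracle <- brute_all_subgroups(pg)
    n_classes <- brute_conjugacy_classes(oracle, pg)
    subs <- enumerate_proper_subgroups(pg)
    expect_equal(length(subs), n_classes, info = sym)
    # every reported subgroup is a group found by the oracle
    okeys <- vapply(oracle, function(g) {
      paste(sort(vapply(g, function(R) paste(R, collapse = ","), character(1))), collapse = "|")
    }, character(1))
    for (s in subs) {
      skey <- paste(sort(vapply(s$rotations, function(R) paste(R, collapse = ","), character(1))),
                    collapse = "|")
      expect_true(skey %in% okeys, info = paste(sym, s$label))
      expect_equal(length(pg$rotations) %% length(s$rotations), 0)
      expect_equal(s$index, length(pg$rotations) / length(s$rotations))
    }
  }
})

test_that("subgroup counts match the expected class structure", {
  # 422: {4}, two classes of {222}, three classes of {2}, {1}
  labs <- vapply(enumerate_proper_subgroups(point_group("422")),
                 function(s) s$label, character(1))
  expect_length(labs, 7)
  expect_equal(sum(grepl("^222", labs)), 2)
  expect_equal(sum(grepl("^2 ", labs)), 3)
  expect_equal(sum(grepl("^4 ", labs)), 1)
  expect_true("1" %in% labs)
  # 222 is abelian: all four proper subgroups are their own class
  expect_length(enumerate_proper_subgroups(point_group("222")), 4)
  # trivial parent has no proper subgroup
  expect_length(enumerate_proper_subgroups(point_group("1")), 0)
  # 432 ~ S4: 10 proper subgroup classes (textbook count for S4)
  expect_length(enumerate_proper_subgroups(point_group("432")), 10)
})

test_that("expansion to subgroups conserves information", {
  ds <- fixture_dataset_50()
  subs <- enumerate_proper_subgroups(ds$pg)
  # expansion to the trivial subgroup multiplies general reflections by the
  # index and maps back exactly
  sub1 <- subs[[which(vapply(subs, function(s) s$label, character(1)) == "1")]]
  expanded <- expand_to_subgroup(ds, sub1)
  expect_gt(n_refl(expanded), n_refl(ds))
  expect_true(paste0("expand:", sub1$label) %in% expanded$provenance)
  merged <- merge_to_parent(expanded, ds$pg)
  ord <- order(merged$hkl[, 1], merged$hkl[, 2], merged$hkl[, 3])
  ord0 <- order(ds$hkl[, 1], ds$hkl[, 2], ds$hkl[, 3])
  expect_equal(merged$hkl[ord, ], ds$hkl[ord0, ])
  expect_equal(merged$I[ord], ds$I[ord0])
  expect_equal(merged$sigI[ord], ds$sigI[ord0])
})

test_that("expansion multiplies unique counts by orbit ratios", {
  cell <- unit_cell(30, 30, 40)
  pg <- point_group("422")
  H <- canonical_asu(grid_hkl(4), pg)
  H <- H[!duplicated(paste(H[, 1], H[, 2], H[, 3])), ]
  ds <- refl_dataset(H, rexp(nrow(H)), rep(1, nrow(H)), cell, "422",
                     canonicalize = FALSE)
  subs <- enumerate_proper_subgroups(pg)
  lab2c <- which(vapply(subs, function(s) s$label, character(1)) == "2 along c")
  expanded <- expand_to_subgroup(ds, subs[[lab2c]])
  # general reflections multiply by the index (4); specials by their orbit
  # ratio: verify total against direct orbit counting
  n_expected <- sum(vapply(seq_len(nrow(H)), function(i) {
    orbit <- unique(t(vapply(pg$rotations, function(R) as.integer(R %*% H[i, ]), integer(3))))
    orbit_pm <- unique(rbind(orbit, -orbit))
    sub_can <- canonical_asu(orbit_pm, as_point_group(subs[[lab2c]]))
    nrow(unique(sub_can))
  }, numeric(1)))
  expect_equal(n_refl(expanded), n_expected)
  # twice-expanded equals once-expanded as sets: 422 -> 222 -> (2 along c)
  lab222 <- which(vapply(subs, function(s) s$label, character(1)) == "222 along c;a,b")
  mid <- expand_to_subgroup(ds, subs[[lab222]])
  subs2 <- enumerate_proper_subgroups(as_point_group(subs[[lab222]]))
  lab2c2 <- which(vapply(subs2, function(s) s$label, character(1)) == "2 along c")
  twice <- expand_to_subgroup(mid, subs2[[lab2c2]])
  key <- function(d) sort(paste(d$hkl[, 1], d$hkl[, 2], d$hkl[, 3], signif(d$I, 10)))
  expect_equal(key(twice), key(expanded))
})

test_that("axial absence screen issues the three verdicts", {
  cell <- unit_cell(30, 30, 40)
  # no axial reflections at all -> unmeasured
  H <- matrix(c(1, 2, 3, 2, 3, 4, 1, 1, 1), ncol = 3, byrow = TRUE)
  ds <- refl_dataset(H, c(10, 10, 10), c(1, 1, 1), cell, "1")
  expect_equal(score_axial_absences(ds, "c", 2)$verdict, "unmeasured")
  # simulated 2_1 axis: odd (0,0,l) at noise level -> absent
  l <- 1:10
  H <- cbind(0, 0, l)
  I <- ifelse(l %% 2 == 0, 500, 0.5)
  ds2 <- refl_dataset(rbind(H, matrix(c(1, 2, 3), 1)), c(I, 100), rep(1, 11), cell, "1")
  expect_equal(score_axial_absences(ds2, "c", 2)$verdict, "absent")
  # strong odd axials -> present
  ds3 <- refl_dataset(H, rep(500, 10), rep(1, 10), cell, "1")
  expect_equal(score_axial_absences(ds3, "c", 2)$verdict, "present")
})
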