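# Brute-force oracles shared across tests. These deliberately use the
# dumbest correct algorithm so they stay independent of the implementation
# paths they check.

# integer grid of Miller indices with |component| <= m, origin excluded
grid_hkl <- function(m) {
  H <- as.matrix(expand.grid(-m:m, -m:m, -m:m))
  unname(H[rowSums(H != 0) > 0, , drop = FALSE])
}

# brute-force epsilon: count rotations fixing h, one reflection at a time
brute_epsilon <- function(h, pg) {
  sum(vapply(pg$rotations, function(R) all(R %*% h == h), logical(1)))
}

brute_centric <- function(h, pg) {
  any(vapply(pg$rotations, function(R) all(R %*% h == -h), logical(1)))
}

# orbit of h under proper rotations only (no Friedel)
brute_orbit_size <- function(h, pg) {
  imgs <- vapply(pg$rotations, function(R) paste(R %*% h, collapse = ","), character(1))
  length(unique(imgs))
}

# all proper subgroups (as sorted element-key sets) by closing EVERY subset
# of non-identity elements; feasible for group order <= 12
rkey <- function(R) paste(as.integer(R), collapse = ",")
brute_all_subgroups <- function(pg) {
  rots <- pg$rotations
  n <- length(rots)
  stopifnot(n <= 12)
  nonid <- Filter(function(R) !all(R == diag(3L)), rots)
  m <- length(nonid)
  found <- character(0)
  groups <- list()
  for (mask in 0:(2^m - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    elems <- c(list(diag(3L)), nonid[sel])
    # naive closure
    repeat {
      keys <- vapply(elems, rkey, character(1))
      new <- list()
      for (a in elems) for (b in elems) {
        p <- a %*% b
        if (!(rkey(p) %in% keys)) { new <- c(new, list(p)); keys <- c(keys, rkey(p)) }
      }
      if (!length(new)) break
      elems <- c(elems, new)
      if (length(elems) > n) break
    }
    if (length(elems) > n || length(elems) == n) next
    key <- paste(sort(vapply(elems, rkey, character(1))), collapse = "|")
    if (!(key %in% found)) {
      found <- c(found, key)
      groups[[length(groups) + 1]] <- elems
    }
  }
  groups
}

# conjugacy-class count of a list of subgroups under the parent group
brute_conjugacy_classes <- function(groups, pg) {
  gkey <- function(g) paste(sort(vapply(g, rkey, character(1))), collapse = "|")
  keys <- vapply(groups, gkey, character(1))
  cls <- rep(NA_integer_, length(groups))
  nxt <- 0L
  for (i in seq_along(groups)) {
    if (!is.na(cls[i])) next
    nxt <- nxt + 1L
    cls[i] <- nxt
    for (R in pg$rotations) {
      conj <- lapply(groups[[i]], function(S) {
        M <- round(R %*% S %*% solve(R)); storage.mode(M) <- "integer"; M
      })
      j <- match(gkey(conj), keys)
      if (!is.na(j)) cls[j] <- nxt
    }
  }
  max(cls)
}

# a small canonical dataset for I/O tests: 50 deterministic records
fixture_dataset_50 <- function() {
  set.seed(101)
  cell <- unit_cell(30, 40, 50)
  H <- generate_grid_unique(cell, "222", 60)
  H <- H[seq_len(50), , drop = FALSE]
  refl_dataset(H, I = round(rexp(50) * 100, 4), sigI = round(runif(50, 1, 5), 4),
               cell = cell, laue_symbol = "222",
               spacegroup_symbol = "P212121", wavelength = 0.9795,
               provenance = c("aniso", "tncs:2"))
}

# unique canonical indices from a grid (helper for fixtures)
generate_grid_unique <- function(cell, laue, n_want, m = 6) {
  H <- grid_hkl(m)
  can <- canonical_asu(H, point_group(laue))
  can <- can[!duplicated(paste(can[, 1], can[, 2], can[, 3])), , drop = FALSE]
  can[seq_len(min(n_want, nrow(can))), , drop = FALSE]
}

# distributional z draws aligned with a synthetic binning, for stats tests
make_z_fixture <- function(n, centric = FALSE, alpha = 0, seed = 1) {
  set.seed(seed)
  draw <- function(k) if (centric) rnorm(k)^2 else rexp(k)
  z <- (1 - alpha) * draw(n) + alpha * draw(n)
  s2 <- runif(n, 0.01, 0.2)
  list(z = z, s2 = s2, binning = make_binning(s2))
}
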