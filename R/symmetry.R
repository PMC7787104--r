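# Point-group algebra on Miller indices.
#
# Merged intensities only feel the rotational part of the Laue class (Friedel
# symmetry is handled implicitly: the orbit of h always includes -h), so groups
# are represented as lists of 3x3 integer matrices acting on Miller index
# column vectors. Trigonal/hexagonal groups use the hexagonal-basis integer
# action.

rot_key <- function(R) paste(as.integer(R), collapse = ",")

mat3 <- function(...) matrix(as.integer(c(...)), 3, 3, byrow = TRUE)

# index-action generators for each supported symbol
pg_generator_table <- function() {
  I3 <- diag(3L)
  two_x <- mat3(1, 0, 0,  0, -1, 0,  0, 0, -1)
  two_y <- mat3(-1, 0, 0,  0, 1, 0,  0, 0, -1)
  two_z <- mat3(-1, 0, 0,  0, -1, 0,  0, 0, 1)
  four_z <- mat3(0, -1, 0,  1, 0, 0,  0, 0, 1)
  three_z_hex <- mat3(0, 1, 0,  -1, -1, 0,  0, 0, 1)   # (h,k,l) -> (k,-h-k,l)
  two_110_hex <- mat3(0, 1, 0,  1, 0, 0,  0, 0, -1)    # (h,k,l) -> (k,h,-l)
  three_111 <- mat3(0, 1, 0,  0, 0, 1,  1, 0, 0)       # (h,k,l) -> (k,l,h)
  list(
    "1"   = list(I3),
    "2"   = list(two_y),                    # b-unique convention
    "222" = list(two_x, two_z),
    "4"   = list(four_z),
    "422" = list(four_z, two_x),
    "3"   = list(three_z_hex),
    "32"  = list(three_z_hex, two_110_hex),
    "6"   = list(three_z_hex, two_z),
    "622" = list(three_z_hex, two_z, two_110_hex),
    "23"  = list(two_z, two_x, three_111),
    "432" = list(two_z, two_x, three_111, four_z)
  )
}

# close a set of integer rotation matrices under multiplication
group_closure <- function(gens) {
  elems <- list(diag(3L))
  names(elems) <- rot_key(diag(3L))
  queue <- gens
  while (length(queue) > 0) {
    R <- queue[[1]]; queue <- queue[-1]
    k <- rot_key(R)
    if (!is.null(elems[[k]])) next
    elems[[k]] <- R
    for (S in elems) {
      queue <- c(queue, list(R %*% S), list(S %*% R))
    }
  }
  if (length(elems) > 64) stop("group closure exceeded plausible point-group order")
  unname(elems[order(names(elems))])
}

# map Laue symbols and simple space-group symbols onto the supported set
normalize_pg_symbol <- function(symbol) {
  s <- gsub("\\s", "", symbol)
  laue_map <- c("-1" = "1", "2/m" = "2", "mmm" = "222", "4/m" = "4",
                "4/mmm" = "422", "-3" = "3", "-3m" = "32", "-3m1" = "32",
                "6/m" = "6", "6/mmm" = "622", "m-3" = "23", "m3" = "23",
                "m-3m" = "432", "m3m" = "432", "432" = "432", "23" = "23")
  if (s %in% names(laue_map)) return(unname(laue_map[s]))
  if (s %in% names(pg_generator_table())) return(s)
  # space-group-ish symbol: strip lattice letter, reduce screw axes
  if (grepl("^[PABCIFR]", s)) {
    core <- sub("^[PABCIFR]", "", s)
    sg_map <- c("1" = "1", "2" = "2", "21" = "2", "222" = "222",
                "212121" = "222", "21212" = "222", "2221" = "222",
                "4" = "4", "41" = "4", "42" = "4", "43" = "4",
                "422" = "422", "4122" = "422", "41212" = "422", "4212" = "422",
                "4322" = "422", "43212" = "422", "42212" = "422", "4222" = "422",
                "3" = "3", "31" = "3", "32" = "3", "321" = "32", "312" = "32",
                "3121" = "32", "3221" = "32", "3112" = "32", "3212" = "32",
                "6" = "6", "61" = "6", "62" = "6", "63" = "6", "64" = "6", "65" = "6",
                "622" = "622", "6122" = "622", "6222" = "622", "6322" = "622",
                "6422" = "622", "6522" = "622",
                "23" = "23", "213" = "23",
                "432" = "432", "4132" = "432", "4232" = "432", "4332" = "432")
    if (core %in% names(sg_map)) return(unname(sg_map[core]))
  }
  stop("unsupported point-group/Laue symbol: ", symbol)
}

#' Point group of a Hermann-Mauguin symbol
#'
#' Supported rotation groups (acting on Miller indices of merged data, Friedel
#' implicit): 1, 2 (b-unique), 222, 4, 422, 3, 32, 6, 622, 23, 432, their Laue
#' symbols (e.g. `4/mmm`) and simple space-group symbols (e.g. `P41212`).
#'
#' @param symbol Hermann-Mauguin text.
#' @return `point_group` object: list with `symbol` and `rotations` (list of
#'   3x3 integer matrices, closed under multiplication, identity included).
#' @export
point_group <- function(symbol) {
  if (inherits(symbol, "point_group")) return(symbol)
  sym <- normalize_pg_symbol(symbol)
  rots <- group_closure(pg_generator_table()[[sym]])
  structure(list(symbol = sym, rotations = rots), class = "point_group")
}

#' @export
print.point_group <- function(x, ...) {
  cat(sprintf("point group %s: %d rotations\n", x$symbol, length(x$rotations)))
  invisible(x)
}

# stack rotations into a 3D array for vectorized orbit work
rot_array <- function(pg) {
  rots <- if (inherits(pg, "point_group")) pg$rotations else pg
  array(unlist(rots), dim = c(3, 3, length(rots)))
}

# All images of the index rows of H under {+R, -R}: returns a list of n x 3
# matrices, one per signed rotation.
orbit_images <- function(H, pg) {
  rots <- if (inherits(pg, "point_group")) pg$rotations else pg
  out <- vector("list", 2L * length(rots))
  for (i in seq_along(rots)) {
    img <- H %*% t(rots[[i]])
    out[[2L * i - 1L]] <- img
    out[[2L * i]] <- -img
  }
  out
}

#' Canonical asymmetric-unit representative
#'
#' Maps each Miller triple to the lexicographically greatest member of its
#' orbit under the Laue group (proper rotations plus Friedel inversion).
#' Idempotent and group-agnostic.
#'
#' @param H n x 3 integer matrix of Miller indices (or a length-3 vector).
#' @param pg a [point_group()] (or symbol).
#' @return n x 3 integer matrix of canonical indices.
#' @export
canonical_asu <- function(H, pg) {
  pg <- point_group(pg)
  vec_in <- !is.matrix(H)
  if (vec_in) H <- matrix(H, 1, 3)
  storage.mode(H) <- "integer"
  imgs <- orbit_images(H, pg)
  # image components can reach 2*max|h| in the hexagonal basis; K must exceed
  # twice that for the base-K key to order lexicographically
  m <- max(abs(H), 1L)
  K <- 4 * m + 3
  keys <- vapply(imgs, function(img) (img[, 1] * K + img[, 2]) * K + img[, 3],
                 numeric(nrow(H)))
  keys <- matrix(keys, nrow = nrow(H))
  pick <- max.col(keys, ties.method = "first")
  out <- H
  for (j in seq_len(nrow(H))) out[j, ] <- imgs[[pick[j]]][j, ]
  storage.mode(out) <- "integer"
  if (vec_in) out else out
}

#' Symmetry-enhancement (epsilon) factor
#'
#' Number of point-group rotations fixing each reflection; scales the expected
#' intensity of reflections on symmetry axes.
#'
#' @inheritParams canonical_asu
#' @return integer vector of epsilon factors (>= 1, dividing the group order).
#' @export
epsilon_factor <- function(H, pg) {
  pg <- point_group(pg)
  if (!is.matrix(H)) H <- matrix(H, 1, 3)
  if (any(rowSums(H != 0) == 0)) stop("epsilon_factor: zero Miller index")
  eps <- integer(nrow(H))
  for (R in pg$rotations) {
    img <- H %*% t(R)
    eps <- eps + as.integer(rowSums(img == H) == 3L)
  }
  eps
}

#' Centric-reflection test
#'
#' A reflection is centric when some point-group rotation maps h to -h; its
#' phase is then restricted and its Wilson distribution is the squared normal.
#'
#' @inheritParams canonical_asu
#' @return logical vector.
#' @export
is_centric <- function(H, pg) {
  pg <- point_group(pg)
  if (!is.matrix(H)) H <- matrix(H, 1, 3)
  if (any(rowSums(H != 0) == 0)) stop("is_centric: zero Miller index")
  cen <- rep(FALSE, nrow(H))
  for (R in pg$rotations) {
    img <- H %*% t(R)
    cen <- cen | (rowSums(img == -H) == 3L)
  }
  cen
}

# --- subgroup machinery ------------------------------------------------------

# order of one rotation matrix
rotation_order <- function(R) {
  P <- R
  for (n in 1:6) {
    if (all(P == diag(3L))) return(n)
    P <- P %*% R
  }
  stop("element order exceeds 6: not a crystallographic rotation")
}

# smallest integer axis vector fixed by R (R of order > 1), deterministic scan
rotation_axis <- function(R) {
  cand <- expand.grid(l = -2:2, k = -2:2, h = -2:2)
  cand <- as.matrix(cand[, c("h", "k", "l")])
  cand <- cand[rowSums(cand != 0) > 0, , drop = FALSE]
  nr2 <- rowSums(cand^2)
  # sign convention: first nonzero component positive
  sgn <- sign(cand[, 1] * 4 + cand[, 2] * 2 + cand[, 3] * 1)
  sgn[sgn == 0] <- sign(rowSums(cand))[sgn == 0]
  ord <- order(nr2, cand[, 1] * -1, cand[, 2] * -1, cand[, 3] * -1)
  for (i in ord) {
    v <- cand[i, ]
    if (all(R %*% v == v)) {
      if (sum(v * c(4, 2, 1)) < 0) v <- -v
      g <- Reduce(function(a, b) if (b == 0) a else rotation_gcd(a, b), abs(v[v != 0]))
      return(as.integer(v / g))
    }
  }
  stop("no rotation axis found")
}

rotation_gcd <- function(a, b) if (b == 0) a else rotation_gcd(b, a %% b)

axis_name <- function(v) {
  letters3 <- c("a", "b", "c")
  parts <- character(0)
  for (i in 1:3) {
    if (v[i] == 0) next
    coef <- if (abs(v[i]) == 1) "" else as.character(abs(v[i]))
    sgn <- if (v[i] < 0 && length(parts) > 0) "-" else if (v[i] < 0) "-" else if (length(parts) > 0) "+" else ""
    parts <- c(parts, paste0(sgn, coef, letters3[i]))
  }
  paste(parts, collapse = "")
}

# Hermann-Mauguin-style symbol for an arbitrary rotation group (by structure)
classify_rotation_group <- function(rots) {
  n <- length(rots)
  ords <- vapply(rots, rotation_order, integer(1))
  if (n == 1) return("1")
  if (any(ords == n)) return(as.character(n))   # cyclic
  if (n == 4) return("222")
  if (n == 6) return("32")
  if (n == 8) return("422")
  if (n == 12) return(if (any(ords == 6)) "622" else "23")
  if (n == 24) return("432")
  stop("unrecognized rotation-group structure (order ", n, ")")
}

# deterministic class label, axis-direction aware: e.g. "2 along c",
# "222 along a,b,c", "4 along c", "23 standard"
subgroup_class_label <- function(rots) {
  sym <- classify_rotation_group(rots)
  if (sym == "1") return("1")
  ords <- vapply(rots, rotation_order, integer(1))
  top <- max(ords)
  if (sym %in% c("23", "432")) return(paste(sym, "standard"))
  if (sym %in% c("2", "3", "4", "6")) {
    ax <- rotation_axis(rots[[which(ords == top)[1]]])
    return(paste(sym, "along", axis_name(ax)))
  }
  # dihedral: principal axis first, then sorted 2-fold axes
  principal <- rotation_axis(rots[[which(ords == top)[1]]])
  twofolds <- unique(vapply(rots[ords == 2], function(R) axis_name(rotation_axis(R)),
                            character(1)))
  twofolds <- setdiff(twofolds, axis_name(principal))
  paste0(sym, " along ", axis_name(principal), ";", paste(sort(twofolds), collapse = ","))
}

# close an element subset; returns NULL if closure exceeds the parent order
close_subset <- function(elems, parent_n) {
  grp <- group_closure(elems)
  if (length(grp) > parent_n) return(NULL)
  grp
}

#' Enumerate proper subgroups of a point group
#'
#' Exhaustive: every subgroup of the supported groups is generated by at most
#' two elements; closures of all element subsets of size up to three are taken
#' for margin and deduplicated. Direction-distinct (conjugate) subgroups are
#' reported separately, each with a class label naming its axes.
#'
#' @param pg a [point_group()].
#' @return list of `subgroup_descriptor` objects, sorted by descending group
#'   order then class label. The trivial subgroup is included (except for the
#'   trivial parent, which has none).
#' @export
enumerate_proper_subgroups <- function(pg) {
  pg <- point_group(pg)
  rots <- pg$rotations
  n <- length(rots)
  if (n == 1) return(list())
  nonid <- Filter(function(R) !all(R == diag(3L)), rots)
  seen <- new.env(parent = emptyenv())
  add <- function(grp) {
    key <- paste(sort(vapply(grp, rot_key, character(1))), collapse = "|")
    if (!is.null(seen[[key]])) return(invisible(NULL))
    seen[[key]] <- grp
  }
  add(list(diag(3L)))
  m <- length(nonid)
  for (i in seq_len(m)) {
    g1 <- close_subset(nonid[i], n); if (!is.null(g1)) add(g1)
    if (i < m) for (j in seq((i + 1), m)) {
      g2 <- close_subset(nonid[c(i, j)], n); if (!is.null(g2)) add(g2)
      if (j < m && m <= 24) for (k in seq((j + 1), m)) {
        g3 <- close_subset(nonid[c(i, j, k)], n); if (!is.null(g3)) add(g3)
      }
    }
  }
  subs <- as.list(seen)
  subs <- Filter(function(grp) length(grp) < n, subs)
  # one representative per conjugacy class under the parent: conjugate
  # subgroups (e.g. 2 along a and 2 along b inside 422) are the same
  # hypothesis up to relabelling of axes
  grp_key <- function(grp) paste(sort(vapply(grp, rot_key, character(1))), collapse = "|")
  keys <- vapply(subs, grp_key, character(1))
  class_of <- rep(NA_integer_, length(subs))
  next_class <- 0L
  inv <- lapply(rots, function(R) solve(R))
  for (i in seq_along(subs)) {
    if (!is.na(class_of[i])) next
    next_class <- next_class + 1L
    class_of[i] <- next_class
    for (g in seq_along(rots)) {
      conj <- lapply(subs[[i]], function(S) {
        Sg <- round(rots[[g]] %*% S %*% inv[[g]])
        storage.mode(Sg) <- "integer"
        Sg
      })
      j <- match(grp_key(conj), keys)
      if (!is.na(j)) class_of[j] <- next_class
    }
  }
  # representative: lexicographically smallest class label within each class
  labels <- vapply(subs, function(grp) subgroup_class_label(grp), character(1))
  reps <- vapply(split(seq_along(subs), class_of), function(ix) ix[order(labels[ix])][1],
                 integer(1))
  subs <- subs[sort(reps)]
  descs <- lapply(subs, function(grp) {
    structure(list(parent = pg$symbol,
                   rotations = grp,
                   index = n / length(grp),
                   label = subgroup_class_label(grp)),
              class = "subgroup_descriptor")
  })
  ord <- order(-vapply(descs, function(d) length(d$rotations), numeric(1)),
               vapply(descs, function(d) d$label, character(1)))
  unname(descs[ord])
}

#' @export
print.subgroup_descriptor <- function(x, ...) {
  cat(sprintf("subgroup [%s] of %s, index %d, %d rotations\n",
              x$label, x$parent, x$index, length(x$rotations)))
  invisible(x)
}

# subgroup_descriptor behaves as a group for canonicalization purposes
as_point_group <- function(x) {
  if (inherits(x, "point_group")) return(x)
  if (inherits(x, "subgroup_descriptor")) {
    return(structure(list(symbol = classify_rotation_group(x$rotations),
                          rotations = x$rotations),
                     class = "point_group"))
  }
  point_group(x)
}
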