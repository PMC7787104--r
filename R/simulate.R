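# Synthetic-pathology generators with known ground truth.
#
# Two levels are provided. simulate_wilson_data() draws normalized intensities
# straight from the Wilson distributions (exponential acentric, squared-normal
# centric) with optional twin mixing — the stated world for the second-moment
# calibration targets. simulate_dataset() is atomistic: point scatterers,
# TNCS copies, direct structure-factor summation, anisotropic attenuation,
# twin mixing and Gaussian noise — used wherever the pathology must live in
# actual Miller indices (Patterson/TNCS/anisotropy recovery, end-to-end runs).
# Point atoms carry no form factor and no solvent; that is a documented
# limitation, sufficient for intensity statistics.

# run code with a local RNG state fully determined by `seed`
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

#' Distribution-level Wilson intensity simulator
#'
#' Draws reflections with uniform-in-volume reciprocal radii, a smooth
#' isotropic falloff `Sigma(s) = K exp(-B_iso s^2 / 2)`, Wilson-distributed
#' true intensities, optional twin mixing `(1-alpha) I1 + alpha I2` with an
#' independent partner of the same class and resolution, and Gaussian
#' measurement noise.
#'
#' @param n_acentric,n_centric class sizes.
#' @param alpha twin fraction in `[0, 0.5]`; 0.5 is a perfect twin.
#' @param d_min,d_max resolution window in Angstrom.
#' @param B_iso isotropic falloff in square Angstrom (default 25, a typical
#'   protein Wilson B).
#' @param K scale of the mean-intensity curve.
#' @param noise_frac measurement sigma as a fraction of `Sigma(s)` (default
#'   0.05, a mid-range counting error).
#' @param seed integer seed; the draw is fully determined by it.
#' @return list with `s2`, `centric` (logical), `I`, `sigI`, `Sigma_true`,
#'   `z_true` (noise-free normalized intensities) and the arguments in
#'   `truth`.
#' @export
simulate_wilson_data <- function(n_acentric, n_centric = 0, alpha = 0,
                                 d_min = 1.8, d_max = 30, B_iso = 25,
                                 K = 100, noise_frac = 0.05, seed = 1) {
  stopifnot(alpha >= 0, alpha <= 0.5)
  n <- n_acentric + n_centric
  with_seed(seed, {
    s3 <- runif(n, (1 / d_max)^3, (1 / d_min)^3)
    s2 <- s3^(2 / 3)
    centric <- c(rep(FALSE, n_acentric), rep(TRUE, n_centric))
    Sigma <- K * exp(-B_iso * s2 / 2)
    draw <- function(cen, k) ifelse(cen, rnorm(k)^2, rexp(k))
    z1 <- draw(centric, n)
    z2 <- draw(centric, n)
    z <- (1 - alpha) * z1 + alpha * z2
    Itrue <- z * Sigma
    sigI <- noise_frac * Sigma
    I <- Itrue + rnorm(n, 0, sigI)
    list(s2 = s2, centric = centric, I = I, sigI = sigI,
         Sigma_true = Sigma, z_true = z,
         truth = list(alpha = alpha, B_iso = B_iso, K = K,
                      noise_frac = noise_frac, seed = seed))
  })
}

#' Ground-truth description for the atomistic simulator
#'
#' Defaults are the stated conditions of the synthetic world: a mid-size
#' primitive cell, 50 point atoms per asymmetric unit, no pathology, 2 percent
#' noise, data to 2.5 Angstrom.
#'
#' @param seed integer seed (fully determines the dataset).
#' @param cell a [unit_cell()].
#' @param laue Laue/point-group symbol of the crystal symmetry used in the
#'   structure-factor summation.
#' @param n_atoms point scatterers per asymmetric unit.
#' @param B_true symmetric 3x3 anisotropy tensor (square Angstrom, traceless
#'   part is what the analysis recovers); intensity attenuated by
#'   `exp(-0.5 s' B s)`.
#' @param tncs list `m` (order, 1 = none), `t` (fractional translation),
#'   `sigma_rmsd` (Angstrom scatter between copies), `f0` (fraction of
#'   scattering related by TNCS at zero angle), `rot` (degrees, order-2
#'   rotation about an axis orthogonal to t).
#' @param twin list `alpha` (fraction) and optional `perm` (index permutation
#'   of the unique list; random derangement when omitted).
#' @param noise_frac measurement sigma as a fraction of the shell mean.
#' @param d_min high-resolution limit in Angstrom.
#' @return list of class `simulation_truth`.
#' @export
simulation_truth <- function(seed = 1,
                             cell = unit_cell(45, 55, 65),
                             laue = "1",
                             n_atoms = 50,
                             B_true = matrix(0, 3, 3),
                             tncs = list(m = 1, t = c(0, 0, 0), sigma_rmsd = 0,
                                         f0 = 1, rot = 0),
                             twin = list(alpha = 0, perm = NULL),
                             noise_frac = 0.02,
                             d_min = 2.5) {
  tncs <- utils::modifyList(list(m = 1, t = c(0, 0, 0), sigma_rmsd = 0, f0 = 1, rot = 0), tncs)
  twin <- utils::modifyList(list(alpha = 0, perm = NULL), twin)
  stopifnot(tncs$m >= 1, twin$alpha >= 0, twin$alpha <= 0.5,
            tncs$f0 >= 0, tncs$f0 <= 1, n_atoms >= 1, d_min > 0)
  structure(list(seed = seed, cell = cell, laue = laue, n_atoms = n_atoms,
                 B_true = B_true, tncs = tncs, twin = twin,
                 noise_frac = noise_frac, d_min = d_min),
            class = "simulation_truth")
}

# all canonical unique Miller indices with d in [d_min, d_max]
generate_miller_set <- function(cell, pg, d_min, d_max = Inf) {
  pg <- as_point_group(pg)
  hmax <- ceiling(cell$a / d_min) + 1L
  kmax <- ceiling(cell$b / d_min) + 1L
  lmax <- ceiling(cell$c / d_min) + 1L
  H <- unname(as.matrix(expand.grid(-hmax:hmax, -kmax:kmax, -lmax:lmax)))
  H <- H[rowSums(H != 0) > 0, , drop = FALSE]
  s2 <- s2_of(H, cell)
  keep <- s2 <= (1 / d_min)^2 & s2 >= (1 / d_max)^2
  H <- H[keep, , drop = FALSE]
  can <- canonical_asu(H, pg)
  can[!duplicated(paste(can[, 1], can[, 2], can[, 3])), , drop = FALSE]
}

#' Atomistic synthetic dataset
#'
#' Places point scatterers, replicates TNCS copies with coordinate scatter
#' and optional order-2 rotation, computes structure factors by direct
#' summation over the symmetry-expanded atom list, applies anisotropic
#' attenuation, twin mixing and Gaussian noise, and returns a canonical
#' merged dataset plus the generating truth.
#'
#' @param truth a [simulation_truth()].
#' @return list with `dataset` (a [refl_dataset()]) and `truth`.
#' @export
simulate_dataset <- function(truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  with_seed(truth$seed, {
    cell <- truth$cell
    pg <- point_group(truth$laue)
    tn <- truth$tncs
    m <- tn$m
    # base motif, fractional coords
    X <- matrix(runif(3 * truth$n_atoms), ncol = 3)
    Oinv <- solve(cell$O)
    copies <- vector("list", m)
    for (k in seq_len(m)) {
      Xi <- X
      # a fraction 1 - f0 of the scattering is unrelated between copies
      if (k > 1 && tn$f0 < 1) {
        unrelated <- runif(truth$n_atoms) > tn$f0
        Xi[unrelated, ] <- matrix(runif(3 * sum(unrelated)), ncol = 3)
      }
      # coordinate scatter: total rms deviation sigma_rmsd, Cartesian
      if (k > 1 && tn$sigma_rmsd > 0) {
        noise_cart <- matrix(rnorm(3 * truth$n_atoms, 0, tn$sigma_rmsd / sqrt(3)), ncol = 3)
        Xi <- Xi + noise_cart %*% t(Oinv)
      }
      # order-2 rotational difference about an axis orthogonal to t
      if (k == 2 && m == 2 && tn$rot != 0) {
        axis <- orthogonal_axis(tn$t, cell)
        Rm <- axis_angle_matrix(axis, tn$rot * pi / 180)
        cen <- colMeans(Xi)
        Xc <- sweep(Xi, 2, cen) %*% t(cell$O)      # Cartesian, centred
        Xi <- sweep(Xc %*% t(Rm) %*% t(Oinv), 2, cen, `+`)
      }
      copies[[k]] <- Xi + matrix(rep((k - 1) * tn$t, each = truth$n_atoms), ncol = 3)
    }
    atoms <- do.call(rbind, copies)
    H <- generate_miller_set(cell, pg, truth$d_min)
    # direct summation over the symmetry-expanded atom list; coordinate
    # action of an index matrix R is t(R)
    Fc <- complex(real = rep(0, nrow(H)), imaginary = rep(0, nrow(H)))
    # coordinate action of the symmetry: W = t(R) (so that indices h and R h
    # are equivalent, and I(R h) = I(h) holds exactly)
    for (R in pg$rotations) {
      phase <- 2 * pi * (H %*% t(R) %*% t(atoms))
      Fc <- Fc + rowSums(exp(1i * phase))
    }
    I <- Mod(Fc)^2
    # anisotropic attenuation exp(-0.5 s' B s)
    sv <- H %*% t(cell$M)
    q <- rowSums((sv %*% truth$B_true) * sv)
    I <- I * exp(-0.5 * q)
    # twin mixing across an index permutation
    alpha <- truth$twin$alpha
    if (alpha > 0) {
      perm <- truth$twin$perm %||% sample(nrow(H))
      I <- (1 - alpha) * I + alpha * I[perm]
    }
    # noise scaled to the shell mean
    s2 <- rowSums(sv * sv)
    binning <- make_binning(s2, nbins = 20, min_per_bin = min(50, nrow(H)))
    shell_mean <- vapply(seq_len(binning$nbins),
                         function(b) mean(I[binning$bin == b]), numeric(1))
    sigI <- truth$noise_frac * shell_mean[binning$bin]
    I <- I + rnorm(nrow(H), 0, sigI)
    ds <- refl_dataset(H, I, sigI, cell, truth$laue, canonicalize = FALSE,
                       provenance = "simulated")
    list(dataset = ds, truth = truth)
  })
}

# unit Cartesian axis orthogonal to the fractional translation t
orthogonal_axis <- function(t_frac, cell) {
  tc <- as.numeric(cell$O %*% t_frac)
  if (all(tc == 0)) return(c(1, 0, 0))
  tc <- tc / sqrt(sum(tc^2))
  trial <- if (abs(tc[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  ax <- trial - sum(trial * tc) * tc
  ax / sqrt(sum(ax^2))
}

axis_angle_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  cs <- cos(angle); sn <- sin(angle)
  Kx <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sn * Kx + (1 - cs) * (Kx %*% Kx)
}

#' Worked-example preset: sevenfold TNCS with tetartohedral twinning
#'
#' Emulates the pathology of a tetragonal crystal whose true symmetry is a
#' twofold but whose perfectly (tetartohedrally) twinned intensities merge in
#' 422: seven TNCS copies along c, moderate 4/mmm-compatible anisotropy.
#' Built by simulating the twofold crystal and re-merging into the 422
#' canonical ASU, which averages the four twin-domain intensities exactly
#' (perfect twinning, alpha = 0.25 per domain).
#'
#' @param seed integer seed.
#' @return list with `dataset` (Laue 4/mmm merged) and `truth`.
#' @export
scenario_4n3e <- function(seed = 1) {
  truth <- simulation_truth(
    seed = seed,
    cell = unit_cell(36, 36, 77),
    laue = "2",                       # true crystal twofold, a subgroup of 422
    n_atoms = 30,
    B_true = diag(c(2, 2, -4)),       # 4/mmm-compatible, traceless
    tncs = list(m = 7, t = c(0, 0, 1 / 7), sigma_rmsd = 0.4, f0 = 0.9, rot = 0),
    twin = list(alpha = 0.25),        # tetartohedral: emulated by 422 merging
    noise_frac = 0.02,
    d_min = 3.2
  )
  # twinning is produced by the merge, not the permutation path
  truth$twin$alpha <- 0
  sim <- simulate_dataset(truth)
  merged <- merge_to_parent(sim$dataset, point_group("422"))
  merged$laue_symbol <- "422"
  merged$provenance <- c("simulated", "tetartohedral-merge")
  truth$twin$alpha <- 0.25
  list(dataset = merged, truth = truth)
}
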