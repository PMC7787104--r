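# Maximum-likelihood anisotropic scaling.
#
# Intensities are modelled with mean mu(h) = eps_sym * eps_tncs * A(h) *
# Sigma(s), A(h) = exp(-0.5 s' B s) with s = M h, B a traceless symmetric
# tensor constrained to the Laue class (the isotropic part is absorbed into
# Sigma(s)). Acentric reflections are exponential, centric half-Gaussian in
# intensity. Refinement is quasi-Newton (BFGS) over the coefficients on the
# symmetry-allowed tensor basis, alternating with Sigma re-estimation, with a
# harmonic restraint toward zero that switches on when the low-resolution
# data are too sparse to anchor the tensor.

# orthonormal basis (Frobenius) of the symmetric 3x3 matrices
sym_basis6 <- function() {
  r2 <- 1 / sqrt(2)
  list(diag(c(1, 0, 0)), diag(c(0, 1, 0)), diag(c(0, 0, 1)),
       matrix(c(0, r2, 0, r2, 0, 0, 0, 0, 0), 3, 3),
       matrix(c(0, 0, r2, 0, 0, 0, r2, 0, 0), 3, 3),
       matrix(c(0, 0, 0, 0, 0, r2, 0, r2, 0), 3, 3))
}

#' Symmetry-constrained anisotropy tensor basis
#'
#' Orthonormal basis of the traceless symmetric tensors invariant under every
#' Laue rotation (expressed in the orthogonal frame): 5 for Laue -1, 3 for
#' 2/m, 2 for mmm, 1 for tetragonal/trigonal/hexagonal classes, 0 for cubic
#' (isotropy forced).
#'
#' @param pg a [point_group()].
#' @param cell a [unit_cell()] compatible with the symmetry.
#' @return list of symmetric 3x3 matrices (possibly empty).
#' @export
constrained_basis <- function(pg, cell) {
  pg <- as_point_group(pg)
  Minv <- solve(cell$M)
  E <- sym_basis6()
  # rows: for each group element g and basis index j, vec(Q E_j Q') in the
  # 6-basis minus E_j; nullspace = invariant tensors; add the trace row
  proj <- function(S) vapply(E, function(Ej) sum(S * Ej), numeric(1))
  rows <- list()
  for (R in pg$rotations) {
    Q <- cell$M %*% R %*% Minv          # action on reciprocal vectors s
    A <- vapply(seq_along(E), function(j) proj(Q %*% E[[j]] %*% t(Q)), numeric(6))
    rows[[length(rows) + 1]] <- t(A) - diag(6)
  }
  tr_row <- matrix(proj(diag(3)), 1, 6)
  Mfull <- rbind(do.call(rbind, lapply(rows, t)), tr_row)
  sv <- svd(Mfull, nu = 0)
  null_ix <- which(sv$d < 1e-9 * max(sv$d, 1))
  ns <- sv$v[, null_ix, drop = FALSE]
  if (ncol(ns) == 0) return(list())
  # orthonormal already (svd V columns); map back to matrices
  lapply(seq_len(ncol(ns)), function(j) {
    Bj <- Reduce(`+`, Map(function(c, Ej) c * Ej, ns[, j], E))
    (Bj + t(Bj)) / 2
  })
}

aniso_tensor_from_coef <- function(coef, basis) {
  if (length(basis) == 0 || length(coef) == 0) return(matrix(0, 3, 3))
  Reduce(`+`, Map(function(c, Bj) c * Bj, coef, basis))
}

# per-reflection intensity attenuation A(h) = exp(-0.5 s' B s)
aniso_factor <- function(H, cell, B) {
  sv <- H %*% t(cell$M)
  exp(-0.5 * rowSums((sv %*% B) * sv))
}

#' Wilson log-likelihood of intensities
#'
#' Sum over reflections of the log Wilson density with mean
#' `mu = factors * A(h) * Sigma(s)`: exponential for acentric, half-Gaussian
#' intensity density for centric. Non-positive intensities are skipped (the
#' count is attached as attribute `n_skipped`); larger is better.
#'
#' @param I intensities.
#' @param mu positive expected intensities.
#' @param centric logical vector.
#' @return scalar log-likelihood with attribute `n_skipped`.
#' @export
wilson_loglik <- function(I, mu, centric) {
  ok <- is.finite(I) & I > 0 & is.finite(mu) & mu > 0
  Is <- ifelse(ok, I, 1); mus <- ifelse(ok, mu, 1)   # placeholders, masked below
  ll_ac <- -log(mus) - Is / mus
  ll_ce <- -0.5 * log(2 * pi * Is * mus) - Is / (2 * mus)
  ll <- ifelse(centric, ll_ce, ll_ac)
  out <- sum(ll[ok])
  attr(out, "n_skipped") <- sum(!ok)
  out
}

# loglik of a coefficient vector given fixed Sigma state (internal objective)
aniso_objective <- function(coef, basis, H, cell, I, centric, eps, Sigma_of_bin,
                            bin, restraint_w) {
  B <- aniso_tensor_from_coef(coef, basis)
  A <- aniso_factor(H, cell, B)
  mu <- eps * A * Sigma_of_bin[bin]
  ll <- as.numeric(wilson_loglik(I, mu, centric))
  ll - restraint_w * sum(coef^2)
}

#' Refine the anisotropic scale tensor
#'
#' BFGS maximization of the Wilson log-likelihood over the constrained tensor
#' coefficients, alternating with re-estimation of the mean-intensity curve,
#' until the coefficient gradient norm falls below `tol` or `max_cycles`
#' alternations. When fewer than 100 reflections lie below s = 0.1 per
#' Angstrom, a harmonic restraint with weight `0.01 * (100 - n_lowres)` per
#' Angstrom^4 pulls the coefficients toward zero (sparse low-resolution data
#' cannot anchor the tensor).
#'
#' @param dataset a [refl_dataset()].
#' @param binning optional [make_binning()] on the dataset's s2.
#' @param tncs_eps optional per-reflection TNCS expected-intensity factors.
#' @param tol gradient-norm convergence target (default 1e-4).
#' @param max_cycles alternation cap (default 100).
#' @return list with `B` (traceless symmetric tensor, Angstrom^2), `coef`,
#'   `basis`, `state` (final [estimate_sigma_curve()] result computed on
#'   corrected intensities), `converged`, `loglik`, `corrected` (the dataset
#'   with I and sigI divided by A(h)).
#' @export
refine_anisotropy <- function(dataset, binning = NULL, tncs_eps = NULL,
                              tol = 1e-4, max_cycles = 100L) {
  stopifnot(inherits(dataset, "refl_dataset"))
  if (n_refl(dataset) < 500) stop("refine_anisotropy: need at least 500 reflections")
  H <- dataset$hkl; cell <- dataset$cell
  s2 <- s2_of(H, cell)
  binning <- binning %||% make_binning(s2)
  eps_sym <- epsilon_factor(H, dataset$pg)
  centric <- is_centric(H, dataset$pg)
  eps <- eps_sym * (tncs_eps %||% rep(1, n_refl(dataset)))
  basis <- constrained_basis(dataset$pg, cell)
  n_lowres <- sum(sqrt(s2) < 0.1)
  restraint_w <- max(0, 100 - n_lowres) * 0.01
  coef <- rep(0, length(basis))
  converged <- length(basis) == 0
  ll <- NA_real_
  for (cycle in seq_len(max_cycles)) {
    B <- aniso_tensor_from_coef(coef, basis)
    A <- aniso_factor(H, cell, B)
    st <- estimate_sigma_curve(dataset$I, binning, factors = eps * A,
                               centric = centric)
    if (length(basis) == 0) { ll <- NA_real_; break }
    obj <- function(cf) -aniso_objective(cf, basis, H, cell, dataset$I, centric,
                                         eps, st$Sigma, binning$bin, restraint_w)
    fit <- optim(coef, obj, method = "BFGS",
                 control = list(maxit = 200, reltol = 1e-12))
    g <- numeric(length(coef))
    h_fd <- 1e-5
    for (j in seq_along(coef)) {
      cp <- fit$par; cp[j] <- cp[j] + h_fd
      cm <- fit$par; cm[j] <- cm[j] - h_fd
      g[j] <- (obj(cp) - obj(cm)) / (2 * h_fd)
    }
    moved <- sqrt(sum((fit$par - coef)^2))
    coef <- fit$par
    ll <- -fit$value
    if (sqrt(sum(g^2)) < tol * max(1, abs(ll)) || moved < 1e-8) { converged <- TRUE; break }
  }
  B <- aniso_tensor_from_coef(coef, basis)
  corrected <- apply_correction(dataset, B)
  A <- aniso_factor(H, cell, B)
  st <- estimate_sigma_curve(corrected$I, binning, factors = eps, centric = centric)
  list(B = B, coef = coef, basis = basis, state = st, converged = converged,
       loglik = ll, corrected = corrected)
}

#' Apply (or remove) an anisotropic correction
#'
#' Divides I and sigI by `A(h) = exp(-0.5 s' B s)`; applying `B` then `-B`
#' restores the input exactly. Provenance label `aniso` is appended.
#'
#' @param dataset a [refl_dataset()].
#' @param B symmetric 3x3 tensor in square Angstrom.
#' @return corrected [refl_dataset()].
#' @export
apply_correction <- function(dataset, B) {
  A <- aniso_factor(dataset$hkl, dataset$cell, B)
  out <- dataset
  out$I <- dataset$I / A
  out$sigI <- dataset$sigI / A
  out$provenance <- c(dataset$provenance, "aniso")
  out
}
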