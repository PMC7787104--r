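#' Unit-cell constructor
#'
#' Builds a unit cell from its six parameters and derives the reciprocal-space
#' orthogonalization matrix `M` such that `M %*% h` is the reciprocal vector of
#' the Miller triple `h` in inverse Angstrom, so `|M h| = 1/d(h)`.
#'
#' @param a,b,c cell edge lengths in Angstrom, all positive.
#' @param alpha,beta,gamma cell angles in degrees, each in (0, 180).
#' @return An object of class `unit_cell`: a list with the six parameters, the
#'   real-space metric tensor `G`, its inverse `Gstar`, the reciprocal
#'   orthogonalization matrix `M` (upper triangular, `t(M) %*% M == Gstar`),
#'   the real-space fractional-to-Cartesian matrix `O` and the cell volume.
#' @examples
#' cl <- unit_cell(40, 40, 40)
#' resolution(c(0, 0, 4), cl)$d  # 10 Angstrom
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  p <- c(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(p))) stop("unit_cell: non-finite parameter")
  if (any(p[1:3] <= 0)) stop("unit_cell: cell lengths must be positive")
  if (any(p[4:6] <= 0 | p[4:6] >= 180)) stop("unit_cell: cell angles must lie in (0, 180)")
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180); cg <- cos(gamma * pi / 180)
  G <- matrix(c(a * a,     a * b * cg, a * c * cb,
                a * b * cg, b * b,     b * c * ca,
                a * c * cb, b * c * ca, c * c), 3, 3)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("unit_cell: metric tensor not positive definite")
  Gstar <- solve(G)
  M <- chol(Gstar)                      # upper triangular, t(M) M = Gstar
  # real-space orthogonalization (fractional -> Cartesian): O = t(chol(G))
  O <- t(chol(G))
  structure(list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
                 G = G, Gstar = Gstar, M = M, O = O,
                 volume = sqrt(det(G))),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell %.3f %.3f %.3f Angstrom, %.2f %.2f %.2f deg, V = %.1f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

#' Resolution of one or more reflections
#'
#' @param h integer Miller triple (length-3 vector) or an n x 3 matrix of triples.
#' @param cell a [unit_cell()].
#' @return list with `d` (Angstrom) and `s` (= 1/d, inverse Angstrom); vectors
#'   when `h` is a matrix.
#' @export
resolution <- function(h, cell) {
  stopifnot(inherits(cell, "unit_cell"))
  H <- if (is.matrix(h)) h else matrix(h, 1, 3)
  if (any(rowSums(H != 0) == 0)) stop("resolution: zero Miller index")
  sv <- H %*% t(cell$M)                 # rows are M h
  s <- sqrt(rowSums(sv * sv))
  list(d = as.numeric(1 / s), s = as.numeric(s))
}

# s^2 for a matrix of indices (no zero check; internal hot path)
s2_of <- function(H, cell) {
  sv <- H %*% t(cell$M)
  rowSums(sv * sv)
}
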