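# Wilson normalization and intensity statistics.
#
# The normalized intensity z = I / (eps_sym * eps_tncs * A * Sigma(s)) should
# be unit-mean exponential for acentric reflections and unit-mean squared
# normal for centric ones; departures of the second moment <z^2>/<z>^2 from
# 2 (acentric) / 3 (centric) diagnose twinning (1.5 / 2 when perfect) and
# uncorrected TNCS (> 2).

#' Equal-count resolution binning
#'
#' @param s2 vector of squared reciprocal resolutions (1/d^2, inverse square
#'   Angstrom).
#' @param nbins target number of bins (default 20).
#' @param min_per_bin minimum reflections per bin; the bin count is reduced
#'   until every bin holds at least this many (default 50).
#' @return object of class `binning`: list with `edges` (bin boundaries in
#'   s2), `bin` (bin index per reflection), `nbins`.
#' @export
make_binning <- function(s2, nbins = 20, min_per_bin = 50) {
  n <- length(s2)
  if (n == 0) stop("make_binning: no reflections")
  nbins <- max(1L, min(as.integer(nbins), n %/% max(1L, as.integer(min_per_bin))))
  if (nbins <= 1L) {
    return(structure(list(edges = range(s2), bin = rep(1L, n), nbins = 1L),
                     class = "binning"))
  }
  qs <- stats::quantile(s2, probs = seq(0, 1, length.out = nbins + 1), names = FALSE,
                        type = 1)
  qs[1] <- -Inf; qs[nbins + 1] <- Inf
  qs <- unique(qs)
  bin <- findInterval(s2, qs, rightmost.closed = TRUE, left.open = TRUE)
  bin[bin == 0L] <- 1L
  # merge any bin that ended up underfull with its lower neighbour
  repeat {
    counts <- tabulate(bin, nbins = max(bin))
    small <- which(counts > 0 & counts < min_per_bin)
    if (!length(small) || max(bin) == 1L) break
    b <- small[1]
    bin[bin == b] <- if (b == 1L) 2L else b - 1L
    bin <- match(bin, sort(unique(bin)))
  }
  bin <- match(bin, sort(unique(bin)))
  structure(list(edges = qs, bin = as.integer(bin), nbins = max(bin)),
            class = "binning")
}

#' Iterated estimation of the mean-intensity curve Sigma(s)
#'
#' Per-bin mean of I over the applied expected-intensity factors, iterated
#' jointly with outlier masking to a fixed point. The result is the
#' normalization state used by every downstream likelihood.
#'
#' @param I intensities.
#' @param binning a [make_binning()] result on the matching s2 values.
#' @param factors positive per-reflection expected-intensity factors
#'   (eps_sym * eps_tncs * anisotropy); default all 1.
#' @param p_cut outlier rejection probability passed to [reject_outliers()];
#'   `NULL` disables masking.
#' @param centric logical vector (needed when `p_cut` is not `NULL`).
#' @param tol,max_iter fixed-point tolerance on max |dSigma|/Sigma and
#'   iteration cap.
#' @return object of class `norm_state`: list with `Sigma` (per-bin curve),
#'   `z` (normalized intensities), `factors`, `binning`, `mask` (TRUE = kept),
#'   `iterations`, `converged`.
#' @export
estimate_sigma_curve <- function(I, binning, factors = NULL, p_cut = 1e-6,
                                 centric = NULL, tol = 1e-6, max_iter = 20L) {
  n <- length(I)
  stopifnot(inherits(binning, "binning"), length(binning$bin) == n)
  factors <- factors %||% rep(1, n)
  if (any(!is.finite(factors)) || any(factors <= 0)) stop("factors must be positive")
  if (!is.null(p_cut) && is.null(centric)) centric <- rep(FALSE, n)
  bin <- binning$bin
  corr <- I / factors
  mask <- rep(TRUE, n)
  Sigma <- rep(NA_real_, binning$nbins)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    Sg <- vapply(seq_len(binning$nbins), function(b) {
      sel <- bin == b & mask
      if (!any(sel)) return(NA_real_)
      mean(corr[sel])
    }, numeric(1))
    # empty bins borrow the nearest populated neighbour
    if (anyNA(Sg)) {
      ok <- which(!is.na(Sg))
      for (b in which(is.na(Sg))) Sg[b] <- Sg[ok[which.min(abs(ok - b))]]
    }
    if (any(Sg <= 0)) Sg[Sg <= 0] <- min(Sg[Sg > 0])
    delta <- if (all(is.na(Sigma))) Inf else max(abs(Sg - Sigma) / Sg)
    Sigma <- Sg
    z <- corr / Sigma[bin]
    if (!is.null(p_cut)) {
      new_mask <- !reject_outliers(z, centric, p_cut)
      if (delta < tol && all(new_mask == mask)) { converged <- TRUE; mask <- new_mask; break }
      mask <- new_mask
    } else if (delta < tol) { converged <- TRUE; break }
  }
  z <- corr / Sigma[bin]
  structure(list(Sigma = Sigma, z = z, factors = factors, binning = binning,
                 mask = mask, iterations = it, converged = converged),
            class = "norm_state")
}

#' Wilson outlier rejection
#'
#' Rejects implausibly strong normalized intensities: acentric when
#' `z > -log(p_cut)` (exponential tail), centric when
#' `z > qnorm(1 - p_cut/2)^2` (squared-normal tail).
#'
#' @param z normalized intensities.
#' @param centric logical vector.
#' @param p_cut tail probability in (0, 0.1).
#' @return logical vector, TRUE = reject.
#' @export
reject_outliers <- function(z, centric, p_cut = 1e-6) {
  if (!is.numeric(p_cut) || p_cut <= 0 || p_cut >= 0.1) {
    stop("p_cut must lie in (0, 0.1)")
  }
  thr_ac <- -log(p_cut)
  thr_ce <- qnorm(1 - p_cut / 2)^2
  ifelse(centric, z > thr_ce, z > thr_ac)
}

#' Second moments of normalized intensities
#'
#' Count-weighted mean over resolution bins of `<z^2>/<z>^2` per class, with a
#' jackknife-over-bins standard error. Expected 2.0 acentric / 3.0 centric for
#' untwinned data; 1.5 / 2.0 for a perfect twin.
#'
#' @param state a [estimate_sigma_curve()] result (or plain numeric z, with
#'   `binning` supplied).
#' @param centric logical vector.
#' @param binning optional [make_binning()]; defaults to the state's.
#' @param min_class_per_bin bins contribute to a class only with at least this
#'   many reflections of the class (default 10).
#' @return list with members `acentric` and `centric`, each either `NULL`
#'   (class absent) or a list `m2`, `se`, `n`.
#' @export
second_moments <- function(state, centric, binning = NULL, min_class_per_bin = 10) {
  if (inherits(state, "norm_state")) {
    z <- state$z; binning <- binning %||% state$binning; mask <- state$mask
  } else {
    z <- state; mask <- rep(TRUE, length(z))
    if (is.null(binning)) stop("binning required when state is a plain vector")
  }
  one_class <- function(sel) {
    sel <- sel & mask
    if (sum(sel) == 0) return(NULL)
    bs <- binning$bin[sel]; zs <- z[sel]
    tab <- tabulate(bs, nbins = binning$nbins)
    use <- which(tab >= min_class_per_bin)
    if (length(use) < 2) {
      # too few bins for a jackknife: single global estimate, se by simple
      # delta method unavailable -> report NA se
      m2 <- mean(zs^2) / mean(zs)^2
      return(list(m2 = m2, se = NA_real_, n = sum(sel)))
    }
    m1b <- vapply(use, function(b) mean(zs[bs == b]), numeric(1))
    m2b <- vapply(use, function(b) mean(zs[bs == b]^2), numeric(1))
    nb <- tab[use]
    est <- sum(nb * (m2b / m1b^2)) / sum(nb)
    loo <- vapply(seq_along(use), function(i) {
      sum(nb[-i] * (m2b[-i] / m1b[-i]^2)) / sum(nb[-i])
    }, numeric(1))
    k <- length(use)
    se <- sqrt((k - 1) / k * sum((loo - mean(loo))^2))
    list(m2 = est, se = se, n = sum(sel))
  }
  list(acentric = one_class(!centric), centric = one_class(centric))
}

#' Detect prior French-Wilson treatment
#'
#' Data already pushed through the French-Wilson posterior have no negative
#' intensities and a depleted low tail (the posterior pulls weak intensities
#' up toward the Wilson prior mean). Flagged when both hold: zero negatives
#' and the acentric fraction below z = 0.05 under half its Wilson expectation
#' `1 - exp(-0.05)`.
#'
#' @param dataset a [refl_dataset()] (or plain intensity vector).
#' @param state optional precomputed [estimate_sigma_curve()] state; computed
#'   from the dataset when missing.
#' @return list `suspected` (logical) and `evidence` (list `frac_negative`,
#'   `low_tail_deficit`).
#' @export
detect_french_wilson <- function(dataset, state = NULL) {
  if (inherits(dataset, "refl_dataset")) {
    I <- dataset$I
    if (is.null(state)) {
      s2 <- s2_of(dataset$hkl, dataset$cell)
      binning <- make_binning(s2)
      eps <- epsilon_factor(dataset$hkl, dataset$pg)
      cen <- is_centric(dataset$hkl, dataset$pg)
      state <- estimate_sigma_curve(I, binning, factors = eps, centric = cen)
    } else {
      cen <- is_centric(dataset$hkl, dataset$pg)
    }
    z_ac <- state$z[!cen]
  } else {
    I <- dataset
    if (is.null(state)) stop("state required when dataset is a plain vector")
    z_ac <- state$z
  }
  frac_neg <- mean(I < 0)
  expect_low <- 1 - exp(-0.05)                       # 0.0488 for unit exponential
  frac_low <- if (length(z_ac)) mean(z_ac < 0.05) else NA_real_
  deficit <- 1 - frac_low / expect_low
  list(suspected = (frac_neg == 0) && isTRUE(frac_low < 0.5 * expect_low),
       evidence = list(frac_negative = frac_neg, low_tail_deficit = deficit))
}

#' French-Wilson posterior moments
#'
#' Posterior of the true intensity J given a Gaussian measurement I +/- sigI
#' and an acentric Wilson (exponential, mean Sigma) prior. The posterior is a
#' normal truncated at zero with location `mu = I - sigI^2/Sigma` and scale
#' `sigI`; intensity moments are closed-form, amplitude moments are evaluated
#' by quadrature.
#'
#' @param I measured intensity (may be negative).
#' @param sigI measurement standard deviation, > 0.
#' @param Sigma Wilson prior mean (> 0), e.g. the bin mean from
#'   [estimate_sigma_curve()].
#' @return list `I_post`, `sigI_post`, `F_post`, `sigF_post` (vectors).
#' @export
french_wilson_posterior <- function(I, sigI, Sigma) {
  if (any(Sigma <= 0)) stop("french_wilson_posterior: Sigma must be positive")
  if (any(sigI <= 0)) stop("french_wilson_posterior: sigI must be positive")
  k <- max(length(I), length(sigI), length(Sigma))
  I <- rep_len(I, k); sigI <- rep_len(sigI, k); Sigma <- rep_len(Sigma, k)
  mu <- I - sigI^2 / Sigma
  a <- mu / sigI
  # truncated-normal moments, stable via Mills ratio for very negative a
  lambda <- exp(dnorm(a, log = TRUE) - pnorm(a, log.p = TRUE))
  I_post <- mu + sigI * lambda
  var_post <- sigI^2 * (1 - lambda * (lambda - a))
  var_post[var_post < 0] <- 0
  F_post <- sigF_post <- numeric(k)
  for (i in seq_len(k)) {
    dens <- function(J) exp(dnorm(J, mu[i], sigI[i], log = TRUE) - pnorm(a[i], log.p = TRUE))
    EF <- integrate(function(J) sqrt(J) * dens(J), 0, Inf, rel.tol = 1e-9,
                    stop.on.error = FALSE)$value
    F_post[i] <- EF
    sigF_post[i] <- sqrt(max(I_post[i] - EF^2, 0))
  }
  list(I_post = I_post, sigI_post = sqrt(var_post), F_post = F_post, sigF_post = sigF_post)
}
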