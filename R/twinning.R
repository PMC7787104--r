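# TNCS-aware Padilla-Yeates L-test.
#
# L = (z1 - z2)/(z1 + z2) for pairs of nearby, symmetry-unrelated reflections
# whose normalized intensities z have had symmetry, anisotropy and TNCS
# expected-intensity factors divided out. For untwinned acentric data L is
# uniform on (-1, 1), so <|L|> = 1/2; for a perfect twin <|L|> = 3/8. The
# test statistic is the standardized departure of the observed mean |L| from
# the untwinned reference, oriented so that untwinned data give p near 1 and
# twinned data give tiny p.

#' Select L-test reflection pairs
#'
#' Unordered pairs of distinct reflections with index difference bounded by
#' `max_step` in every component, never symmetry-related under the Laue group
#' (guaranteed here because the dataset is canonical and indices distinct),
#' each reflection used in at most `max_degree` pairs to keep dependence weak.
#'
#' @param dataset a canonical [refl_dataset()].
#' @param max_step bound on each |Delta h| component (default 2).
#' @param max_degree cap on pairs per reflection (default 4).
#' @param keep optional logical vector: rows eligible for pairing. The
#'   reference distributions assume acentric statistics, so centric
#'   reflections should be excluded (done by [twin_test()]).
#' @return 2-column integer matrix of row indices into the dataset.
#' @export
select_ltest_pairs <- function(dataset, max_step = 2, max_degree = 4, keep = NULL) {
  H <- dataset$hkl
  n <- nrow(H)
  if (n == 0) return(matrix(integer(0), 0, 2))
  keep <- keep %||% rep(TRUE, n)
  key <- paste(H[, 1], H[, 2], H[, 3])
  lookup <- new.env(parent = emptyenv())
  for (i in which(keep)) assign(key[i], i, envir = lookup)
  # positive-lexicographic offsets only: each unordered pair considered once
  offs <- as.matrix(expand.grid(dh = -max_step:max_step, dk = -max_step:max_step,
                                dl = -max_step:max_step))
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & (offs[, 2] > 0 | (offs[, 2] == 0 & offs[, 3] > 0))), ,
               drop = FALSE]
  degree <- integer(n)
  cap <- n * max_degree
  from <- integer(cap); to <- integer(cap); np <- 0L
  ord <- order(H[, 1], H[, 2], H[, 3])
  ord <- ord[keep[ord]]
  for (i in ord) {
    if (degree[i] >= max_degree) next
    for (r in seq_len(nrow(offs))) {
      h2 <- H[i, ] + offs[r, ]
      j <- lookup[[paste(h2[1], h2[2], h2[3])]]
      if (is.null(j) || degree[j] >= max_degree) next
      np <- np + 1L
      from[np] <- i; to[np] <- j
      degree[i] <- degree[i] + 1L
      degree[j] <- degree[j] + 1L
      if (degree[i] >= max_degree) break
    }
  }
  cbind(from = from[seq_len(np)], to = to[seq_len(np)])
}

#' L-test statistics
#'
#' @param pairs 2-column index matrix from [select_ltest_pairs()] (or any
#'   pairing of the z vector).
#' @param z corrected normalized intensities (symmetry, anisotropy and TNCS
#'   factors divided out).
#' @return list `mean_absL`, `n` (pairs used), `curve` (data frame with the
#'   empirical cumulative distribution of |L| on a 0.02 grid).
#' @export
ltest_statistics <- function(pairs, z) {
  if (nrow(pairs) == 0) stop("ltest_statistics: no pairs")
  z1 <- z[pairs[, 1]]; z2 <- z[pairs[, 2]]
  ok <- is.finite(z1) & is.finite(z2) & (z1 + z2) > 0
  if (!any(ok)) stop("ltest_statistics: all pairs degenerate (z1 + z2 <= 0)")
  L <- (z1[ok] - z2[ok]) / (z1[ok] + z2[ok])
  absL <- abs(L)
  grid <- seq(0, 1, by = 0.02)
  curve <- data.frame(absL = grid,
                      cumulative = vapply(grid, function(g) mean(absL <= g), numeric(1)))
  list(mean_absL = mean(absL), n = length(absL), curve = curve)
}

# cache for Monte-Carlo |L| reference moments
.ltest_ref_cache <- new.env(parent = emptyenv())

# mean and sd of |L| for twin fraction alpha, by seeded Monte Carlo
ltest_reference <- function(alpha, n_mc = 1e6, mc_seed = 990017) {
  key <- sprintf("%.6f_%d", alpha, n_mc)
  hit <- .ltest_ref_cache[[key]]
  if (!is.null(hit)) return(hit)
  res <- with_seed(mc_seed, {
    mix <- function() (1 - alpha) * rexp(n_mc) + alpha * rexp(n_mc)
    J1 <- mix(); J2 <- mix()
    absL <- abs((J1 - J2) / (J1 + J2))
    list(mean = mean(absL), sd = sd(absL))
  })
  if (alpha == 0) res$mean <- 0.5        # exact: |L| uniform on (0, 1)
  .ltest_ref_cache[[key]] <- res
  res
}

#' Expected mean |L| for a given twin fraction
#'
#' Monte-Carlo expectation of |L| for pairs of `(1-alpha) I1 + alpha I2`
#' mixtures of independent unit exponentials (deterministic: fixed internal
#' seed, cached). 0.5 at alpha = 0, 0.375 at alpha = 0.5, monotone
#' non-increasing in between.
#'
#' @param alpha twin fraction in `[0, 0.5]`.
#' @return scalar expected mean |L|.
#' @export
expected_mean_absL <- function(alpha) {
  if (!is.numeric(alpha) || alpha < 0 || alpha > 0.5) {
    stop("alpha must lie in [0, 0.5]")
  }
  ltest_reference(alpha)$mean
}

#' Twin p-values from L-test statistics
#'
#' `p_untwinned = pnorm((mean_absL - 0.5) / se0)`: the probability, under the
#' untwinned null, of a mean |L| at least as twin-like (small) as observed —
#' near 1 for untwinned data, tiny for twinned data. `p_twin_le_5pct` is the
#' same construction against the alpha = 0.05 reference.
#'
#' @param stats list with `mean_absL` and `n` (from [ltest_statistics()]).
#' @return list `p_untwinned`, `p_twin_le_5pct`.
#' @export
twin_pvalues <- function(stats) {
  if (stats$n < 100) stop("twin_pvalues: need at least 100 pairs")
  r0 <- ltest_reference(0)
  r5 <- ltest_reference(0.05)
  list(p_untwinned = pnorm((stats$mean_absL - r0$mean) / (r0$sd / sqrt(stats$n))),
       p_twin_le_5pct = pnorm((stats$mean_absL - r5$mean) / (r5$sd / sqrt(stats$n))))
}

#' Full twin report for a corrected dataset
#'
#' Runs pair selection, the L statistics and the p-values on fully corrected
#' normalized intensities, and issues the verdict used as the subgroup
#' expansion trigger.
#'
#' @param dataset corrected canonical [refl_dataset()].
#' @param z normalized intensities aligned with the dataset rows (computed
#'   from the dataset when missing).
#' @param p_threshold verdict threshold on `p_untwinned` (default 1e-6).
#' @param max_step,max_degree pair-selection controls.
#' @return object of class `twin_report`: `n_pairs`, `mean_absL`,
#'   `p_untwinned`, `p_twin_le_5pct`, `curve`, `verdict`
#'   (`"twinned"`/`"untwinned"`).
#' @export
twin_test <- function(dataset, z = NULL, p_threshold = 1e-6, max_step = 2,
                      max_degree = 4) {
  cen <- is_centric(dataset$hkl, dataset$pg)
  if (is.null(z)) {
    s2 <- s2_of(dataset$hkl, dataset$cell)
    eps <- epsilon_factor(dataset$hkl, dataset$pg)
    st <- estimate_sigma_curve(dataset$I, make_binning(s2), factors = eps,
                               centric = cen)
    z <- st$z
  }
  pairs <- select_ltest_pairs(dataset, max_step = max_step, max_degree = max_degree,
                              keep = !cen)
  stats <- ltest_statistics(pairs, z)
  pv <- twin_pvalues(stats)
  structure(list(n_pairs = stats$n, mean_absL = stats$mean_absL,
                 p_untwinned = pv$p_untwinned, p_twin_le_5pct = pv$p_twin_le_5pct,
                 curve = stats$curve,
                 verdict = if (pv$p_untwinned < p_threshold) "twinned" else "untwinned"),
            class = "twin_report")
}

#' @export
print.twin_report <- function(x, ...) {
  cat(sprintf("L-test: %d pairs, mean |L| = %.4f (0.5 untwinned, 0.375 perfect twin)\n",
              x$n_pairs, x$mean_absL))
  cat(sprintf("  P(untwinned) = %.3g, P(twin alpha < 5%%) = %.3g -> %s\n",
              x$p_untwinned, x$p_twin_le_5pct, x$verdict))
  invisible(x)
}
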